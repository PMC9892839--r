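#' Delimited-text interfaces
#'
#' All tabular inputs and outputs are UTF-8 TSV files with a header row:
#' a phenotype table (`subject_id`, `age`, `sex`, `protocol`, `transition`,
#' `followup_years`), per-family feature tables (`subject_id` + feature
#' columns, plus a `TIV` column for the sMRI families), a dosage table
#' (`subject_id` + one 0/1/2/NA column per SNP), a weight table (`snp_id`,
#' `effect_allele`, `weight`, `p_value`, ...), and an exposure table
#' (`subject_id` + eight factor columns with NA for missing).
#'
#' @name tsv_io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' @rdname tsv_io
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @export
write_phenotype_tsv <- function(cohort, path) {
  write_tsv(data.frame(subject_id = cohort$subject_id,
                       age = cohort$age_years, sex = cohort$sex,
                       protocol = cohort$protocol,
                       transition = cohort$transition,
                       followup_years = cohort$followup_years), path)
}

#' @rdname tsv_io
#' @export
read_phenotype_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("subject_id", "age", "sex", "protocol", "transition",
            "followup_years")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed phenotype TSV: need columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(subject_id = as.character(df$subject_id),
                    age_years = df$age, sex = df$sex, protocol = df$protocol,
                    transition = df$transition,
                    followup_years = df$followup_years,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @rdname tsv_io
#' @param features a `modality_features`.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(subject_id = rownames(features$values),
                   features$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(features$tiv)) df$TIV <- unname(features$tiv)
  write_tsv(df, path)
}

#' @rdname tsv_io
#' @param family modality family tag for the table being read.
#' @export
read_features_tsv <- function(path, family) {
  df <- read_tsv(path)
  if (!"subject_id" %in% names(df)) {
    stop("malformed feature TSV: no subject_id column", call. = FALSE)
  }
  ids <- as.character(df$subject_id)
  tiv <- NULL
  if ("TIV" %in% names(df)) {
    tiv <- df$TIV
    names(tiv) <- ids
  }
  vals <- as.matrix(df[setdiff(names(df), c("subject_id", "TIV"))])
  rownames(vals) <- ids
  modality_features(vals, family, tiv = tiv)
}

#' @rdname tsv_io
#' @param dosages subjects x SNPs dosage matrix.
#' @export
write_dosage_tsv <- function(dosages, path) {
  write_tsv(data.frame(subject_id = rownames(dosages), dosages,
                       check.names = FALSE, stringsAsFactors = FALSE), path)
}

#' @rdname tsv_io
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path)
  ids <- as.character(df$subject_id)
  m <- as.matrix(df[setdiff(names(df), "subject_id")])
  rownames(m) <- ids
  m
}

#' @rdname tsv_io
#' @param weights weight table data frame.
#' @export
write_weight_tsv <- function(weights, path) write_tsv(weights, path)

#' @rdname tsv_io
#' @export
read_weight_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("snp_id", "effect_allele", "weight") %in% names(df))) {
    stop("malformed weight TSV: need snp_id, effect_allele, weight",
         call. = FALSE)
  }
  df$snp_id <- as.character(df$snp_id)
  df
}

#' @rdname tsv_io
#' @param exposures exposure data frame.
#' @export
write_exposure_tsv <- function(exposures, path) write_tsv(exposures, path)

#' @rdname tsv_io
#' @export
read_exposure_tsv <- function(path) {
  df <- read_tsv(path)
  if (!"subject_id" %in% names(df)) {
    stop("malformed exposure TSV: no subject_id column", call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df
}
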