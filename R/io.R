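# Delimited-text readers and writers for the pipeline's tables.  All
# files are plain TSV; abundance matrices carry a two-line metadata
# header (treatment and region per sample) above the feature rows.

#' Write / read an axial-length cohort table
#'
#' Columns `plant`, `day`, `treatment`, `length_cm`.
#'
#' @param cohort data frame.
#' @param path file path.
#' @return `read_cohort_tsv` returns the data frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a position-indexed profile
#'
#' Two-column TSV: `position_mm` and the profile value (any value column
#' name is preserved).
#'
#' @param profile data frame whose first column is `position_mm`.
#' @param path file path.
#' @return `read_profile_tsv` returns the data frame.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write an abundance matrix as TSV
#'
#' Features in rows, samples in columns, preceded by two comment header
#' lines carrying each sample's treatment and region.
#'
#' @param m an [abundance_matrix()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_abundance_tsv <- function(m, path) {
  stopifnot(inherits(m, "abundance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#treatment", m$samples$treatment), collapse = "\t"),
             con)
  writeLines(paste(c("#region", m$samples$region), collapse = "\t"), con)
  writeLines(paste(c("feature", m$samples$sample), collapse = "\t"), con)
  for (i in seq_len(nrow(m$values))) {
    writeLines(paste(c(rownames(m$values)[i],
                       ifelse(is.na(m$values[i, ]), "NA",
                              format(m$values[i, ], digits = 15,
                                     trim = TRUE, scientific = FALSE))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an abundance matrix written by [write_abundance_tsv()]
#'
#' @param path file path.
#' @return An [abundance_matrix()].
#' @export
read_abundance_tsv <- function(path) {
  lines <- readLines(path)
  trt <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  reg <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  body <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                     check.names = FALSE)
  vals <- as.matrix(body[, -1, drop = FALSE])
  rownames(vals) <- body[[1]]
  samples <- data.frame(sample = colnames(vals), treatment = trt,
                        region = reg,
                        replicate = stats::ave(seq_along(trt),
                                               paste(trt, reg),
                                               FUN = seq_along),
                        stringsAsFactors = FALSE)
  abundance_matrix(vals, samples)
}

#' Export a logistic fit as JSON
#'
#' @param fit a `logistic_fit` from [fit_logistic()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(a1 = fit$a1, a2 = fit$a2, x0 = fit$x0, p = fit$p, R = fit$R,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
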