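# Cohort container and delimited-text I/O.
#
# A cohort couples a wide relative-abundance table (one row per sample, one
# column per bacterial family) with per-sample metadata (subject, yearly
# collection wave, covariates). All downstream distance and stability
# operations take the cohort object first and return tibbles.

#' Construct a longitudinal cohort from abundance and metadata tables
#'
#' Validates and couples a wide family-level relative-abundance table with
#' per-sample metadata. Every abundance row must lie on the unit simplex:
#' rows whose sum deviates from 1 by at most `1e-6` are renormalized to sum
#' exactly 1 (sequencing pipelines export rounded fractions); larger
#' deviations and negative entries are errors.
#'
#' @param abundance A data frame with a `sample_id` column followed by one
#'   numeric column per bacterial family. Rows are samples; values are
#'   relative abundances in `[0, 1]` summing to 1 per row.
#' @param metadata A data frame with columns `sample_id`, `subject_id`,
#'   `year_index` (integer collection wave, 1-based) and any number of
#'   per-subject covariate columns (e.g. `age`, `sex`, `bmi`, `smoker`,
#'   `alcohol`, `intake_group_10y`). Missing covariate values are allowed
#'   and are dropped listwise by the statistical routines that use them.
#'
#' @return An object of class `gut_cohort`: a list with elements
#'   `abundance` (tibble, renormalized), `metadata` (tibble) and
#'   `families` (character vector, in table-column order). The original
#'   row sums are kept in the `row_sums` attribute of `abundance`.
#'
#' @details `year_index` is an ordinal wave number, not a calendar year;
#'   consecutive waves are assumed roughly one year apart. The pair
#'   (`subject_id`, `year_index`) must be unique.
#'
#' @examples
#' ab <- tibble::tibble(sample_id = c("s1", "s2"),
#'                      Bacteroidaceae = c(0.6, 0.3),
#'                      Lachnospiraceae = c(0.4, 0.7))
#' md <- tibble::tibble(sample_id = c("s1", "s2"),
#'                      subject_id = c("A", "A"), year_index = c(1L, 2L))
#' gut_cohort(ab, md)
#' @export
gut_cohort <- function(abundance, metadata) {
  abundance <- tibble::as_tibble(abundance)
  metadata <- tibble::as_tibble(metadata)
  if (!"sample_id" %in% names(abundance)) {
    abort("`abundance` must have a `sample_id` column (first column).")
  }
  req <- c("sample_id", "subject_id", "year_index")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0) {
    abort(paste0("`metadata` is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  families <- setdiff(names(abundance), "sample_id")
  if (length(families) < 2) {
    abort("Abundance table needs at least 2 family columns.")
  }
  mat <- as.matrix(abundance[families])
  if (!is.numeric(mat)) abort("Family columns must be numeric.")
  if (anyNA(mat)) abort("Abundance table contains missing values.")
  if (any(mat < 0)) {
    bad <- abundance$sample_id[which(rowSums(mat < 0) > 0)[1]]
    abort(paste0("negative abundance in sample '", bad, "'"))
  }
  sums <- rowSums(mat)
  off <- abs(sums - 1) > 1e-6 * (1 + 1e-6)  # exact boundary is accepted
  if (any(off)) {
    abort(paste0("Row sum of sample '", abundance$sample_id[which(off)[1]],
                 "' is ", format(sums[which(off)[1]]),
                 "; must be within 1e-6 of 1."))
  }
  mat <- mat / sums
  abundance[families] <- mat

  if (anyDuplicated(abundance$sample_id)) {
    abort("Duplicate sample_id in abundance table.")
  }
  unknown <- setdiff(metadata$sample_id, abundance$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("metadata sample_id not in abundance table: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  orphan <- setdiff(abundance$sample_id, metadata$sample_id)
  if (length(orphan) > 0) {
    abort(paste0("abundance sample_id missing from metadata: ",
                 paste(head(orphan, 3), collapse = ", ")))
  }
  metadata$year_index <- as.integer(metadata$year_index)
  if (any(metadata$year_index < 1)) abort("year_index must be >= 1.")
  key <- paste(metadata$subject_id, metadata$year_index)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (subject_id, year_index): ",
                 key[anyDuplicated(key)]))
  }
  metadata <- metadata[match(abundance$sample_id, metadata$sample_id), ]
  attr(abundance, "row_sums") <- sums
  structure(list(abundance = abundance, metadata = metadata,
                 families = families),
            class = "gut_cohort")
}

#' @export
print.gut_cohort <- function(x, ...) {
  n_sub <- dplyr::n_distinct(x$metadata$subject_id)
  yrs <- sort(unique(x$metadata$year_index))
  cat("<gut_cohort> ", nrow(x$abundance), " samples, ", n_sub,
      " subjects, ", length(x$families), " families, waves ",
      paste(yrs, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A [gut_cohort()].
#' @return Integer sample count.
#' @export
n_samples <- function(cohort) nrow(cohort$abundance)

# Abundance rows as a named-row matrix (samples x families).
abundance_matrix <- function(cohort) {
  m <- as.matrix(cohort$abundance[cohort$families])
  rownames(m) <- cohort$abundance$sample_id
  m
}

#' Read a cohort from delimited abundance and metadata files
#'
#' @param path Path to the abundance table: TSV or CSV (sniffed from the
#'   extension, `.csv` means comma), first column `sample_id`, remaining
#'   columns one per family.
#' @param metadata_path Path to the metadata table with columns
#'   `sample_id`, `subject_id`, `year_index` and optional covariates.
#' @return A validated [gut_cohort()].
#' @export
read_abundance_table <- function(path, metadata_path) {
  gut_cohort(read_delim_auto(path), read_delim_auto(metadata_path))
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write / read a square labelled distance matrix
#'
#' `write_distance_matrix()` stores a [pairwise_distances()] result as a
#' square TSV with a header row and a label column; numbers are written at
#' full double precision so `read_distance_matrix(write(x))` round-trips
#' within 1e-12 (in practice exactly).
#'
#' @param matrix A `gut_dist` object or a symmetric, zero-diagonal base
#'   matrix with row/column names.
#' @param path Output file path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns a `gut_dist` object.
#' @export
write_distance_matrix <- function(matrix, path) {
  metric <- "unknown"
  if (inherits(matrix, "gut_dist")) {
    metric <- attr(matrix, "metric")
    matrix <- unclass_dist(matrix)
  }
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-12))) {
    abort("Distance matrix is not symmetric.")
  }
  if (any(diag(matrix) != 0)) abort("Distance matrix diagonal must be 0.")
  df <- data.frame(sample_id = rownames(matrix),
                   matrix, check.names = FALSE)
  readr::write_tsv(df, path, num_threads = 1)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  new_gut_dist(m, metric = "unknown")
}

#' Write / read a stability report
#'
#' Serializes a [stability_report()] tibble to tidy TSV, one row per
#' subject. Missing third-wave distances are written as empty fields and
#' the persistence category as `NA`.
#'
#' @param report A `stability_report` tibble.
#' @param path Output file path.
#' @return `write_stability_report()` returns `path` invisibly;
#'   `read_stability_report()` returns the report tibble (threshold
#'   restored from the header comment).
#' @export
write_stability_report <- function(report, path) {
  thr <- attr(report, "threshold")
  lines <- paste0("# threshold: ", format(thr, digits = 17))
  readr::write_lines(lines, path)
  readr::write_tsv(report, path, append = TRUE, col_names = TRUE,
                   num_threads = 1)
  invisible(path)
}

#' @rdname write_stability_report
#' @export
read_stability_report <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  thr <- as.numeric(sub("^# threshold: ", "", first))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "threshold") <- thr
  class(out) <- c("stability_report", class(out))
  out
}
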