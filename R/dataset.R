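## Multi-study genotype-count datasets: read, validate, write, access.

#' @keywords internal
PHENOTYPES <- c("neovascular_amd", "pcv", "control")

DATASET_COLUMNS <- c("study_id", "year", "ethnicity", "phenotype",
                     "n_gg", "n_gt", "n_tt")

#' Read a multi-study genotype-count dataset
#'
#' Reads a comma-separated table with one row per (study, phenotype group)
#' and validates it. Required header columns: `study_id`, `year`,
#' `ethnicity`, `phenotype`, `n_gg`, `n_gt`, `n_tt`. The phenotype vocabulary
#' is closed — `neovascular_amd`, `pcv` or `control` — to prevent silent
#' group mismatches in subtype comparisons.
#'
#' An empty file (header only) yields an empty dataset; errors are raised
#' only when a meta-analytic operation is attempted on it.
#'
#' @param path Path to the CSV file.
#' @return An object of class `snp_dataset` (a validated data frame, one row
#'   per study-phenotype pair).
#' @examples
#' path <- system.file("extdata", "table2.csv", package = "snpmeta")
#' ds <- read_dataset(path)
#' ds
#' @seealso [write_dataset()], [study_group()], [simulate_dataset()]
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_snp_dataset(df)
}

#' Validate a data frame as an snp_dataset
#'
#' @param df Data frame with the columns described in [read_dataset()].
#' @return The validated `snp_dataset`.
#' @export
as_snp_dataset <- function(df) {
  missing_cols <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, DATASET_COLUMNS]
  if (nrow(df) > 0) {
    bad_ph <- !df$phenotype %in% PHENOTYPES
    if (any(bad_ph)) {
      stop("unknown phenotype label(s) in row(s) ",
           paste(which(bad_ph), collapse = ", "), ": ",
           paste(unique(df$phenotype[bad_ph]), collapse = ", "),
           " (allowed: ", paste(PHENOTYPES, collapse = ", "), ")",
           call. = FALSE)
    }
    cnt <- as.matrix(df[, c("n_gg", "n_gt", "n_tt")])
    if (anyNA(cnt) || any(cnt < 0)) {
      bad <- which(apply(cnt, 1, function(r) anyNA(r) || any(r < 0)))
      stop("negative or missing genotype count(s) in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    key <- paste(df$study_id, df$phenotype, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      stop("duplicate (study, phenotype) row(s): ",
           paste(sprintf("row %d (%s, %s)", dup, df$study_id[dup],
                         df$phenotype[dup]), collapse = "; "),
           call. = FALSE)
    }
  }
  df$study_id <- as.character(df$study_id)
  df$phenotype <- as.character(df$phenotype)
  class(df) <- c("snp_dataset", "data.frame")
  df
}

#' Write a dataset back to CSV
#'
#' Inverse of [read_dataset()]: the round trip reproduces the file up to
#' column order and whitespace.
#'
#' @param dataset An `snp_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "snp_dataset"))
  utils::write.csv(as.data.frame(dataset)[, DATASET_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.snp_dataset <- function(x, ...) {
  ids <- unique(x$study_id)
  cat(sprintf("<snp_dataset> %d stud%s, %d group rows, %d subjects\n",
              length(ids), if (length(ids) == 1) "y" else "ies", nrow(x),
              sum(x$n_gg + x$n_gt + x$n_tt)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Study identifiers of a dataset
#'
#' @param dataset An `snp_dataset`.
#' @param phenotype Optional phenotype label; if given, only studies that
#'   contain that group are returned (in dataset order).
#' @return Character vector of study ids.
#' @export
study_ids <- function(dataset, phenotype = NULL) {
  stopifnot(inherits(dataset, "snp_dataset"))
  if (!is.null(phenotype)) {
    dataset <- dataset[dataset$phenotype == match.arg(phenotype, PHENOTYPES), ]
  }
  unique(dataset$study_id)
}

#' Extract one phenotype group of one study
#'
#' @param dataset An `snp_dataset`.
#' @param study A study id present in the dataset.
#' @param phenotype One of `"neovascular_amd"`, `"pcv"`, `"control"`.
#' @return The group's [genotype_counts], or `NULL` if the study lacks that
#'   group.
#' @export
study_group <- function(dataset, study, phenotype) {
  stopifnot(inherits(dataset, "snp_dataset"))
  phenotype <- match.arg(phenotype, PHENOTYPES)
  if (!study %in% dataset$study_id) {
    stop("no study '", study, "' in dataset", call. = FALSE)
  }
  row <- dataset[dataset$study_id == study & dataset$phenotype == phenotype, ]
  if (nrow(row) == 0) return(NULL)
  genotype_counts(row$n_gg, row$n_gt, row$n_tt)
}

#' Studies containing both disease subtypes
#'
#' @param dataset An `snp_dataset`.
#' @return Character vector of study ids that contain both a
#'   `neovascular_amd` and a `pcv` case group.
#' @export
dual_subtype_studies <- function(dataset) {
  intersect(study_ids(dataset, "neovascular_amd"), study_ids(dataset, "pcv"))
}

## Internal: list of per-study case/control genotype pairs for a phenotype,
## restricted to studies that have both the case group and a control group.
case_control_pairs <- function(dataset, phenotype) {
  ids <- intersect(study_ids(dataset, phenotype), study_ids(dataset, "control"))
  if (length(ids) == 0) {
    stop("no study with both a '", phenotype,
         "' group and a control group in dataset", call. = FALSE)
  }
  lapply(stats::setNames(ids, ids), function(id) {
    list(case = study_group(dataset, id, phenotype),
         control = study_group(dataset, id, "control"))
  })
}
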