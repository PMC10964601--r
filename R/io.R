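# On-disk conventions: tab-separated numeric tables with an optional single
# header row; region order is defined by the atlas, never inferred from
# headers.  The manifest is a CSV with columns subject_id,site,cohort,path.

COHORT_LEVELS <- c("youth", "older_excellent", "older_poor")

# Parse a delimited numeric table strictly: any non-numeric cell is an error
# that names its coordinates (1-based, counting data rows after the header).
parse_numeric_table <- function(path, what = "table") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(what, " file is empty: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  has_header <- anyNA(first)
  header <- NULL
  if (has_header) {
    header <- fields[[1L]]
    fields <- fields[-1L]
    if (length(fields) == 0L) {
      stop(what, " file has a header but no data rows: ", path,
           call. = FALSE)
    }
  }
  ncol <- length(fields[[1L]])
  nrow <- length(fields)
  out <- matrix(NA_real_, nrow, ncol)
  for (r in seq_len(nrow)) {
    row <- fields[[r]]
    if (length(row) != ncol) {
      stop(what, " row ", r, " has ", length(row),
           " fields, expected ", ncol, " (", path, ")", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(row))
    if (anyNA(vals)) {
      cbad <- which(is.na(vals))[1L]
      stop("non-numeric value '", row[cbad], "' at row ", r,
           ", column ", cbad, " of ", path, call. = FALSE)
    }
    out[r, ] <- vals
  }
  list(values = out, header = header)
}

#' Read a parcellated ROI time-series table
#'
#' Reads a tab-separated table with rows = timepoints and columns = regions
#' (one optional header row).  The column count must match the atlas; region
#' order is taken from the atlas, never from the header.
#'
#' @param path Path to the TSV file.
#' @param atlas A [region_atlas()] defining the expected regions.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return An object of class `roi_timeseries`: a timepoints x regions
#'   numeric matrix with attributes `subject_id` and region column names.
#' @export
read_timeseries <- function(path, atlas,
                            subject_id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- parse_numeric_table(path, what = "time-series")
  m <- tab$values
  if (ncol(m) != atlas$n_regions) {
    stop("expected ", atlas$n_regions, " regions, found ", ncol(m),
         " in ", path, call. = FALSE)
  }
  roi_timeseries(m, subject_id = subject_id, atlas = atlas)
}

#' Construct and validate an ROI time-series object
#'
#' @param values Timepoints x regions numeric matrix.
#' @param subject_id Subject identifier string.
#' @param atlas Optional [region_atlas()]; supplies column names.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id, atlas = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 3L) {
    stop("time series needs at least 3 timepoints, got ", nrow(values),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("time series for subject ", subject_id,
         " contains missing or non-finite values", call. = FALSE)
  }
  if (!is.null(atlas)) colnames(values) <- atlas$labels
  structure(values, subject_id = subject_id, class = "roi_timeseries")
}

#' Read a functional-connectivity matrix from a TSV file
#'
#' The file must hold a square numeric table (optional single header row).
#' Asymmetry beyond `asym_tol` is an error; a diagonal that is not exactly 1
#' is reset to 1 with a warning (self-correlation is definitionally 1 and the
#' diagonal enters no downstream computation).
#'
#' @param path Path to the TSV file.
#' @param subject_id Subject identifier; defaults to the file name.
#' @param asym_tol Maximum tolerated absolute asymmetry (default `1e-9`).
#' @return An object of class `fc_matrix`.
#' @export
read_fc_matrix <- function(path,
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           asym_tol = 1e-9) {
  tab <- parse_numeric_table(path, what = "FC-matrix")
  m <- tab$values
  if (nrow(m) != ncol(m)) {
    stop("matrix not square: ", nrow(m), " rows x ", ncol(m),
         " columns in ", path, call. = FALSE)
  }
  fc_matrix(m, subject_id = subject_id, asym_tol = asym_tol,
            repair_diagonal = TRUE)
}

#' Write a functional-connectivity matrix as TSV
#'
#' Values are serialized with 17 significant digits so that a
#' write-then-read round trip is lossless to double precision.
#'
#' @param m An `fc_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(m, path) {
  txt <- apply(unclass(m), 1L, function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
  })
  writeLines(txt, path)
  invisible(path)
}

#' Construct and validate an FC matrix
#'
#' Enforces the structural invariants of a functional-connectivity matrix:
#' square, finite, symmetric to within `asym_tol`, unit diagonal.  Entries of
#' a raw Pearson matrix lie in `[-1, 1]`; harmonized matrices may leave that
#' range and are deliberately not range-checked here.
#'
#' @param values R x R numeric matrix.
#' @param subject_id Subject identifier string.
#' @param asym_tol Maximum tolerated absolute asymmetry.
#' @param repair_diagonal If `TRUE`, a diagonal differing from 1 is reset to 1
#'   with a warning; if `FALSE` it is an error.
#' @return An object of class `fc_matrix` (a numeric matrix with a
#'   `subject_id` attribute).
#' @export
fc_matrix <- function(values, subject_id = "subject",
                      asym_tol = 1e-12, repair_diagonal = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop("FC matrix must be square, got ", nrow(values), " x ",
         ncol(values), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("FC matrix for subject ", subject_id,
         " contains non-finite values", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > asym_tol) {
    stop("FC matrix for subject ", subject_id, " is asymmetric (max |m - t(m)| = ",
         format(asym), ", tolerance ", format(asym_tol), ")", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  d <- diag(values)
  if (any(d != 1)) {
    if (!repair_diagonal) {
      stop("FC matrix diagonal must be 1 (max deviation ",
           format(max(abs(d - 1))), ")", call. = FALSE)
    }
    warning("FC matrix diagonal for subject ", subject_id,
            " deviates from 1 (max ", format(max(abs(d - 1))),
            "); reset to 1", call. = FALSE)
    diag(values) <- 1
  }
  structure(values, subject_id = subject_id, class = "fc_matrix")
}

#' Load a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `site`, `cohort`, `path`
#' listing every subject in the study.  Cohort labels must be one of
#' `youth`, `older_excellent`, `older_poor`.
#'
#' @param path Path to the manifest CSV.
#' @param check_paths If `TRUE` (default), every `path` entry must resolve to
#'   an existing file (relative paths are resolved against the manifest's
#'   directory).
#' @return A data frame of class `cohort_manifest`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "site", "cohort", "path")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort_manifest(df, base_dir = dirname(path), check_paths = check_paths)
}

#' Construct and validate a cohort manifest
#'
#' @param df Data frame with columns `subject_id`, `site`, `cohort`, `path`.
#' @param base_dir Directory against which relative paths are resolved.
#' @param check_paths Whether to require every path to exist.
#' @return A data frame of class `cohort_manifest`.
#' @export
cohort_manifest <- function(df, base_dir = ".", check_paths = TRUE) {
  df$subject_id <- as.character(df$subject_id)
  df$site <- as.character(df$site)
  df$cohort <- as.character(df$cohort)
  if (anyDuplicated(df$subject_id)) {
    dup <- df$subject_id[duplicated(df$subject_id)][1L]
    stop("duplicate subject_id in manifest: ", dup, call. = FALSE)
  }
  bad <- setdiff(unique(df$cohort), COHORT_LEVELS)
  if (length(bad)) {
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are: ", paste(COHORT_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (check_paths && "path" %in% names(df)) {
    resolved <- ifelse(file.exists(df$path), df$path,
                       file.path(base_dir, df$path))
    missing <- !file.exists(resolved)
    if (any(missing)) {
      stop("manifest references missing file(s): ",
           paste(utils::head(df$path[missing], 3L), collapse = ", "),
           call. = FALSE)
    }
    df$path <- resolved
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' @export
print.cohort_manifest <- function(x, ...) {
  counts <- table(x$cohort)
  cat("<cohort_manifest> ", nrow(x), " subjects (",
      paste(sprintf("%d %s", as.integer(counts), names(counts)),
            collapse = ", "),
      ") across ", length(unique(x$site)), " site(s)\n", sep = "")
  invisible(x)
}

#' Tabulate a manifest by site and cohort
#'
#' @param manifest A `cohort_manifest`.
#' @return A contingency table of subject counts, site x cohort.
#' @export
manifest_counts <- function(manifest) {
  table(site = manifest$site, cohort = manifest$cohort)
}

#' Write a subjects x regions score table as TSV
#'
#' @param scores Numeric matrix, rows named by subject, columns by region
#'   label.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (is.null(colnames(scores))) {
    colnames(scores) <- sprintf("Region_%03d", seq_len(ncol(scores)))
  }
  if (is.null(rownames(scores))) {
    rownames(scores) <- sprintf("subject_%03d", seq_len(nrow(scores)))
  }
  df <- data.frame(subject_id = rownames(scores),
                   scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a subjects x regions score table written by [write_scores()]
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with subject row names and region column names.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
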