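#' Pearson functional connectivity from an ROI time series
#'
#' Entry (i, j) of the result is the Pearson correlation between the BOLD
#' time series of regions i and j.  The diagonal is exactly 1 and all
#' entries lie in `[-1, 1]`.
#'
#' @param ts An `roi_timeseries` (timepoints x regions matrix), or any
#'   numeric matrix with at least 3 rows.
#' @return An `fc_matrix` of size R x R.
#' @examples
#' x <- matrix(rnorm(50 * 4), 50, 4)
#' fc <- pearson_fc(roi_timeseries(x, "s1"))
#' @export
pearson_fc <- function(ts) {
  m <- unclass(ts)
  subject_id <- attr(ts, "subject_id")
  if (is.null(subject_id)) subject_id <- "subject"
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    idx <- which(sds == 0)
    nm <- colnames(m)[idx]
    if (is.null(nm)) nm <- paste0("region ", idx)
    stop("zero-variance time series for region(s): ",
         paste(utils::head(nm, 5L), collapse = ", "),
         " (subject ", subject_id, ")", call. = FALSE)
  }
  r <- stats::cor(m)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r <- (r + t(r)) / 2
  diag(r) <- 1
  fc_matrix(r, subject_id = subject_id)
}

#' Flatten the strict upper triangle of an FC matrix to a connection vector
#'
#' Uses row-major strict-upper-triangle order
#' (1,2), (1,3), ..., (1,R), (2,3), ... so a 116-region matrix yields
#' `116 * 115 / 2 = 6670` connections.  This fixed ordering is the contract
#' shared by [devectorize()] and the harmonization stage.
#'
#' @param m An `fc_matrix` or square symmetric numeric matrix.
#' @return Numeric vector of length `R * (R - 1) / 2`, with attribute
#'   `subject_id` when present on the input.
#' @export
vectorize_upper <- function(m) {
  v <- t(unclass(m))[lower.tri(m)]   # row-major upper triangle
  attr(v, "subject_id") <- attr(m, "subject_id")
  v
}

#' Rebuild a symmetric FC matrix from a connection vector
#'
#' Inverse of [vectorize_upper()]: fills the strict upper triangle in
#' row-major order, mirrors it, and sets the diagonal to 1.
#'
#' @param v Numeric connection vector of length `R * (R - 1) / 2`.
#' @param n_regions The matrix size R.
#' @param subject_id Subject identifier for the rebuilt matrix.
#' @param validate If `FALSE`, skip `fc_matrix()` validation (harmonized
#'   vectors may contain values outside `[-1, 1]`; they are still valid
#'   symmetric matrices, so validation is on by default).
#' @return An `fc_matrix`.
#' @export
devectorize <- function(v, n_regions,
                        subject_id = attr(v, "subject_id"),
                        validate = TRUE) {
  expected <- n_regions * (n_regions - 1L) / 2L
  if (length(v) != expected) {
    stop("connection vector has length ", length(v), ", expected ",
         expected, " for ", n_regions, " regions", call. = FALSE)
  }
  if (is.null(subject_id)) subject_id <- "subject"
  m <- matrix(0, n_regions, n_regions)
  m[lower.tri(m)] <- as.numeric(v)
  m <- t(m)            # vector was row-major upper triangle
  m <- m + t(m)
  diag(m) <- 1
  if (validate) {
    fc_matrix(m, subject_id = subject_id)
  } else {
    structure(m, subject_id = subject_id, class = "fc_matrix")
  }
}

#' Number of connections for a given region count
#'
#' @param n_regions Number of regions R.
#' @return `R * (R - 1) / 2`.
#' @export
n_connections <- function(n_regions) {
  as.integer(n_regions * (n_regions - 1L) / 2L)
}

#' Regional connectivity profile
#'
#' Row `i` of the FC matrix with the self-connection removed: the FC between
#' region `i` and each of the other `R - 1` regions, in atlas order.  This
#' length-(R-1) vector is the `f` profile on which the connectome
#' distinctiveness index is based; the constant self-correlation of 1 is
#' excluded because it would bias the profile correlation.
#'
#' @param m An `fc_matrix`.
#' @param i Region index (1-based).
#' @return Numeric vector of length R - 1.
#' @export
region_profile <- function(m, i) {
  R <- nrow(m)
  if (i < 1L || i > R) {
    stop("region index ", i, " out of range 1..", R, call. = FALSE)
  }
  unclass(m)[i, -i]
}

#' Average FC matrices over a set of subjects
#'
#' Elementwise mean of a list of FC matrices (cohort-level summary).
#'
#' @param fc_list List of `fc_matrix` objects of the same size.
#' @return An `fc_matrix` labelled `"average"`.
#' @export
average_fc <- function(fc_list) {
  stopifnot(length(fc_list) >= 1L)
  acc <- Reduce(`+`, lapply(fc_list, unclass))
  fc_matrix(acc / length(fc_list), subject_id = "average")
}
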