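# The resting-state FC scores model (rs-FCSM).
#
# For subject s and region i, the connectome distinctiveness index is
#   CDI_{s,i} = 1/(N-1) * sum_{p=1}^{N} (1 - corr(f_{s,i}, f_{p,i}))
# where f_{.,i} is the length-(R-1) connectivity profile of region i
# (self-connection excluded) and p runs over the N reference (youth)
# subjects.  The sum has N terms but the divisor is N-1: when a youth
# subject is scored against their own cohort the self term is exactly
# 1 - corr(f, f) = 0, which makes the divisor natural; for non-reference
# subjects the index is uniformly inflated by N/(N-1), which is harmless
# after Z-standardization and is kept as defined.
#
# The rs-FCSM score is the Z-standardization of CDI against the reference
# cohort's own CDI distribution:
#   Z_{s,i} = (CDI_{s,i} - mean_CDI_i) / std_CDI_i
# with the columnwise mean and sample (N-1) standard deviation taken over
# the reference cohort.  Higher Z means a larger deviation of region i's
# connectivity profile from the young reference.

# Region profiles of a cohort, one slice per region: returns an
# R-element list of n_subjects x (R-1) matrices with rows centered and
# scaled to unit norm, so that profile Pearson correlations are row inner
# products.
normalized_profiles <- function(fc_list) {
  R <- nrow(fc_list[[1L]])
  n <- length(fc_list)
  arr <- array(unlist(lapply(fc_list, unclass), use.names = FALSE),
               dim = c(R, R, n))
  lapply(seq_len(R), function(i) {
    P <- t(arr[i, -i, , drop = TRUE])       # n x (R-1)
    if (n == 1L) P <- matrix(arr[i, -i, 1L], nrow = 1L)
    Pc <- P - rowMeans(P)
    nrm <- sqrt(rowSums(Pc^2))
    if (any(nrm == 0)) {
      bad <- which(nrm == 0)[1L]
      id <- attr(fc_list[[bad]], "subject_id")
      stop("constant connectivity profile for region ", i,
           " (subject ", id, "); profile correlation undefined",
           call. = FALSE)
    }
    Pc / nrm
  })
}

#' Connectome distinctiveness index for one subject
#'
#' @param fc The subject's `fc_matrix`.
#' @param reference List of reference-cohort `fc_matrix` objects (size
#'   N >= 2, same region count).
#' @return Numeric length-R vector of CDI values, named by region when the
#'   matrix carries region names.
#' @examples
#' ts <- lapply(1:4, function(i) matrix(rnorm(200), 50, 4))
#' ref <- lapply(seq_along(ts), function(i)
#'   pearson_fc(roi_timeseries(ts[[i]], paste0("y", i))))
#' cdi_subject(ref[[1]], ref)
#' @export
cdi_subject <- function(fc, reference) {
  cdi_matrix(list(fc), reference)[1L, ]
}

#' Connectome distinctiveness index for a cohort
#'
#' Computes `CDI_{s,i}` for every subject in `fc_list` against the
#' reference cohort.  When a subject appears in the reference (the
#' reference cohort scored against itself), its self term contributes 0 by
#' construction; no special casing is applied.
#'
#' @param fc_list List of `fc_matrix` objects to score.
#' @param reference List of reference-cohort `fc_matrix` objects (N >= 2).
#' @return Subjects x regions numeric matrix of CDI values; rows named by
#'   subject id.
#' @export
cdi_matrix <- function(fc_list, reference) {
  N <- length(reference)
  if (N < 2L) {
    stop("reference cohort must contain at least 2 subjects, got ", N,
         call. = FALSE)
  }
  R <- nrow(fc_list[[1L]])
  if (!all(vapply(c(fc_list, reference), nrow, 0L) == R)) {
    stop("all FC matrices must share the same region count", call. = FALSE)
  }
  subj_prof <- normalized_profiles(fc_list)
  ref_prof <- normalized_profiles(reference)
  out <- matrix(NA_real_, length(fc_list), R)
  for (i in seq_len(R)) {
    corr <- tcrossprod(subj_prof[[i]], ref_prof[[i]])  # n_subj x N
    out[, i] <- (N - rowSums(corr)) / (N - 1)
  }
  ids <- vapply(fc_list, function(m) {
    id <- attr(m, "subject_id")
    if (is.null(id)) NA_character_ else id
  }, "")
  if (!anyNA(ids)) rownames(out) <- unname(ids)
  labels <- rownames(fc_list[[1L]])
  if (!is.null(labels)) colnames(out) <- labels
  out
}

#' Reference-cohort CDI distribution
#'
#' Columnwise mean and sample (N-1) standard deviation of the reference
#' cohort's CDI matrix, the normalization constants of the rs-FCSM score.
#'
#' @param youth_cdi Reference-cohort subjects x regions CDI matrix (from
#'   [cdi_matrix()] of the youth cohort against itself).
#' @param sd_floor Optional strictly positive lower bound substituted for a
#'   zero standard deviation.  Default `NULL`: a degenerate reference
#'   (any region with zero CDI spread) is an error, because the Z score is
#'   undefined there.
#' @return List with numeric length-R vectors `mean_cdi` and `std_cdi`.
#' @export
reference_stats <- function(youth_cdi, sd_floor = NULL) {
  youth_cdi <- as.matrix(youth_cdi)
  if (nrow(youth_cdi) < 2L) {
    stop("reference cohort must contain at least 2 subjects", call. = FALSE)
  }
  mean_cdi <- colMeans(youth_cdi)
  std_cdi <- apply(youth_cdi, 2L, stats::sd)
  if (any(std_cdi == 0)) {
    if (is.null(sd_floor)) {
      bad <- which(std_cdi == 0)
      nm <- colnames(youth_cdi)[bad]
      if (is.null(nm)) nm <- paste0("region ", bad)
      stop("degenerate reference: zero CDI standard deviation for ",
           paste(utils::head(nm, 5L), collapse = ", "),
           "; Z scores are undefined (set sd_floor to override)",
           call. = FALSE)
    }
    stopifnot(sd_floor > 0)
    std_cdi[std_cdi == 0] <- sd_floor
  }
  list(mean_cdi = mean_cdi, std_cdi = std_cdi)
}

#' rs-FCSM Z scores
#'
#' Standardizes a CDI matrix against the reference-cohort distribution:
#' `Z_{s,i} = (CDI_{s,i} - mean_CDI_i) / std_CDI_i`.
#'
#' @param cdi Subjects x regions CDI matrix.
#' @param stats Reference statistics from [reference_stats()].
#' @return Subjects x regions matrix of Z scores.
#' @export
z_scores <- function(cdi, stats) {
  cdi <- as.matrix(cdi)
  if (ncol(cdi) != length(stats$mean_cdi)) {
    stop("CDI matrix has ", ncol(cdi), " regions but reference stats have ",
         length(stats$mean_cdi), call. = FALSE)
  }
  sweep(sweep(cdi, 2L, stats$mean_cdi, "-"), 2L, stats$std_cdi, "/")
}

#' Full rs-FCSM scoring of a study
#'
#' Convenience wrapper: scores every cohort against the youth reference.
#' The youth cohort is scored against itself (its Z columns then have mean
#' 0 and sample standard deviation 1 by construction).
#'
#' @param fc_by_cohort Named list with elements `youth`, `older_excellent`,
#'   `older_poor` (the last two optional), each a list of `fc_matrix`
#'   objects.
#' @param sd_floor Passed to [reference_stats()].
#' @return List with `z` (named list of Z-score matrices per cohort),
#'   `cdi` (CDI matrices per cohort) and `reference` (the youth
#'   [reference_stats()]).
#' @export
fcsm_scores <- function(fc_by_cohort, sd_floor = NULL) {
  if (!"youth" %in% names(fc_by_cohort)) {
    stop("fc_by_cohort must contain a 'youth' reference cohort",
         call. = FALSE)
  }
  youth <- fc_by_cohort$youth
  cdi <- lapply(fc_by_cohort, cdi_matrix, reference = youth)
  ref <- reference_stats(cdi$youth, sd_floor = sd_floor)
  z <- lapply(cdi, z_scores, stats = ref)
  list(z = z, cdi = cdi, reference = ref)
}
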