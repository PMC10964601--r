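#' Region atlas
#'
#' A parcellation atlas is an ordered list of region labels.  Region order is
#' a study-wide contract: every time-series table, FC matrix and score table
#' must use the same order, and all user-facing output is labelled 1-based
#' (AAL numbering, e.g. region 40 = `ParaHippocampal_R`).
#'
#' @param labels Character vector of unique region names, in atlas order.
#' @return An object of class `region_atlas` with fields `n_regions` and
#'   `labels`.
#' @examples
#' atlas <- region_atlas(c("A", "B", "C"))
#' atlas$n_regions
#' @export
region_atlas <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) {
    stop("atlas must contain at least one region", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1L]
    stop("atlas labels must be unique; duplicated label: ", dup,
         call. = FALSE)
  }
  structure(
    list(n_regions = length(labels), labels = labels),
    class = "region_atlas"
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", x$n_regions, " regions: ",
      x$labels[1L], " ... ", x$labels[x$n_regions], "\n", sep = "")
  invisible(x)
}

#' The AAL-116 atlas
#'
#' The Automated Anatomical Labeling parcellation (version 1), 116 regions in
#' the conventional numbering (odd indices left hemisphere, even indices
#' right, cerebellum and vermis last).
#'
#' @return A `region_atlas` with 116 regions.
#' @export
aal116_atlas <- function() {
  path <- system.file("extdata", "aal116_labels.txt", package = "rsfcsm",
                      mustWork = TRUE)
  read_atlas(path)
}

#' Read an atlas from a one-column text file of region names
#'
#' @param path Path to a plain-text file, one region label per line.
#' @return A `region_atlas`.
#' @export
read_atlas <- function(path) {
  labels <- readLines(path, warn = FALSE)
  labels <- trimws(labels)
  labels <- labels[nzchar(labels)]
  region_atlas(labels)
}

#' Default atlas for a given region count
#'
#' Returns the AAL-116 atlas when `n_regions` is 116, otherwise generic
#' `Region_001 ...` labels (used by the synthetic generator at reduced
#' sizes).
#'
#' @param n_regions Number of regions.
#' @return A `region_atlas`.
#' @export
default_atlas <- function(n_regions) {
  if (n_regions == 116L) {
    aal116_atlas()
  } else {
    region_atlas(sprintf("Region_%03d", seq_len(n_regions)))
  }
}
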