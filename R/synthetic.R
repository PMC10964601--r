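# Synthetic two-site, three-cohort study generator.
#
# Youth subjects are drawn from a common latent-factor ("network")
# covariance with per-subject loading jitter.  Older subjects share that
# structure except at two kinds of regions:
#   * planted biomarker regions: the region's latent loadings are rotated
#     toward a fixed alternative direction by a near-constant magnitude,
#     larger in the poor-cognition cohort (a consistent, cognition-linked
#     deviation from the young connectome);
#   * dispersion regions: both older cohorts deviate with a random
#     per-subject direction and magnitude (aging-related between-subject
#     heterogeneity carrying no cognition signal).  These populate the
#     high-Sum_std tail that the dual selection rule is designed to
#     reject, mirroring the partially overlapping top-10% sets seen in
#     real data.
# Site effects emulate the two-database setting (a "GSP"-like youth site
# and a "LEiDA"-like older site): in matrix mode, per-connection additive
# offsets and multiplicative scalings applied to the FC values; in
# time-series mode, site-specific latent signal mixed into the series.

#' Configuration of a synthetic two-site cohort
#'
#' Defaults emulate the study layout of the real two-database setting: 116
#' AAL regions, 150 timepoints, 90 youth at a "GSP" site, 55
#' excellent-cognition and 43 poor-cognition older subjects at a "LEiDA"
#' site, 6 planted biomarker regions whose connectivity profiles deviate
#' from the youth covariance with magnitude 0.1 (excellent) and 0.5
#' (poor), and 12 cognition-independent dispersion regions.
#'
#' @param n_regions Number of parcels (default 116; tests use 20-30).
#' @param n_timepoints BOLD series length (default 150).
#' @param n_youth,n_excellent,n_poor Cohort sizes (defaults 90/55/43).
#' @param n_networks Number of latent "resting-state networks" in the
#'   shared covariance (default 8).
#' @param planted_regions 1-based indices of regions carrying the cohort
#'   effect.  Default: for 116 regions, the parahippocampal / lingual /
#'   mid-occipital / mid-temporal set `c(40, 47, 51, 52, 86, 87)`;
#'   otherwise 6 evenly spaced regions.
#' @param effect_excellent,effect_poor Profile rotation magnitudes in
#'   `[0, 1]` for the two older cohorts (defaults 0.1 and 0.5; the poor
#'   cohort deviates more by construction).
#' @param dispersion_regions 1-based indices of aging-dispersion regions;
#'   default 12 regions spread over the atlas, disjoint from
#'   `planted_regions`.  Set to `integer(0)` to disable.
#' @param effect_dispersion Mean per-subject rotation magnitude at
#'   dispersion regions (default 0.4, per-subject sd 0.2, random
#'   direction, identical distribution in both older cohorts).
#' @param site_additive Scale of per-connection additive site offsets
#'   (default 0.1).
#' @param site_multiplicative Log-scale of per-connection multiplicative
#'   site scalings (default 0.1).
#' @param noise_sd Per-subject jitter of the shared network loadings
#'   (default 0.1).
#' @param sites Length-2 character vector naming the youth and older
#'   sites.
#' @param seed Integer seed; mandatory, the generator is fully
#'   deterministic given the config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_regions = 116L, n_timepoints = 150L,
                              n_youth = 90L, n_excellent = 55L,
                              n_poor = 43L, n_networks = 8L,
                              planted_regions = NULL,
                              effect_excellent = 0.1, effect_poor = 0.5,
                              dispersion_regions = NULL,
                              effect_dispersion = 0.4,
                              site_additive = 0.1,
                              site_multiplicative = 0.1,
                              noise_sd = 0.1,
                              sites = c("GSP", "LEiDA"),
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(planted_regions)) {
    planted_regions <- if (n_regions == 116L) {
      c(40L, 47L, 51L, 52L, 86L, 87L)
    } else {
      unique(round(seq(2L, n_regions - 1L, length.out = 6L)))
    }
  }
  planted_regions <- sort(as.integer(planted_regions))
  if (any(planted_regions < 1L | planted_regions > n_regions)) {
    stop("planted_regions out of range 1..", n_regions, call. = FALSE)
  }
  if (is.null(dispersion_regions)) {
    pool <- setdiff(seq_len(n_regions), planted_regions)
    n_disp <- min(12L, max(0L, length(pool) - 6L))
    dispersion_regions <- pool[unique(round(
      seq(1L, length(pool), length.out = n_disp)))]
  }
  dispersion_regions <- sort(as.integer(dispersion_regions))
  if (length(intersect(dispersion_regions, planted_regions))) {
    stop("dispersion_regions must be disjoint from planted_regions",
         call. = FALSE)
  }
  if (any(dispersion_regions < 1L | dispersion_regions > n_regions)) {
    stop("dispersion_regions out of range 1..", n_regions, call. = FALSE)
  }
  if (min(n_youth, n_excellent, n_poor) < 2L) {
    stop("every cohort needs at least 2 subjects", call. = FALSE)
  }
  stopifnot(n_timepoints >= 3L, n_regions >= 4L,
            effect_excellent >= 0, effect_poor >= 0,
            effect_dispersion >= 0, length(sites) == 2L)
  structure(
    list(n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         n_youth = as.integer(n_youth),
         n_excellent = as.integer(n_excellent),
         n_poor = as.integer(n_poor),
         n_networks = as.integer(n_networks),
         planted_regions = planted_regions,
         effect_excellent = effect_excellent,
         effect_poor = effect_poor,
         dispersion_regions = dispersion_regions,
         effect_dispersion = effect_dispersion,
         site_additive = site_additive,
         site_multiplicative = site_multiplicative,
         noise_sd = noise_sd,
         sites = as.character(sites),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Ground truth of a simulation config
#'
#' @param config A [simulation_config()].
#' @return List with `planted_regions` (1-based indices of the
#'   cognition-linked biomarker regions), `dispersion_regions`,
#'   `cohorts` (per-subject cohort labels in generation order) and
#'   `sites` (per-subject site labels).
#' @export
ground_truth <- function(config) {
  cohorts <- c(rep("youth", config$n_youth),
               rep("older_excellent", config$n_excellent),
               rep("older_poor", config$n_poor))
  sites <- c(rep(config$sites[1L], config$n_youth),
             rep(config$sites[2L], config$n_excellent + config$n_poor))
  list(planted_regions = config$planted_regions,
       dispersion_regions = config$dispersion_regions,
       cohorts = cohorts, sites = sites)
}

# base loadings: each region loads on one network plus small cross-talk
base_loadings <- function(R, k) {
  network <- rep(seq_len(k), length.out = R)
  B <- matrix(stats::rnorm(R * k, 0, 0.08), R, k)
  B[cbind(seq_len(R), network)] <- stats::runif(R, 0.6, 0.9)
  B
}

# rotate a loading row toward a unit direction u by magnitude m,
# preserving its norm
rotate_row <- function(row, u, m) {
  m <- min(max(m, 0), 1)
  nrm <- sqrt(sum(row^2))
  sqrt(1 - m^2) * row + m * nrm * u
}

#' Generate a synthetic two-site cohort
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory; when given, per-subject data
#'   files (TSV) and a `manifest.csv` are written there and the manifest's
#'   `path` column points at them.
#' @param mode `"matrix"` (default): emit FC matrices directly, with exact
#'   per-connection affine site effects — fast, used by unit tests.
#'   `"timeseries"`: emit BOLD-like series; the pipeline then computes FC
#'   itself, and site effects enter through site-specific latent signal.
#' @return List with `manifest` (a `cohort_manifest`), `data` (named list
#'   of `fc_matrix` or `roi_timeseries` objects, one per subject),
#'   `config`, `truth` (the [ground_truth()]) and `mode`.
#' @export
generate_cohort <- function(config, out_dir = NULL,
                            mode = c("matrix", "timeseries")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "simulation_config"))
  R <- config$n_regions
  k <- config$n_networks
  Tn <- config$n_timepoints
  atlas <- default_atlas(R)
  truth <- ground_truth(config)

  set.seed(config$seed)
  B <- base_loadings(R, k)
  unique_sd <- 0.7
  # each planted region is re-wired toward a different network: the
  # alternative direction is that network's axis, orthogonalized against
  # the region's own base loadings so the rotation angle is comparable
  # across planted regions
  network_of <- rep(seq_len(k), length.out = R)
  U <- lapply(config$planted_regions, function(r) {
    u <- numeric(k)
    u[(network_of[r] + floor(k / 2) - 1L) %% k + 1L] <- 1
    b <- B[r, ]
    u <- u - b * sum(u * b) / sum(b^2)
    u / sqrt(sum(u^2))
  })
  names(U) <- as.character(config$planted_regions)

  nC <- n_connections(R)
  site_add <- rbind(rep(0, nC),
                    stats::rnorm(nC, 0, config$site_additive))
  site_mult <- rbind(rep(1, nC),
                     exp(stats::rnorm(nC, 0, config$site_multiplicative)))
  rownames(site_add) <- rownames(site_mult) <- config$sites
  # site-specific latent signal weights (time-series mode)
  site_w <- rbind(rep(0, R),
                  stats::rnorm(R, 0, config$site_additive))
  rownames(site_w) <- config$sites

  n_total <- config$n_youth + config$n_excellent + config$n_poor
  ids <- c(sprintf("%s_Y%03d", config$sites[1L], seq_len(config$n_youth)),
           sprintf("%s_E%03d", config$sites[2L],
                   seq_len(config$n_excellent)),
           sprintf("%s_P%03d", config$sites[2L], seq_len(config$n_poor)))
  effect_of <- c(youth = 0, older_excellent = config$effect_excellent,
                 older_poor = config$effect_poor)

  data <- vector("list", n_total)
  names(data) <- ids
  for (s in seq_len(n_total)) {
    cohort <- truth$cohorts[s]
    site <- truth$sites[s]
    # shared network loadings with per-subject jitter
    A <- B + config$noise_sd * matrix(stats::rnorm(R * k), R, k)
    eff <- effect_of[[cohort]]
    if (eff > 0) {
      for (r in config$planted_regions) {
        # small magnitude jitter: the cohort effect is a consistent shift,
        # not extra within-cohort dispersion
        m <- eff + stats::rnorm(1L, 0, 0.05 * eff)
        A[r, ] <- rotate_row(A[r, ], U[[as.character(r)]], m)
      }
    }
    if (cohort != "youth" && length(config$dispersion_regions)) {
      for (r in config$dispersion_regions) {
        # aging heterogeneity: random direction and magnitude per subject,
        # same distribution in both older cohorts
        m <- stats::rnorm(1L, config$effect_dispersion, 0.2)
        u <- stats::rnorm(k)
        u <- u / sqrt(sum(u^2))
        A[r, ] <- rotate_row(A[r, ], u, m)
      }
    }
    Z <- matrix(stats::rnorm(Tn * k), Tn, k)
    X <- Z %*% t(A) + unique_sd * matrix(stats::rnorm(Tn * R), Tn, R)
    if (mode == "timeseries") {
      g <- stats::rnorm(Tn)
      X <- X + g %*% t(site_w[site, ])
      data[[s]] <- roi_timeseries(X, subject_id = ids[s], atlas = atlas)
    } else {
      fc <- pearson_fc(roi_timeseries(X, subject_id = ids[s],
                                      atlas = atlas))
      v <- vectorize_upper(fc)
      v <- v * site_mult[site, ] + site_add[site, ]
      m <- devectorize(v, R, subject_id = ids[s])
      dimnames(m) <- list(atlas$labels, atlas$labels)
      data[[s]] <- m
    }
  }

  mf <- data.frame(subject_id = ids, site = truth$sites,
                   cohort = truth$cohorts,
                   path = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (mode == "matrix") "_fc.tsv" else "_ts.tsv"
    mf$path <- file.path(out_dir, paste0(ids, ext))
    for (s in seq_len(n_total)) {
      if (mode == "matrix") {
        write_fc_matrix(data[[s]], mf$path[s])
      } else {
        utils::write.table(unclass(data[[s]]), mf$path[s], sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    }
    utils::write.csv(mf, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  manifest <- cohort_manifest(mf, check_paths = !is.null(out_dir))
  list(manifest = manifest, data = data, config = config, truth = truth,
       mode = mode)
}
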