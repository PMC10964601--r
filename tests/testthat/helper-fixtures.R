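# Shared fixtures, all generated in code.

# random valid FC matrix from an actual time series (guarantees a proper
# correlation structure)
random_fc <- function(R = 6L, Tn = 60L, subject_id = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(Tn * R), Tn, R)
  pearson_fc(roi_timeseries(x, subject_id = subject_id))
}

# list of random FC matrices
random_fc_list <- function(n, R = 6L, Tn = 60L, prefix = "s", seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- matrix(rnorm(Tn * R), Tn, R)
    pearson_fc(roi_timeseries(x, subject_id = paste0(prefix, i)))
  })
}

# symmetric matrix with unit diagonal and prescribed first-row profile;
# remaining off-diagonal entries get fixed non-constant filler so every
# region's profile has variance
fc_with_profile <- function(profile) {
  R <- length(profile) + 1L
  m <- diag(R)
  filler <- seq(0.05, 0.30, length.out = R * (R - 1L) / 2L)
  m[lower.tri(m)] <- filler
  m <- t(m)
  m[lower.tri(m)] <- filler
  diag(m) <- 1
  m[1L, -1L] <- profile
  m[-1L, 1L] <- profile
  fc_matrix(m, subject_id = "crafted")
}

# independent double-loop CDI oracle, straight from the definition
cdi_oracle <- function(fc_list, reference) {
  N <- length(reference)
  R <- nrow(fc_list[[1L]])
  out <- matrix(NA_real_, length(fc_list), R)
  for (s in seq_along(fc_list)) {
    for (i in seq_len(R)) {
      f_s <- unclass(fc_list[[s]])[i, -i]
      total <- 0
      for (p in seq_len(N)) {
        f_p <- unclass(reference[[p]])[i, -i]
        total <- total + (1 - cor(f_s, f_p))
      }
      out[s, i] <- total / (N - 1)
    }
  }
  out
}

# small quick simulation config for unit tests
test_sim_config <- function(seed, ...) {
  defaults <- list(n_regions = 20L, n_timepoints = 100L, n_youth = 15L,
                   n_excellent = 10L, n_poor = 10L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
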