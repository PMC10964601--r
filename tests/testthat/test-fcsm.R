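test_that("a subject identical to every reference has zero CDI", {
  fcs <- random_fc_list(4, R = 6L, seed = 31L)
  ref <- rep(fcs[1], 4)
  cdi <- cdi_subject(fcs[[1]], ref)
  expect_equal(unname(cdi), rep(0, 6), tolerance = 1e-12)
})

test_that("CDI sums N terms but divides by N - 1, as defined", {
  # reference profiles crafted to correlate 1.0, 0.5, 0.0 with the
  # subject profile at region 1: CDI_1 = (0 + 0.5 + 1.0) / 2 = 0.75
  subj <- fc_with_profile(c(1, 0, -1) / 2)
  ref <- list(fc_with_profile(c(1, 0, -1) / 2),
              fc_with_profile(c(1, -1, 0) / 2),
              fc_with_profile(c(1, -2, 1) / 4))
  expect_equal(cor(c(1, 0, -1), c(1, -1, 0)), 0.5)
  expect_equal(cor(c(1, 0, -1), c(1, -2, 1)), 0)
  cdi <- cdi_subject(subj, ref)
  expect_equal(unname(cdi[1]), 0.75, tolerance = 1e-12)
})

test_that("vectorized CDI equals the naive double-loop oracle", {
  set.seed(32)
  for (case in list(c(R = 6L, N = 4L), c(R = 15L, N = 8L),
                    c(R = 30L, N = 20L))) {
    subj <- random_fc_list(5, R = case[["R"]], seed = case[["R"]])
    ref <- random_fc_list(case[["N"]], R = case[["R"]],
                          seed = case[["R"]] + 100L)
    fast <- cdi_matrix(subj, ref)
    slow <- cdi_oracle(subj, ref)
    expect_lt(max(abs(fast - slow)), 1e-12)
  }
})

test_that("a reference subject's self term contributes nothing", {
  ref <- random_fc_list(5, R = 8L, seed = 33L)
  cdi_with_self <- cdi_matrix(ref[1], ref)
  # manually drop the self term: sum over the other 4, same divisor N-1=4
  others <- cdi_oracle(ref[1], ref[-1]) * (3 / 4)  # rescale divisor 3 -> 4
  expect_equal(unname(cdi_with_self), unname(others), tolerance = 1e-12)
})

test_that("reference stats use the sample (N-1) standard deviation", {
  youth <- matrix(c(1, 2, 3, 4, 6, 8), 3, 2)
  st <- reference_stats(youth)
  expect_equal(st$mean_cdi, c(2, 6))
  expect_equal(st$std_cdi, c(1, 2))

  one_pass <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  set.seed(34)
  big <- matrix(runif(90 * 116), 90, 116)
  st2 <- reference_stats(big)
  expect_lt(max(abs(st2$std_cdi - apply(big, 2, one_pass))), 1e-10)
})

test_that("a degenerate reference is an error unless floored", {
  youth <- matrix(1, 4, 3)
  expect_error(reference_stats(youth), "degenerate reference")
  st <- reference_stats(youth, sd_floor = 1e-6)
  expect_equal(st$std_cdi, rep(1e-6, 3))
})

test_that("z_scores is the plain standardization", {
  st <- list(mean_cdi = c(2, 2), std_cdi = c(1, 1))
  expect_equal(as.numeric(z_scores(matrix(c(2, 3.5), 1), st)),
               c(0, 1.5))
  expect_error(z_scores(matrix(0, 1, 3), st), "3 regions")
})

test_that("the youth cohort standardizes itself to mean 0, sd 1", {
  cfg <- test_sim_config(seed = 35L)
  sim <- generate_cohort(cfg)
  youth <- sim$data[sim$manifest$cohort == "youth"]
  cdi <- cdi_matrix(youth, youth)
  z <- z_scores(cdi, reference_stats(cdi))
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
})

test_that("CDI is invariant to positive affine transforms of all profiles", {
  subj <- random_fc_list(3, R = 8L, seed = 36L)
  ref <- random_fc_list(5, R = 8L, seed = 37L)
  rescale <- function(m) {
    v <- unclass(m) * 0.37 + 0.11
    structure(v, subject_id = attr(m, "subject_id"), class = "fc_matrix")
  }
  cdi1 <- cdi_matrix(subj, ref)
  cdi2 <- cdi_matrix(lapply(subj, rescale), lapply(ref, rescale))
  expect_lt(max(abs(cdi1 - cdi2)), 1e-12)
})

test_that("expected Z rises monotonically with perturbation magnitude", {
  mags <- c(0, 0.15, 0.3, 0.45, 0.6)
  mean_z <- vapply(seq_along(mags), function(i) {
    cfg <- test_sim_config(seed = 38L, effect_poor = mags[i],
                           effect_excellent = 0,
                           dispersion_regions = integer(0),
                           site_additive = 0, site_multiplicative = 0)
    sim <- generate_cohort(cfg)
    by <- split(sim$data, sim$manifest$cohort)
    sc <- fcsm_scores(by)
    mean(sc$z$older_poor[, cfg$planted_regions])
  }, 0)
  expect_gt(cor(mags, mean_z, method = "spearman"), 0.9)
})

test_that("older subjects from the youth distribution score like youth", {
  cfg <- test_sim_config(seed = 39L, effect_poor = 0, effect_excellent = 0,
                         dispersion_regions = integer(0),
                         site_additive = 0, site_multiplicative = 0,
                         n_youth = 30L, n_excellent = 25L, n_poor = 25L)
  sim <- generate_cohort(cfg)
  by <- split(sim$data, sim$manifest$cohort)
  sc <- fcsm_scores(by)
  ks <- stats::ks.test(as.numeric(sc$z$youth),
                       as.numeric(rbind(sc$z$older_excellent,
                                        sc$z$older_poor)))
  expect_gt(ks$p.value, 0.01)
})
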