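test_that("the generator is deterministic given its seed", {
  cfg <- test_sim_config(seed = 61L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$manifest, b$manifest)
  c <- generate_cohort(test_sim_config(seed = 62L))
  expect_false(identical(a$data, c$data))
})

test_that("ground truth matches the config", {
  cfg <- simulation_config(seed = 63L)
  gt <- ground_truth(cfg)
  expect_length(gt$planted_regions, 6L)
  expect_identical(gt$planted_regions, c(40L, 47L, 51L, 52L, 86L, 87L))
  expect_equal(table(gt$cohorts)[["youth"]], 90L)
  expect_equal(table(gt$sites)[["LEiDA"]], 98L)
  expect_length(intersect(gt$planted_regions, gt$dispersion_regions), 0L)
})

test_that("null effects leave older cohorts indistinguishable from youth", {
  cfg <- test_sim_config(seed = 64L, effect_excellent = 0, effect_poor = 0,
                         dispersion_regions = integer(0),
                         site_additive = 0, site_multiplicative = 0,
                         n_youth = 30L)
  sim <- generate_cohort(cfg)
  sc <- fcsm_scores(split(sim$data, sim$manifest$cohort))
  ks <- stats::ks.test(as.numeric(sc$z$youth),
                       as.numeric(sc$z$older_poor))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted regions carry the strongest poor-cohort deviation", {
  gaps <- vapply(71:73, function(s) {
    cfg <- test_sim_config(seed = s, site_additive = 0,
                           site_multiplicative = 0)
    sim <- generate_cohort(cfg)
    sc <- fcsm_scores(split(sim$data, sim$manifest$cohort))
    p <- cfg$planted_regions
    rest <- setdiff(seq_len(cfg$n_regions),
                    c(p, cfg$dispersion_regions))
    mean(sc$z$older_poor[, p]) - mean(sc$z$older_poor[, rest])
  }, 0)
  expect_true(all(gaps > 1))
})

test_that("written cohorts reload through the manifest identically", {
  dir <- withr::local_tempdir()
  cfg <- test_sim_config(seed = 65L, n_youth = 4L, n_excellent = 3L,
                         n_poor = 3L, n_regions = 8L)
  sim <- generate_cohort(cfg, out_dir = dir)
  mf <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(mf), 10L)
  fc <- read_fc_matrix(mf$path[1], subject_id = mf$subject_id[1])
  expect_lt(max(abs(unclass(fc) - unclass(sim$data[[mf$subject_id[1]]]))),
            1e-12)
})

test_that("time-series mode feeds the FC stage directly", {
  cfg <- test_sim_config(seed = 66L, n_youth = 3L, n_excellent = 2L,
                         n_poor = 2L, n_regions = 10L)
  sim <- generate_cohort(cfg, mode = "timeseries")
  expect_s3_class(sim$data[[1]], "roi_timeseries")
  expect_equal(dim(sim$data[[1]]), c(100L, 10L))
  fc <- pearson_fc(sim$data[[1]])
  expect_equal(dim(fc), c(10L, 10L))
})

test_that("site effects are detectable before ComBat and removed after", {
  cfg <- test_sim_config(seed = 67L, site_additive = 0.15,
                         site_multiplicative = 0.15,
                         effect_excellent = 0, effect_poor = 0,
                         dispersion_regions = integer(0),
                         n_youth = 30L, n_excellent = 15L, n_poor = 15L)
  sim <- generate_cohort(cfg)
  vectors <- t(vapply(sim$data, vectorize_upper,
                      numeric(n_connections(cfg$n_regions))))
  sites <- sim$manifest$site
  gap_before <- abs(colMeans(vectors[sites == "GSP", ]) -
                      colMeans(vectors[sites == "LEiDA", ]))
  adj <- harmonize_vectors(vectors, sites)$adjusted
  gap_after <- abs(colMeans(adj[sites == "GSP", ]) -
                     colMeans(adj[sites == "LEiDA", ]))
  expect_gt(mean(gap_before), 5 * mean(gap_after))

  # a site classifier is near-perfect before harmonization and cannot
  # beat chance afterwards (in-sample mean equalization typically drives
  # it below chance)
  y_site <- ifelse(sites == "GSP", 2L, 1L)
  acc_before <- cross_validate(vectors, y_site, n_folds = 5L,
                               n_hidden = 200L,
                               seed = 1L)$summary$accuracy[["mean"]]
  acc_after <- cross_validate(adj, y_site, n_folds = 5L, n_hidden = 200L,
                              seed = 1L)$summary$accuracy[["mean"]]
  expect_gt(acc_before, 90)
  expect_lt(acc_after, 60)
})

test_that("config validation rejects impossible layouts", {
  expect_error(simulation_config(seed = 1, n_regions = 10L,
                                 planted_regions = c(2L, 11L)),
               "out of range")
  expect_error(simulation_config(seed = 1, n_youth = 1L),
               "at least 2")
  expect_error(simulation_config(n_regions = 10L), "seed is mandatory")
  expect_error(simulation_config(seed = 1, planted_regions = 2L,
                                 dispersion_regions = 2L),
               "disjoint")
})
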