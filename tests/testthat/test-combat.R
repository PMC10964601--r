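test_that("null two-site data yields near-identity site effects", {
  set.seed(101)
  C <- 200L
  Y <- matrix(rnorm(80 * C, 0.2, 0.3), 80, C)
  sites <- rep(c("a", "b"), each = 40)
  model <- fit_combat(Y, sites)
  sd_pooled <- sqrt(model$var_pooled)
  # gamma* on the data scale, delta* as a scale factor
  gamma_data <- sweep(model$gamma_star, 2L, sd_pooled, "*")
  delta <- sqrt(model$delta2_star)
  expect_gte(mean(abs(gamma_data) < 0.05), 0.95)
  expect_gte(mean(abs(delta - 1) < 0.1), 0.95)
})

test_that("a planted additive site offset is removed", {
  # the empirical-Bayes residual scales with within-site sampling noise,
  # so the check uses a well-powered design
  set.seed(102)
  C <- 300L
  Y <- matrix(rnorm(600 * C, 0, 0.05), 600, C)
  sites <- rep(c("a", "b"), each = 300)
  Y[sites == "b", ] <- Y[sites == "b", ] + 0.3
  adj <- harmonize_vectors(Y, sites)$adjusted
  gap <- colMeans(adj[sites == "a", ]) - colMeans(adj[sites == "b", ])
  expect_lt(max(abs(gap)), 0.02)
})

test_that("identity model leaves data untouched; Eq-style adjustment is literal", {
  Y <- matrix(rnorm(30), 5, 6)
  id_model <- structure(list(
    sites = c("a", "b"), n_per_site = c(a = 3L, b = 2L),
    n_connections = 6L, alpha = rep(0, 6), beta = NULL,
    covariate_names = NULL, var_pooled = rep(1, 6),
    gamma_star = matrix(0, 2, 6), delta2_star = matrix(1, 2, 6),
    passthrough = rep(FALSE, 6), eb = TRUE, n_iter = c(0L, 0L)),
    class = "combat_model")
  sites <- c("a", "a", "a", "b", "b")
  expect_equal(apply_combat(id_model, Y, sites), Y)

  # alpha = 0, beta = 0, gamma* = 0.5, delta* = 2 -> (y - 0.5) / 2
  shift_model <- id_model
  shift_model$gamma_star <- matrix(0.5, 2, 6)
  shift_model$delta2_star <- matrix(4, 2, 6)
  y <- matrix(rnorm(6), 1, 6)
  expect_equal(apply_combat(shift_model, y, "a"), (y - 0.5) / 2)
})

test_that("omitting covariates equals supplying an absent design", {
  set.seed(103)
  Y <- matrix(rnorm(200), 20, 10)
  sites <- rep(c("a", "b"), each = 10)
  a1 <- harmonize_vectors(Y, sites)$adjusted
  a2 <- harmonize_vectors(Y, sites, covariates = NULL)$adjusted
  expect_identical(a1, a2)
})

test_that("degenerate inputs are rejected or passed through as specified", {
  Y <- matrix(rnorm(40), 10, 4)
  expect_error(fit_combat(Y, rep("only", 10)), "one site")
  expect_error(fit_combat(Y, c(rep("a", 9), "b")), "fewer than 2")

  # zero-variance connection passes through unadjusted
  Y[, 2] <- 0.7
  sites <- rep(c("a", "b"), each = 5)
  expect_message(h <- harmonize_vectors(Y, sites), "passed through")
  expect_identical(h$adjusted[, 2], Y[, 2])
  expect_false(identical(h$adjusted[, 1], Y[, 1]))

  model <- h$model
  expect_error(apply_combat(model, Y, rep("c", 10)), "not seen at fit")

  # confounded covariate
  expect_error(
    fit_combat(Y[, -2], sites,
               covariates = cbind(x = as.numeric(sites == "a"))),
    "confounded")
})

test_that("adjustment agrees with the sva reference implementation", {
  set.seed(104)
  n1 <- 15L; n2 <- 12L; C <- 40L
  Y <- rbind(matrix(rnorm(n1 * C, 0, 1), n1),
             matrix(rnorm(n2 * C, 0.3, 1.5), n2))
  sites <- rep(c("a", "b"), c(n1, n2))
  mine <- harmonize_vectors(Y, sites)$adjusted
  ref <- t(suppressMessages(sva::ComBat(dat = t(Y), batch = sites)))
  expect_lt(max(abs(mine - ref)), 1e-6)

  x <- rnorm(n1 + n2)
  Y2 <- Y + outer(x, rnorm(C, 0.5, 0.2))
  mine2 <- harmonize_vectors(Y2, sites, covariates = cbind(x = x))$adjusted
  ref2 <- t(suppressMessages(
    sva::ComBat(dat = t(Y2), batch = sites,
                mod = stats::model.matrix(~x))))
  expect_lt(max(abs(mine2 - ref2)), 1e-6)
})

test_that("multiplicative site effects are equalized (variance ratios)", {
  set.seed(105)
  C <- 500L
  Y <- matrix(rnorm(300 * C, 0.1, 0.25), 300, C)
  sites <- rep(c("a", "b"), each = 150)
  Y[sites == "b", ] <- sweep(sweep(Y[sites == "b", ], 2,
                                   colMeans(Y[sites == "b", ]), "-") * 2,
                             2, colMeans(Y[sites == "b", ]), "+") + 0.3
  adj <- harmonize_vectors(Y, sites)$adjusted
  va <- apply(adj[sites == "a", ], 2, var)
  vb <- apply(adj[sites == "b", ], 2, var)
  ratio <- vb / va
  expect_gte(mean(ratio >= 0.8 & ratio <= 1.25), 0.95)
})

test_that("planted group differences survive cohort-protected adjustment", {
  set.seed(106)
  C <- 300L
  n <- 60L
  group <- rep(c(0, 1), each = n / 2)          # balanced across sites
  sites <- rep(c("a", "b"), times = n / 2)
  effect <- c(rep(0.4, 50), rep(0, C - 50))
  # site distortion hits the measurement; the biological effect is the
  # same at both sites
  Y <- matrix(rnorm(n * C, 0, 0.3), n, C)
  Y[sites == "b", ] <- Y[sites == "b", ] * 1.5 + 0.2
  Y <- Y + outer(group, effect)
  adj <- harmonize_vectors(Y, sites,
                           covariates = cbind(g = group))$adjusted
  es <- function(M) {
    (colMeans(M[group == 1, ]) - colMeans(M[group == 0, ]))[1:50] / 0.4
  }
  # effect attenuation under 15% on average
  expect_lt(abs(1 - mean(es(adj))), 0.15)
})

test_that("a fitted model survives a JSON round trip", {
  set.seed(107)
  Y <- matrix(rnorm(300), 20, 15)
  sites <- rep(c("a", "b"), each = 10)
  model <- fit_combat(Y, sites)
  path <- withr::local_tempfile(fileext = ".json")
  write_combat_model(model, path)
  model2 <- read_combat_model(path)
  expect_equal(apply_combat(model2, Y, sites),
               apply_combat(model, Y, sites), tolerance = 1e-12)
})
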