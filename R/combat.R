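# Location/scale batch harmonization of connection vectors across
# acquisition sites, with parametric empirical-Bayes shrinkage of the
# per-site effects (normal prior on the additive effect gamma, inverse-gamma
# prior on the squared multiplicative effect delta^2, method-of-moments
# hyperparameters, iterative conditional updates).
#
# The adjustment applied to subject j at site i, connection v is
#   y_adj = (y - alpha_v - X beta_v - gamma*_iv) / delta*_iv
#           + alpha_v + X beta_v
# where gamma* and delta* are the empirical-Bayes site effects expressed on
# the data scale (internally they are estimated on data standardized by the
# pooled residual standard deviation, as in the standard procedure).

#' Fit a ComBat harmonization model on connection vectors
#'
#' Estimates per-connection additive and multiplicative site effects across
#' two or more acquisition sites and shrinks them with parametric
#' empirical Bayes.  Connections with zero variance across all subjects are
#' passed through unadjusted (and flagged in the returned model).
#'
#' @param vectors Subjects x connections numeric matrix (one row per
#'   subject; for FC data, rows are [vectorize_upper()] outputs).
#' @param sites Character or factor vector of per-subject site labels; at
#'   least 2 sites with at least 2 subjects each.
#' @param covariates Optional subjects x p numeric matrix (or data frame of
#'   numeric/factor columns, expanded via `model.matrix`) of biological
#'   covariates whose signal must be preserved.  Default none.
#' @param eb If `TRUE` (default) apply empirical-Bayes shrinkage; `FALSE`
#'   uses the per-site maximum-likelihood effects directly.
#' @param tol Convergence tolerance of the iterative conditional updates
#'   (maximum absolute change in the standardized site effects), default
#'   `1e-6`.
#' @param max_iter Iteration cap for the conditional updates.
#' @return An object of class `combat_model` holding, per connection, the
#'   grand intercept `alpha`, covariate coefficients `beta`, pooled
#'   residual variance `var_pooled`, and per-site shrunken effects
#'   `gamma_star` (additive) and `delta2_star` (squared multiplicative,
#'   strictly positive).
#' @export
fit_combat <- function(vectors, sites, covariates = NULL, eb = TRUE,
                       tol = 1e-6, max_iter = 1000L) {
  Y <- as.matrix(vectors)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  C <- ncol(Y)
  if (C < 1L) stop("need at least one connection", call. = FALSE)
  site <- factor(sites)
  if (length(site) != n) {
    stop("length(sites) must equal nrow(vectors)", call. = FALSE)
  }
  if (nlevels(site) < 2L) {
    stop("only one site present; harmonization is not applicable - ",
         "skip the harmonization step for single-site data", call. = FALSE)
  }
  ni <- as.integer(table(site))
  if (any(ni < 2L)) {
    small <- levels(site)[ni < 2L]
    stop("site(s) with fewer than 2 subjects: ",
         paste(small, collapse = ", "), call. = FALSE)
  }

  Xcov <- build_covariate_matrix(covariates, n)
  B <- stats::model.matrix(~ 0 + site)
  D <- cbind(B, Xcov)
  if (qr(D)$rank < ncol(D)) {
    stop("confounded design: covariates are collinear with site labels",
         call. = FALSE)
  }

  # features with no variance anywhere are passed through unadjusted
  passthrough <- apply(Y, 2L, function(col) stats::var(col) == 0)
  if (any(passthrough)) {
    message(sum(passthrough),
            " zero-variance connection(s) passed through unadjusted")
  }

  coef <- solve(crossprod(D), crossprod(D, Y))      # (I + p) x C
  I <- nlevels(site)
  site_coef <- coef[seq_len(I), , drop = FALSE]
  beta <- if (ncol(D) > I) coef[-seq_len(I), , drop = FALSE] else NULL

  alpha <- as.numeric(crossprod(ni / n, site_coef))  # weighted grand mean
  fitted <- D %*% coef
  var_pooled <- colMeans((Y - fitted)^2)             # divisor n, per Johnson
  sd_pooled <- sqrt(pmax(var_pooled, 0))
  active <- !passthrough & sd_pooled > 0

  # standardized data: remove grand mean and covariate effects, unit scale
  stand <- matrix(alpha, n, C, byrow = TRUE)
  if (!is.null(beta)) stand <- stand + Xcov %*% beta
  Z <- Y - stand
  Z[, active] <- sweep(Z[, active, drop = FALSE], 2L, sd_pooled[active], "/")

  gamma_hat <- matrix(0, I, C)
  delta2_hat <- matrix(1, I, C)
  for (i in seq_len(I)) {
    zi <- Z[site == levels(site)[i], active, drop = FALSE]
    gamma_hat[i, active] <- colMeans(zi)
    delta2_hat[i, active] <- apply(zi, 2L, stats::var)
  }

  if (eb) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    n_iter <- integer(I)
    for (i in seq_len(I)) {
      g <- gamma_hat[i, active]
      d2 <- delta2_hat[i, active]
      gbar <- mean(g)
      t2 <- stats::var(g)
      m <- mean(d2)
      s2 <- stats::var(d2)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      zi <- Z[site == levels(site)[i], active, drop = FALSE]
      n_i <- nrow(zi)
      g_new <- g
      d_new <- d2
      for (it in seq_len(max_iter)) {
        g_old <- g_new
        d_old <- d_new
        g_new <- (n_i * t2 * g + d_new * gbar) / (n_i * t2 + d_new)
        ss <- colSums(sweep(zi, 2L, g_new, "-")^2)
        d_new <- (b_prior + 0.5 * ss) / (n_i / 2 + a_prior - 1)
        if (max(abs(g_new - g_old), abs(d_new - d_old)) < tol) break
      }
      n_iter[i] <- it
      gamma_star[i, active] <- g_new
      delta2_star[i, active] <- d_new
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    n_iter <- integer(I)
  }
  if (any(delta2_star[, active] <= 0)) {
    stop("non-positive multiplicative site effect estimated; ",
         "data are degenerate within a site", call. = FALSE)
  }

  structure(
    list(
      sites = levels(site),
      n_per_site = stats::setNames(ni, levels(site)),
      n_connections = C,
      alpha = alpha,
      beta = beta,
      covariate_names = colnames(Xcov),
      var_pooled = var_pooled,
      gamma_star = gamma_star,
      delta2_star = delta2_star,
      passthrough = passthrough,
      eb = eb,
      n_iter = n_iter
    ),
    class = "combat_model"
  )
}

#' @export
print.combat_model <- function(x, ...) {
  cat("<combat_model> ", x$n_connections, " connections, sites: ",
      paste(sprintf("%s (n=%d)", x$sites, x$n_per_site), collapse = ", "),
      if (x$eb) "; empirical-Bayes shrinkage" else "; no shrinkage",
      "\n", sep = "")
  invisible(x)
}

build_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    X <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  } else {
    X <- as.matrix(covariates)
    storage.mode(X) <- "double"
  }
  if (nrow(X) != n) {
    stop("covariates must have one row per subject", call. = FALSE)
  }
  X
}

#' Apply a fitted ComBat model to connection vectors
#'
#' @param model A `combat_model` from [fit_combat()].
#' @param vectors Subjects x connections matrix with the same connection
#'   count the model was fitted on.
#' @param sites Per-subject site labels; every label must have been seen at
#'   fit time.
#' @param covariates Covariates matching those used at fit time (required if
#'   the model was fitted with covariates).
#' @return Adjusted matrix of the same shape as `vectors`.
#' @export
apply_combat <- function(model, vectors, sites, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  Y <- as.matrix(vectors)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  C <- ncol(Y)
  if (C != model$n_connections) {
    stop("model was fitted on ", model$n_connections,
         " connections, data has ", C, call. = FALSE)
  }
  site <- as.character(sites)
  unseen <- setdiff(unique(site), model$sites)
  if (length(unseen)) {
    stop("site label(s) not seen at fit time: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  Xcov <- build_covariate_matrix(covariates, n)
  if (is.null(Xcov) != is.null(model$beta)) {
    stop("covariates must match those used at fit time", call. = FALSE)
  }

  stand <- matrix(model$alpha, n, C, byrow = TRUE)
  if (!is.null(model$beta)) stand <- stand + Xcov %*% model$beta
  sd_pooled <- sqrt(pmax(model$var_pooled, 0))
  active <- !model$passthrough & sd_pooled > 0

  Z <- Y - stand
  Z[, active] <- sweep(Z[, active, drop = FALSE], 2L, sd_pooled[active], "/")
  out <- Y
  for (i in seq_along(model$sites)) {
    rows <- site == model$sites[i]
    if (!any(rows)) next
    zadj <- sweep(Z[rows, active, drop = FALSE], 2L,
                  model$gamma_star[i, active], "-")
    zadj <- sweep(zadj, 2L, sqrt(model$delta2_star[i, active]), "/")
    out[rows, active] <- sweep(zadj, 2L, sd_pooled[active], "*") +
      stand[rows, active, drop = FALSE]
  }
  dimnames(out) <- dimnames(Y)
  out
}

#' Fit and apply ComBat in one step
#'
#' @inheritParams fit_combat
#' @return A list with elements `adjusted` (harmonized subjects x
#'   connections matrix) and `model` (the fitted `combat_model`).
#' @export
harmonize_vectors <- function(vectors, sites, covariates = NULL, eb = TRUE,
                              tol = 1e-6) {
  model <- fit_combat(vectors, sites, covariates = covariates, eb = eb,
                      tol = tol)
  list(adjusted = apply_combat(model, vectors, sites,
                               covariates = covariates),
       model = model)
}

#' Persist a ComBat model as JSON
#'
#' @param model A `combat_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  obj <- unclass(model)
  obj$gamma_star <- as.data.frame(t(obj$gamma_star))
  names(obj$gamma_star) <- model$sites
  obj$delta2_star <- as.data.frame(t(obj$delta2_star))
  names(obj$delta2_star) <- model$sites
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ComBat model written by [write_combat_model()]
#'
#' @param path JSON path.
#' @return A `combat_model`.
#' @export
read_combat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$gamma_star <- t(as.matrix(obj$gamma_star))
  obj$delta2_star <- t(as.matrix(obj$delta2_star))
  dimnames(obj$gamma_star) <- NULL
  dimnames(obj$delta2_star) <- NULL
  obj$n_per_site <- stats::setNames(as.integer(obj$n_per_site), obj$sites)
  if (length(obj$beta) == 0L) obj$beta <- NULL else {
    obj$beta <- as.matrix(obj$beta)
  }
  if (length(obj$covariate_names) == 0L) obj$covariate_names <- NULL
  structure(obj, class = "combat_model")
}
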