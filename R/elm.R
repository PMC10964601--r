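# Extreme learning machine: a single-hidden-layer feed-forward network
# whose input weights and biases are drawn at random and never trained;
# only the linear readout is fitted, by least squares via the Moore-Penrose
# pseudoinverse.  Class coding follows the cognition labels: 1 = poor,
# 2 = excellent; the excellent class is the positive class in every
# reported metric.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train an extreme learning machine classifier
#'
#' Input weights are drawn Uniform(-1, 1) and hidden biases Uniform(0, 1)
#' from the seeded generator; hidden activations are logistic-sigmoid; the
#' readout solves the one-hot least-squares problem with the Moore-Penrose
#' pseudoinverse (no ridge term).  Features are standardized to the
#' training mean and standard deviation by default.
#'
#' @param features Subjects x d numeric matrix.
#' @param labels Integer class labels in `{1, 2}` (1 = poor, 2 =
#'   excellent); both classes must be present.
#' @param n_hidden Hidden-layer width, default 500.
#' @param seed Integer seed for the random input layer.
#' @param standardize Standardize features to training mean/sd (default
#'   `TRUE`).  Constant features get unit scale.
#' @return An object of class `elm_model`.
#' @export
elm_train <- function(features, labels, n_hidden = 500L, seed,
                      standardize = TRUE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.integer(labels)
  if (!all(y %in% c(1L, 2L))) {
    stop("labels must be coded 1 (poor) or 2 (excellent)", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (any(!is.finite(X))) {
    stop("features contain non-finite values", call. = FALSE)
  }
  if (nrow(X) != length(y)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  d <- ncol(X)
  stopifnot(d >= 1L, n_hidden >= 1L)

  center <- rep(0, d)
  scale <- rep(1, d)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")

  set.seed(as.integer(seed))
  W <- matrix(stats::runif(n_hidden * d, -1, 1), n_hidden, d)
  b <- stats::runif(n_hidden, 0, 1)

  H <- sigmoid(Xs %*% t(W) + matrix(b, nrow(Xs), n_hidden, byrow = TRUE))
  Tmat <- cbind(as.numeric(y == 1L), as.numeric(y == 2L))
  beta <- MASS::ginv(H) %*% Tmat

  structure(
    list(input_weights = W, biases = b, output_weights = beta,
         n_hidden = as.integer(n_hidden), d = d,
         center = center, scale = scale, seed = as.integer(seed),
         activation = "sigmoid"),
    class = "elm_model"
  )
}

#' @export
print.elm_model <- function(x, ...) {
  cat("<elm_model> ", x$d, " features -> ", x$n_hidden,
      " sigmoid hidden units -> 2 classes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Predict classes with a trained ELM
#'
#' Argmax over the two output scores; an exact tie goes to the lower class
#' label (1 = poor).
#'
#' @param model An `elm_model`.
#' @param features Query subjects x d matrix (d as at training).
#' @return Integer vector of predicted labels in `{1, 2}`.
#' @export
elm_predict <- function(model, features) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (ncol(X) != model$d) {
    stop("model expects ", model$d, " features, got ", ncol(X),
         call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  H <- sigmoid(Xs %*% t(model$input_weights) +
                 matrix(model$biases, nrow(Xs), model$n_hidden,
                        byrow = TRUE))
  scores <- H %*% model$output_weights
  unname(ifelse(scores[, 2L] > scores[, 1L], 2L, 1L))
}

# Confusion counts and percentage metrics for one fold.  Positive class is
# excellent (label 2).
fold_metrics <- function(truth, predicted) {
  tp <- sum(truth == 2L & predicted == 2L)
  fn <- sum(truth == 2L & predicted == 1L)
  tn <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 1L & predicted == 2L)
  n <- tp + fn + tn + fp
  list(
    tp = tp, fn = fn, tn = tn, fp = fp, n_test = n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / n
  )
}

#' Stratified fold assignment
#'
#' Subjects are shuffled within class and dealt cyclically across folds,
#' continuing the deal across classes, so that per-class fold counts and
#' total fold sizes each differ by at most one.
#'
#' @param labels Integer class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold ids (1..n_folds) per subject.
#' @export
stratified_folds <- function(labels, n_folds, seed) {
  y <- as.integer(labels)
  n <- length(y)
  stopifnot(n_folds >= 2L, n_folds <= n)
  set.seed(as.integer(seed))
  fold <- integer(n)
  counter <- 0L
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    fold[idx] <- (counter + seq_along(idx) - 1L) %% n_folds + 1L
    counter <- counter + length(idx)
  }
  fold
}

#' Cross-validated ELM classification
#'
#' Stratified N-fold cross-validation (default N = 10): each fold serves
#' once as the test set with the other folds as training data.  Per-fold
#' sensitivity, specificity and accuracy are reported in percent with the
#' excellent group (label 2) as the positive class, plus the
#' mean +/- sample standard deviation across folds.
#'
#' @param features Subjects x d matrix.
#' @param labels Labels in `{1, 2}`; each class needs at least `n_folds`
#'   members for stratification.
#' @param n_folds Number of folds, default 10.
#' @param n_hidden Hidden-layer width, default 500.
#' @param seed Integer seed controlling both the fold assignment and the
#'   per-fold random input layers.
#' @param standardize Passed to [elm_train()].
#' @return An object of class `elm_cv`: list with `folds` (data frame of
#'   per-fold metrics and confusion counts) and `summary` (mean and sd of
#'   each metric across folds).
#' @export
cross_validate <- function(features, labels, n_folds = 10L,
                           n_hidden = 500L, seed, standardize = TRUE) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (min(table(y)) < n_folds) {
    warning("a class has fewer than n_folds members; some folds will ",
            "miss a class and their sensitivity/specificity are undefined",
            call. = FALSE)
  }
  fold <- stratified_folds(y, n_folds, seed = seed)
  rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    model <- elm_train(X[!test, , drop = FALSE], y[!test],
                       n_hidden = n_hidden, seed = seed + f,
                       standardize = standardize)
    pred <- elm_predict(model, X[test, , drop = FALSE])
    m <- fold_metrics(y[test], pred)
    if (length(unique(y[test])) < 2L) {
      warning("fold ", f, " contains a single class; sensitivity or ",
              "specificity undefined for that fold", call. = FALSE)
    }
    rows[[f]] <- data.frame(fold = f, n_test = m$n_test,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            accuracy = m$accuracy,
                            tp = m$tp, fn = m$fn, tn = m$tn, fp = m$fp)
  }
  folds <- do.call(rbind, rows)
  summarise <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v[!is.na(v)]))
  structure(
    list(folds = folds,
         summary = list(sensitivity = summarise(folds$sensitivity),
                        specificity = summarise(folds$specificity),
                        accuracy = summarise(folds$accuracy)),
         n_folds = n_folds, n_hidden = n_hidden, seed = seed),
    class = "elm_cv"
  )
}

#' @export
print.elm_cv <- function(x, ...) {
  cat("<elm_cv> ", x$n_folds, "-fold cross-validation, ", x$n_hidden,
      " hidden units\n", sep = "")
  print.data.frame(x$folds[, c("fold", "n_test", "sensitivity",
                               "specificity", "accuracy")],
                   row.names = FALSE, digits = 4)
  s <- x$summary
  cat(sprintf("mean +/- sd: sensitivity %.2f +/- %.2f, specificity %.2f +/- %.2f, accuracy %.2f +/- %.2f\n",
              s$sensitivity["mean"], s$sensitivity["sd"],
              s$specificity["mean"], s$specificity["sd"],
              s$accuracy["mean"], s$accuracy["sd"]))
  invisible(x)
}

#' Permutation baseline for the cross-validated ELM
#'
#' Repeats the cross-validation with the labels randomly permuted,
#' yielding the null distribution of the mean CV accuracy.
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of label permutations.
#' @return List with `accuracies` (numeric vector, one mean CV accuracy
#'   per permutation; empty when `n_permutations = 0`), `mean`, and
#'   `interval` (empirical 2.5% and 97.5% quantiles), the latter two `NA`
#'   when empty.
#' @export
permutation_baseline <- function(features, labels, n_permutations,
                                 n_folds = 10L, n_hidden = 500L, seed,
                                 standardize = TRUE) {
  stopifnot(n_permutations >= 0L)
  if (n_permutations == 0L) {
    return(list(accuracies = numeric(0), mean = NA_real_,
                interval = c(NA_real_, NA_real_), empty = TRUE))
  }
  y <- as.integer(labels)
  acc <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    set.seed(as.integer(seed) + 7919L * p)
    yp <- sample(y)
    cv <- cross_validate(features, yp, n_folds = n_folds,
                         n_hidden = n_hidden, seed = seed + 104729L + p,
                         standardize = standardize)
    acc[p] <- cv$summary$accuracy["mean"]
  }
  list(accuracies = acc, mean = mean(acc),
       interval = stats::quantile(acc, c(0.025, 0.975), names = FALSE),
       empty = FALSE)
}
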