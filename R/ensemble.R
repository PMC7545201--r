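# Model validation by repeated stratified k-fold cross-validation ensembles:
# a true-label ensemble and a permuted-label null ensemble built by the same
# machinery, compared by an empirical p-value.
#
# Unit of analysis: one CV *iteration* (its k fold-models jointly predict
# every sample exactly once), so 100 iterations of 10-fold CV give 100
# accuracies from 1000 fitted models and SEM = sd / sqrt(iterations).

#' Cross-validation ensemble configuration
#'
#' @param k_folds folds per iteration (>= 2); 10 by convention.
#' @param iterations number of independent CV repetitions.
#' @param stratified draw folds within each class (default TRUE; with class
#'   sizes around 14-15 unstratified folds are occasionally single-class).
#' @param n_ortho,scaling passed to [fit_opls_da()] per fold.
#' @param seed base seed; folds and permutations use distinct,
#'   iteration-indexed substreams.
#' @param noise_policy optional [exclusion_policy()]: when given, RSD-noise
#'   bins are re-detected inside each training fold and dropped for that
#'   fold's fit and predictions (no test-set leakage).
#' @param positive_class label coded +1 (sensitivity refers to this class).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k_folds = 10L, iterations = 100L, stratified = TRUE,
                      n_ortho = 1L, scaling = "unit_variance", seed = 1L,
                      noise_policy = NULL, positive_class = NULL) {
  k_folds <- assert_count(k_folds, "k_folds", lower = 2L)
  iterations <- assert_count(iterations, "iterations", lower = 1L)
  assert_flag(stratified, "stratified")
  n_ortho <- assert_count(n_ortho, "n_ortho", lower = 0L)
  seed <- assert_count(seed, "seed")
  if (!is.null(noise_policy) && !inherits(noise_policy, "exclusion_policy"))
    stop_f("noise_policy must be NULL or an exclusion_policy")
  structure(list(k_folds = k_folds, iterations = iterations,
                 stratified = stratified, n_ortho = n_ortho,
                 scaling = scaling, seed = seed, noise_policy = noise_policy,
                 positive_class = positive_class),
            class = "cv_config")
}

# Random fold assignment; stratified draws balance classes across folds.
# Returns an integer vector of fold ids in 1..k.
make_folds <- function(y_num, k, stratified) {
  n <- length(y_num)
  folds <- integer(n)
  if (stratified) {
    for (cls in unique(y_num)) {
      idx <- which(y_num == cls)
      folds[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

run_cv_iteration <- function(X, y_num, folds, config, keep_models = FALSE) {
  k <- max(folds)
  y_hat <- numeric(length(y_num))
  pred_cls <- numeric(length(y_num))
  r2x <- r2y <- numeric(k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    cols <- if (!is.null(config$noise_policy))
      !noise_flags(Xtr, config$noise_policy) else rep(TRUE, ncol(X))
    fit <- fit_opls_da(Xtr[, cols, drop = FALSE],
                       ifelse(y_num[!test] > 0, "pos", "neg"),
                       n_ortho = config$n_ortho, scaling = config$scaling,
                       positive_class = "pos")
    pr <- predict(fit, X[test, cols, drop = FALSE])
    y_hat[test] <- pr$y_hat
    pred_cls[test] <- ifelse(pr$class == "pos", 1, -1) # tie -> control-like
    r2x[f] <- fit$R2X; r2y[f] <- fit$R2Y
    if (keep_models) models[[f]] <- fit
  }
  pos <- y_num > 0
  acc <- 100 * mean(pred_cls == y_num)
  sens <- 100 * mean(pred_cls[pos] == 1)
  spec <- 100 * mean(pred_cls[!pos] == -1)
  q2 <- 1 - sum((y_num - y_hat)^2) / sum((y_num - mean(y_num))^2)
  list(accuracy = acc, sensitivity = sens, specificity = spec, q2 = q2,
       r2x = mean(r2x), r2y = mean(r2y), y_hat = y_hat, models = models)
}

run_ensemble <- function(X, y, config, permute) {
  if (inherits(X, "binned_matrix"))
    X <- model_matrix(X, drop_noise = is.null(config$noise_policy))
  X <- as.matrix(X)
  stopifnot(inherits(config, "cv_config"))
  code <- code_response(y, config$positive_class)
  y_num <- code$y_num
  tab <- table(y_num)
  if (config$stratified && any(tab < config$k_folds))
    stop_f(paste0("smallest class (n = %d) has fewer members than k_folds ",
                  "= %d under stratification; lower k_folds"),
           min(tab), config$k_folds)
  if (any(tab < 2L)) stop_f("each class needs >= 2 samples")
  it_names <- c("accuracy", "sensitivity", "specificity", "q2", "r2x", "r2y")
  out <- matrix(NA_real_, config$iterations, length(it_names),
                dimnames = list(NULL, it_names))
  old_opt <- options(metabopls.warn_zero_sd = FALSE)
  on.exit(options(old_opt))
  for (it in seq_len(config$iterations)) {
    y_it <- y_num
    if (permute)
      y_it <- with_seed(derive_seed(config$seed, 2L, it),
                        y_num[sample.int(length(y_num))])
    folds <- with_seed(derive_seed(config$seed, 1L, it),
                       make_folds(y_it, config$k_folds, config$stratified))
    res <- run_cv_iteration(X, y_it, folds, config)
    out[it, ] <- unlist(res[it_names])
  }
  summ <- data.frame(
    metric = it_names,
    mean = colMeans(out),
    sem = apply(out, 2, stats::sd) / sqrt(config$iterations),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(iterations = as.data.frame(out),
                 summary = summ,
                 label_mode = if (permute) "permuted" else "true",
                 config = config, n = nrow(X), n_vars = ncol(X),
                 classes = c(positive = code$positive,
                             negative = code$negative)),
            class = "ensemble_result")
}

#' True-label cross-validation ensemble
#'
#' Per iteration: draw a fresh random (stratified) k-fold partition, fit an
#' OPLS-DA on each training split and predict its held-out fold, so every
#' sample is predicted exactly once per iteration; record that iteration's
#' pooled accuracy, sensitivity, specificity and `Q2 = 1 - PRESS / SS_y`,
#' plus R2X/R2Y averaged over the k fold-models. Summaries are mean +/- SEM
#' across iterations.
#'
#' @param X numeric matrix or `binned_matrix` (samples x retained bins).
#' @param y two-class labels.
#' @param config a [cv_config()].
#' @return an `ensemble_result`.
#' @export
ensemble_cv <- function(X, y, config = cv_config()) {
  run_ensemble(X, y, config, permute = FALSE)
}

#' Permuted-label (null) cross-validation ensemble
#'
#' Identical to [ensemble_cv()] except that each iteration first draws one
#' fresh uniform permutation of the labels; the resulting ensemble is the
#' null distribution of the validation metrics (chance-level accuracy is
#' about 50% for two near-balanced classes).
#'
#' @inheritParams ensemble_cv
#' @return an `ensemble_result` with `label_mode = "permuted"`.
#' @export
permutation_null <- function(X, y, config = cv_config()) {
  run_ensemble(X, y, config, permute = TRUE)
}

#' @export
print.ensemble_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ensemble_result (%s labels): %d iterations x %d-fold CV>\n",
              x$label_mode, x$config$iterations, x$config$k_folds))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %8.3f +/- %.3f\n", s$metric[i], s$mean[i],
                s$sem[i]))
  invisible(x)
}

#' Compare a true-label ensemble to its permutation null
#'
#' Reports the mean differences for accuracy, sensitivity, specificity and
#' Q2, and the empirical p-value
#' `p = (1 + #{null iterations with accuracy >= observed mean accuracy}) /
#' (1 + iterations)`, whose floor is `1 / (iterations + 1)`.
#'
#' @param obs `ensemble_result` with true labels.
#' @param null `ensemble_result` with permuted labels, same config shape.
#' @return list of class `null_comparison` with `delta`, `p_accuracy`,
#'   `observed_mean_accuracy`, `null_mean_accuracy`, `iterations`.
#' @export
compare_to_null <- function(obs, null) {
  stopifnot(inherits(obs, "ensemble_result"),
            inherits(null, "ensemble_result"))
  if (obs$label_mode != "true" || null$label_mode != "permuted")
    stop_f("expected obs with true labels and null with permuted labels")
  if (obs$config$k_folds != null$config$k_folds ||
      obs$config$iterations != null$config$iterations)
    stop_f("ensembles were built with different k_folds/iterations")
  metrics <- c("accuracy", "sensitivity", "specificity", "q2")
  delta <- colMeans(obs$iterations[metrics]) -
    colMeans(null$iterations[metrics])
  obs_acc <- mean(obs$iterations$accuracy)
  p <- (1 + sum(null$iterations$accuracy >= obs_acc)) /
    (1 + nrow(null$iterations))
  structure(list(delta = delta, p_accuracy = p,
                 observed_mean_accuracy = obs_acc,
                 null_mean_accuracy = mean(null$iterations$accuracy),
                 iterations = nrow(null$iterations)),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(paste0("<null_comparison: accuracy %.1f%% vs null %.1f%%, ",
                     "empirical p = %.4g>\n"),
              x$observed_mean_accuracy, x$null_mean_accuracy, x$p_accuracy))
  invisible(x)
}
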