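# The CV ensemble engine: stratification, determinism, metric definitions,
# null behaviour, and the comparison report.

small_cfg <- function(iterations = 20, seed = 9, ...) {
  cv_config(k_folds = 10, iterations = iterations, seed = seed, ...)
}

test_that("stratified folds always contain both classes", {
  y <- rep(c(1, -1), c(15, 14))
  for (seed in 1:100) {
    folds <- with(list(), metabopls:::with_seed(seed,
      metabopls:::make_folds(y, 10, TRUE)))
    tab <- table(folds, y)
    expect_true(all(tab > 0))
    expect_identical(sort(unique(folds)), 1:10)
  }
})

test_that("a fixed seed gives a bit-identical ensemble", {
  pm <- planted_matrix()
  cfg <- small_cfg(iterations = 5)
  e1 <- ensemble_cv(pm$X, pm$y, cfg)
  e2 <- ensemble_cv(pm$X, pm$y, cfg)
  expect_identical(e1$iterations, e2$iterations)
  n1 <- permutation_null(pm$X, pm$y, cfg)
  n2 <- permutation_null(pm$X, pm$y, cfg)
  expect_identical(n1$iterations, n2$iterations)
  # permutations differ across iterations (fresh draw each time)
  expect_gt(stats::sd(n1$iterations$accuracy), 0)
})

test_that("every sample is predicted exactly once per iteration", {
  pm <- planted_matrix()
  e <- ensemble_cv(pm$X, pm$y, small_cfg(iterations = 10))
  n <- length(pm$y)
  # pooled accuracy/sensitivity/specificity must be multiples of 1/n counts
  expect_true(all(abs(e$iterations$accuracy * n / 100 -
                        round(e$iterations$accuracy * n / 100)) < 1e-9))
  npos <- sum(pm$y == "trt")
  expect_true(all(abs(e$iterations$sensitivity * npos / 100 -
                        round(e$iterations$sensitivity * npos / 100)) < 1e-9))
})

test_that("summary SEM is sd over iterations divided by sqrt(iterations)", {
  pm <- planted_matrix()
  e <- permutation_null(pm$X, pm$y, small_cfg(iterations = 4))
  acc <- e$iterations$accuracy
  s <- e$summary
  expect_equal(s$sem[s$metric == "accuracy"], stats::sd(acc) / sqrt(4),
               tolerance = 1e-12)
  expect_equal(s$sem, apply(e$iterations, 2, stats::sd) / sqrt(4),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a well-separated simulated cohort is classified almost perfectly", {
  fx <- plasma_fixture()
  e <- ensemble_cv(model_matrix(fx$bm, drop_noise = FALSE), fx$groups,
                   small_cfg(iterations = 15, positive_class = "LPS",
                             noise_policy = fx$policy))
  expect_gte(mean(e$iterations$accuracy), 95)
})

test_that("the permuted-label null sits at chance with negative Q2", {
  pm <- planted_matrix(n_per = 15, delta = 6)
  nul <- permutation_null(pm$X, pm$y, small_cfg(iterations = 30,
                                                positive_class = "trt"))
  acc <- nul$iterations$accuracy
  sem <- stats::sd(acc) / sqrt(length(acc))
  expect_lte(abs(mean(acc) - 50), 3 * sem)
  expect_lt(stats::median(nul$iterations$q2), 0)
  expect_identical(nul$label_mode, "permuted")
})

test_that("class smaller than k_folds is rejected with guidance", {
  pm <- planted_matrix(n_per = 5)
  expect_error(ensemble_cv(pm$X, pm$y, cv_config(k_folds = 10)),
               "lower k_folds")
})

test_that("compare_to_null implements the empirical p-value exactly", {
  mk <- function(acc, mode) {
    structure(list(iterations = data.frame(accuracy = acc,
                                           sensitivity = acc,
                                           specificity = acc, q2 = 0,
                                           r2x = 0.5, r2y = 0.5),
                   summary = NULL, label_mode = mode,
                   config = cv_config(iterations = length(acc)),
                   n = 29), class = "ensemble_result")
  }
  obs <- mk(rep(100, 100), "true")
  nul <- mk(seq(30, 69.6, by = 0.4), "permuted")
  cmp <- compare_to_null(obs, nul)
  expect_equal(cmp$p_accuracy, 1 / 101, tolerance = 1e-12)
  expect_equal(unname(cmp$delta["accuracy"]), 100 - mean(nul$iterations$accuracy),
               tolerance = 1e-12)
  expect_error(compare_to_null(nul, obs), "permuted")
  # a null compared against itself: delta 0, p near 1/2
  self <- mk(nul$iterations$accuracy, "true")
  cs <- compare_to_null(self, nul)
  expect_equal(unname(cs$delta["accuracy"]), 0, tolerance = 1e-12)
  expect_true(cs$p_accuracy > 0.3 && cs$p_accuracy < 0.7)
})

test_that("per-fold parameters are fitted strictly inside each fold", {
  fx <- plasma_fixture()
  X <- model_matrix(fx$bm, drop_noise = FALSE)
  y_num <- ifelse(fx$groups == "LPS", 1, -1)
  cfg <- cv_config(seed = 2, noise_policy = fx$policy)
  folds <- metabopls:::with_seed(1, metabopls:::make_folds(y_num, 10, TRUE))
  run <- function(f) metabopls:::run_cv_iteration(X, y_num, f, cfg,
                                                  keep_models = TRUE)
  r1 <- run(folds)
  # relocate one sample from fold 1 to fold 2
  folds2 <- folds
  moved <- which(folds == 1)[1]
  folds2[moved] <- 2L
  r2 <- run(folds2)
  for (f in 3:10) {
    expect_identical(r1$models[[f]]$w, r2$models[[f]]$w)
    expect_identical(r1$models[[f]]$scaling$center,
                     r2$models[[f]]$scaling$center)
    expect_identical(r1$models[[f]]$n_vars, r2$models[[f]]$n_vars)
  }
  expect_false(identical(r1$models[[1]]$scaling$center,
                         r2$models[[1]]$scaling$center))
})
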