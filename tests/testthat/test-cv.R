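test_that("component standardization is population-moment exact", {
  expect_equal(standardize_component(c(1, 2, 3)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_warning(z <- standardize_component(rep(5, 10)), "constant")
  expect_equal(z, rep(0, 10))
  set.seed(70)
  for (i in 1:5) {
    v <- standardize_component(rnorm(50, sd = runif(1, 0.1, 10)))
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(mean(v^2) - 1), 1e-9)
  }
  ## the row-wise helper agrees with the scalar definition
  m <- matrix(rnorm(40), 4, 10)
  expect_equal(refsca:::standardize_rows(m),
               t(apply(m, 1, standardize_component)))
})

test_that("confusion metrics follow the disease-positive convention", {
  expect_equal(confusion_metrics(c(1, 1, -1, -1), c(1, 1, -1, -1)),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  y_true <- c(rep(1, 4), rep(-1, 4))
  y_pred <- c(1, 1, 1, -1, 1, 1, -1, -1)  # TP=3 FN=1 FP=2 TN=2
  expect_equal(confusion_metrics(y_true, y_pred),
               c(sensitivity = 0.75, specificity = 0.5, accuracy = 0.625))
  expect_equal(confusion_metrics(y_true, rep(1, 8))[["specificity"]], 0)
  expect_equal(confusion_metrics(y_true, rep(1, 8))[["sensitivity"]], 1)
  expect_error(confusion_metrics(rep(1, 4), rep(1, 4)), "single class")
})

test_that("stratified folds balance classes to within one sample", {
  set.seed(71)
  for (i in 1:20) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    labels <- c(rep(1, n1), rep(-1, n2))
    fold <- stratified_twofold(labels)
    for (f in 1:2) {
      expect_lte(abs(sum(labels == 1 & fold == f) -
                     sum(labels == 1 & fold != f)), 1)
      expect_lte(abs(sum(labels == -1 & fold == f) -
                     sum(labels == -1 & fold != f)), 1)
    }
  }
})

test_that("widely separated synthetic classes classify perfectly", {
  sim <- simulate_mixture(sim_config(K = 600, n_disease = 10, n_control = 10,
                                     sector_disease = c(80, 89.9),
                                     sector_neutral = c(40, 50),
                                     sector_control = c(0.1, 10),
                                     seed = 8))
  g <- cv_grid(M_values = 3, delta_theta_values = 5, lambda_multipliers = 1e-6,
               n_repetitions = 3, mode = "sweep")
  rep <- suppressWarnings(repeated_two_fold_cv(sim$dataset, g, seed = 9))
  expect_equal(rep$mean_sensitivity, 1)
  expect_equal(rep$mean_specificity, 1)
})

test_that("reports are deterministic given the seed", {
  sim <- simulate_mixture(sim_config(K = 100, n_disease = 6, n_control = 6,
                                     seed = 10))
  g <- cv_grid(M_values = 2, delta_theta_values = 5,
               lambda_multipliers = 1e-4, n_repetitions = 2, mode = "sweep")
  r1 <- suppressWarnings(repeated_two_fold_cv(sim$dataset, g, seed = 123))
  r2 <- suppressWarnings(repeated_two_fold_cv(sim$dataset, g, seed = 123))
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("sweep tables are consistent with the winning configuration", {
  sim <- simulate_mixture(sim_config(K = 100, n_disease = 6, n_control = 6,
                                     seed = 11))
  g <- cv_grid(M_values = c(2, 3), delta_theta_values = 5,
               lambda_multipliers = 1e-4, n_repetitions = 2, mode = "sweep")
  rep <- suppressWarnings(repeated_two_fold_cv(sim$dataset, g, seed = 13))
  tab <- grid_report(rep)
  expect_true(all(c("M", "delta_theta", "lambda", "kernel", "set") %in%
                  names(tab)))
  expect_equal(nrow(tab), 8L)  # 2 M x 4 sets x 1 kernel
  best <- tab[which.max(tab$mean_accuracy), ]
  expect_equal(best$M, rep$winning_config$M)
  expect_equal(best$set, rep$winning_config$component_set)
  expect_equal(best$mean_accuracy, rep$mean_accuracy)
  ## a best-configuration record in the published style round-trips
  expect_true(all(tab$mean_sensitivity >= 0 & tab$mean_sensitivity <= 1))
})

test_that("nested mode selects a configuration on the training half only", {
  sim <- simulate_mixture(sim_config(K = 300, n_disease = 8, n_control = 8,
                                     seed = 12))
  g <- cv_grid(M_values = c(2, 3), delta_theta_values = 5,
               lambda_multipliers = 1e-4, n_repetitions = 2, mode = "nested")
  rep <- suppressWarnings(repeated_two_fold_cv(sim$dataset, g, seed = 17))
  expect_s3_class(rep, "cv_report")
  expect_equal(nrow(rep$per_evaluation), 4L)  # 2 reps x 2 folds, winner only
  expect_true(rep$winning_config$M %in% c(2L, 3L))
  expect_true(rep$winning_config$component_set %in%
              c("controlref_disease", "controlref_control",
                "diseaseref_control", "diseaseref_disease"))

  tiny <- expression_dataset(matrix(rnorm(4 * 20), 4, 20), c(1, 1, -1, -1))
  g2 <- cv_grid(M_values = 2, delta_theta_values = 5,
                lambda_multipliers = 1e-4, n_repetitions = 1, mode = "nested")
  expect_error(suppressWarnings(repeated_two_fold_cv(tiny, g2, seed = 1)),
               "inner split impossible")
})
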