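test_that("correlation, bias and the linear fit match closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(41)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20, 0, 0.3)
  expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")

  s <- data.frame(ph_measured = c(1, 1.2, 0.9), ph_sfm = c(1, 1.2, 0.9))
  expect_equal(height_bias(s), 0)
  s$ph_sfm <- s$ph_measured - 0.08
  expect_equal(height_bias(s), -0.08)

  two <- data.frame(ph_measured = c(0, 1), ph_sfm = c(0, 1))
  f <- fit_linear(two)
  expect_equal(c(f$a, f$b), c(1, 0), tolerance = 1e-12)
  shift <- data.frame(ph_sfm = c(0.5, 0.8, 1.1),
                      ph_measured = c(0.6, 0.9, 1.2))
  fs <- fit_linear(shift)
  expect_equal(c(fs$a, fs$b), c(1, 0.1), tolerance = 1e-10)
  set.seed(42)
  smp <- data.frame(ph_sfm = runif(30, 0.5, 1.2))
  smp$ph_measured <- 1.1 * smp$ph_sfm + 0.07 + rnorm(30, 0, 0.03)
  ff <- fit_linear(smp)
  oc <- oracle_ols(smp$ph_sfm, smp$ph_measured)
  expect_equal(c(ff$a, ff$b), unname(oc), tolerance = 1e-10)
  expect_error(fit_linear(data.frame(ph_sfm = c(1, 1),
                                     ph_measured = c(1, 2))),
               "degenerate predictor")
})

test_that("validation metrics follow their definitions", {
  val <- data.frame(ph_sfm = c(0.8, 0.9, 1.0, 1.1),
                    ph_measured = c(0.8, 0.9, 1.0, 1.1))
  ident <- structure(list(a = 1, b = 0), class = "linear_calibration")
  ev <- evaluate_calibration(ident, val)
  expect_equal(ev$r2, 1)
  expect_equal(ev$mae, 0)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$mape, 0)

  # predicting the validation mean gives R2 = 0 by definition
  mean_model <- structure(list(a = 0, b = mean(val$ph_measured)),
                          class = "linear_calibration")
  expect_equal(evaluate_calibration(mean_model, val)$r2, 0)

  # constant error: MAE = RMSE = shift, MAPE from the direct formula
  shifted <- structure(list(a = 1, b = 0.1), class = "linear_calibration")
  ev2 <- evaluate_calibration(shifted, val)
  expect_equal(ev2$mae, 0.1)
  expect_equal(ev2$rmse, 0.1)
  expect_equal(ev2$mape, 100 * mean(0.1 / val$ph_measured))
  expect_error(evaluate_calibration(
    ident, data.frame(ph_sfm = 1, ph_measured = 0)), "MAPE")
})

test_that("MAE never exceeds RMSE", {
  set.seed(43)
  for (i in 1:20) {
    val <- data.frame(ph_sfm = runif(15, 0.5, 1.5))
    val$ph_measured <- val$ph_sfm + rnorm(15, 0, 0.1)
    m <- structure(list(a = runif(1, 0.8, 1.2), b = rnorm(1, 0, 0.05)),
                   class = "linear_calibration")
    ev <- evaluate_calibration(m, val)
    expect_lte(ev$mae, ev$rmse + 1e-12)
  }
})

test_that("the OLS fit dominates alternative lines on its training data", {
  set.seed(44)
  s <- data.frame(ph_sfm = runif(25, 0.5, 1.2))
  s$ph_measured <- 1.05 * s$ph_sfm + 0.05 + rnorm(25, 0, 0.04)
  fit <- fit_linear(s)
  rss_fit <- sum((fit$a * s$ph_sfm + fit$b - s$ph_measured)^2)
  for (da in seq(-0.2, 0.2, by = 0.05)) for (db in seq(-0.1, 0.1, by = 0.025))
    expect_gte(sum(((fit$a + da) * s$ph_sfm + (fit$b + db) -
                      s$ph_measured)^2), rss_fit - 1e-12)
})

test_that("validation-set enumeration crosses flights and groups", {
  expect_equal(nrow(enumerate_cv_sets(3, 3)), 18)
  expect_equal(nrow(enumerate_cv_sets(1, 3)), 0)
  expect_equal(nrow(enumerate_cv_sets(2, 2)), 4)
  for (nr in 1:5) for (ng in 1:4)
    expect_equal(nrow(enumerate_cv_sets(nr, ng)),
                 oracle_cv_count(nr, ng))
  sets <- enumerate_cv_sets(4, 2)
  expect_true(all(sets$train_rep != sets$val_rep))
})

test_that("cross-validation partitions never leak samples", {
  set.seed(45)
  n_rows <- 12
  grid <- expand.grid(row_id = seq_len(n_rows), repetition = 1:3)
  grid$group <- ((grid$row_id - 1) %/% 4) + 1
  grid$sample_id <- paste(grid$row_id, grid$repetition)
  sets <- enumerate_cv_sets(3, 3)
  for (j in seq_len(nrow(sets))) {
    cs <- sets[j, ]
    train <- grid[grid$repetition == cs$train_rep & grid$group != cs$val_group, ]
    val <- grid[grid$repetition == cs$val_rep & grid$group == cs$val_group, ]
    expect_length(intersect(train$sample_id, val$sample_id), 0)
    expect_length(intersect(train$row_id, val$row_id), 0)
    expect_false(any(val$repetition %in% train$repetition))
  }
})

test_that("condition reports aggregate repetitions and validation sets", {
  set.seed(46)
  grid <- expand.grid(row_id = 1:12, repetition = 1:3)
  grid$group <- ((grid$row_id - 1) %/% 4) + 1
  grid$ph_measured <- rep(runif(12, 0.7, 1.1), 3)
  grid$ph_sfm <- grid$ph_measured   # perfect photogrammetry
  rep0 <- run_condition(grid)
  expect_equal(rep0$r, 1)
  expect_equal(rep0$bias, 0)
  expect_equal(rep0$r2_val, 1)
  expect_equal(rep0$mae, 0)
  expect_equal(rep0$n_sets, 18)
  expect_equal(rep0$n_train, 8)
  expect_equal(rep0$n_val, 4)

  # per-flight datum shifts: within-flight fit stays sharp, transfer fails
  shifts <- c(0, 0.8, -0.6)
  grid$ph_sfm <- grid$ph_measured - 0.05 + shifts[grid$repetition]
  rep1 <- run_condition(grid)
  expect_gt(rep1$r2_train, 0.99)
  expect_lt(rep1$r2_val, 0)

  # a single repetition cannot be cross-validated
  one <- grid[grid$repetition == 1, ]
  rep2 <- run_condition(one)
  expect_equal(rep2$n_sets, 0)
  expect_true(is.na(rep2$r2_val))
  expect_false(is.na(rep2$r))

  # missing (repetition, group) cell is an incomplete design
  broken <- grid[!(grid$repetition == 2 & grid$group == 3), ]
  expect_error(run_condition(broken), "incomplete design")
})

test_that("calibration recovery: intercept finds the apex shrinkage", {
  # heights from the full-scale field, photogrammetric heights lowered
  # by a known shrinkage plus centimeter observation noise
  lay <- field2_layout_fullscale()
  can <- canopy_vegetative()
  h <- generate_true_heights(lay, can, 314)
  h <- h[h$measured, ][1:112, ]
  shrink <- 0.08
  set.seed(315)
  s <- data.frame(ph_measured = h$true_height,
                  ph_sfm = h$true_height - shrink + rnorm(112, 0, 0.01))
  fit <- fit_linear(s)
  expect_lt(abs(fit$a - 1), 3 * fit$se_a)
  expect_lt(abs(fit$b - shrink), 3 * fit$se_b)
})

test_that("condition tables rank by validation R2 and label LC/HC", {
  reports <- data.frame(
    camera_angle = c(-60, -60, -90), rtk = c(FALSE, TRUE, FALSE),
    gcp = c(FALSE, TRUE, FALSE), method = c("M3", "M1", "M2"),
    r = c(0.9, 0.95, 0.5), bias = c(-0.07, -0.06, -0.1),
    r2_train = c(0.8, 0.85, 0.3), r2_val = c(0.2, 0.8, -0.5),
    mae = c(0.05, 0.03, 0.1), rmse = c(0.06, 0.04, 0.12),
    mape = c(5, 3, 10), n_sets = 18L, n_train = 112L, n_val = 56L)
  tab <- condition_table(reports)
  expect_equal(tab$r2_val, c(0.8, 0.2, -0.5))
  expect_equal(tab$label, c("HC", "LC", ""))
  single <- condition_table(reports[1, ])
  expect_equal(nrow(single), 1)
})
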