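#' Pearson correlation between measured and photogrammetric height
#'
#' @param x,y numeric vectors of equal length, at least 3 pairs, each
#'   with nonzero variance.
#' @return product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Mean bias of photogrammetric height
#'
#' @param samples data frame with columns `ph_sfm` and `ph_measured` (m).
#' @return mean of `ph_sfm - ph_measured` (m).
#' @export
height_bias <- function(samples) {
  if (!nrow(samples)) stop("no samples")
  mean(samples$ph_sfm - samples$ph_measured)
}

#' Fit the linear height calibration
#'
#' Ordinary least squares of measured height on photogrammetric height:
#' `ph_measured = a * ph_sfm + b`.
#'
#' @param samples data frame with `ph_measured` and `ph_sfm`; needs at
#'   least two distinct `ph_sfm` values.
#' @return object of class `linear_calibration`: list with slope `a`,
#'   intercept `b` (m), their standard errors `se_a`, `se_b`, `r2_train`
#'   and `n`.
#' @export
fit_linear <- function(samples) {
  if (nrow(samples) < 2 || length(unique(samples$ph_sfm)) < 2)
    stop("degenerate predictor: need at least two distinct ph_sfm values")
  fit <- stats::lm(ph_measured ~ ph_sfm, data = samples)
  # summary.lm warns on numerically perfect fits; harmless here
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    a = unname(stats::coef(fit)[2]),
    b = unname(stats::coef(fit)[1]),
    se_a = if (nrow(co) == 2) co[2, 2] else NA_real_,
    se_b = co[1, 2],
    r2_train = suppressWarnings(summary(fit))$r.squared,
    n = nrow(samples)
  ), class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("linear_calibration: ph_measured = %.4f * ph_sfm + %.4f  (n = %d, R2 = %.3f)\n",
              x$a, x$b, x$n, x$r2_train))
  invisible(x)
}

#' Predict measured height from photogrammetric height
#' @param object a `linear_calibration`.
#' @param newdata data frame with `ph_sfm`.
#' @param ... unused.
#' @return predicted heights (m).
#' @export
predict.linear_calibration <- function(object, newdata, ...) {
  object$a * newdata$ph_sfm + object$b
}

#' Evaluate a calibration on validation samples
#'
#' Computes the coefficient of determination about the validation set's
#' own mean (`R2 = 1 - SSres / SStot`, not clipped below zero: a model
#' trained on a flight with a different vertical datum can score far
#' below zero), the mean absolute error, root mean squared error, and
#' mean absolute percentage error.
#'
#' @param model a [fit_linear()] calibration.
#' @param samples validation data frame with `ph_measured`, `ph_sfm`;
#'   `ph_measured` must be nonzero for the MAPE.
#' @return named list `r2`, `mae` (m), `rmse` (m), `mape` (percent).
#' @export
evaluate_calibration <- function(model, samples) {
  if (!nrow(samples)) stop("no validation samples")
  if (any(samples$ph_measured == 0))
    stop("MAPE undefined: zero measured height")
  pred <- predict(model, samples)
  err <- pred - samples$ph_measured
  sstot <- sum((samples$ph_measured - mean(samples$ph_measured))^2)
  list(
    r2 = 1 - sum(err^2) / sstot,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    mape = 100 * mean(abs(err) / abs(samples$ph_measured))
  )
}

#' Enumerate different-targets-and-different-flight validation sets
#'
#' All ordered pairs of distinct flight repetitions (train, validation)
#' crossed with every choice of held-out spatial group: the calibration
#' is trained on the other `n_groups - 1` groups of the training flight
#' and validated on the held-out group of the validation flight, so
#' validation samples differ from training samples in both flight and
#' spatial group. With 3 repetitions and 3 groups this yields the
#' scheme's 18 sets.
#'
#' @param n_repetitions number of flight repetitions (>= 1).
#' @param n_groups number of spatial groups (>= 1).
#' @return data frame `train_rep`, `val_rep`, `val_group` with
#'   `n_repetitions * (n_repetitions - 1) * n_groups` lines.
#' @export
enumerate_cv_sets <- function(n_repetitions, n_groups) {
  stopifnot(n_repetitions >= 1, n_groups >= 1)
  if (n_repetitions < 2)
    return(data.frame(train_rep = integer(0), val_rep = integer(0),
                      val_group = integer(0)))
  out <- expand.grid(val_group = seq_len(n_groups),
                     val_rep = seq_len(n_repetitions),
                     train_rep = seq_len(n_repetitions))
  out <- out[out$train_rep != out$val_rep,
             c("train_rep", "val_rep", "val_group")]
  out <- out[order(out$train_rep, out$val_rep, out$val_group), ]
  rownames(out) <- NULL
  out
}

#' Run the cross-validation report for one condition
#'
#' `samples` holds every height sample of one analysis condition: one
#' line per measured row and flight repetition with `ph_measured`,
#' `ph_sfm`, `repetition` and spatial `group`. Correlation and bias are
#' computed per repetition on the full flight and averaged over
#' repetitions. For each validation set the calibration is fitted on the
#' training partition and evaluated on the validation partition; the
#' report averages the metrics over all sets.
#'
#' @param samples data frame as described; `sample_id` optional.
#' @param cv_sets validation sets from [enumerate_cv_sets()]; derived
#'   from the data when `NULL`.
#' @return one-line data frame: `r`, `bias`, `r2_train`, `r2_val`,
#'   `mae`, `rmse`, `mape`, `n_sets`, `n_train`, `n_val`. With fewer
#'   than two repetitions the CV columns are `NA` and only `r` and
#'   `bias` are reported.
#' @export
run_condition <- function(samples, cv_sets = NULL) {
  stopifnot(all(c("ph_measured", "ph_sfm", "repetition", "group")
                %in% names(samples)))
  reps <- sort(unique(samples$repetition))
  groups <- sort(unique(samples$group))
  tab <- table(samples$repetition, samples$group)
  if (any(tab == 0))
    stop("incomplete design: every (repetition, group) cell needs samples")

  per_rep <- lapply(reps, function(rp) {
    s <- samples[samples$repetition == rp, ]
    c(r = pearson_r(s$ph_measured, s$ph_sfm), bias = height_bias(s))
  })
  r_mean <- mean(vapply(per_rep, `[[`, 0, "r"))
  bias_mean <- mean(vapply(per_rep, `[[`, 0, "bias"))

  if (is.null(cv_sets))
    cv_sets <- enumerate_cv_sets(length(reps), length(groups))
  if (!nrow(cv_sets))
    return(data.frame(r = r_mean, bias = bias_mean, r2_train = NA_real_,
                      r2_val = NA_real_, mae = NA_real_, rmse = NA_real_,
                      mape = NA_real_, n_sets = 0L,
                      n_train = NA_integer_, n_val = NA_integer_))

  metrics <- lapply(seq_len(nrow(cv_sets)), function(j) {
    cs <- cv_sets[j, ]
    train <- samples[samples$repetition == reps[cs$train_rep] &
                       samples$group != groups[cs$val_group], ]
    val <- samples[samples$repetition == reps[cs$val_rep] &
                     samples$group == groups[cs$val_group], ]
    model <- fit_linear(train)
    ev <- evaluate_calibration(model, val)
    c(r2_train = model$r2_train, r2_val = ev$r2, mae = ev$mae,
      rmse = ev$rmse, mape = ev$mape, n_train = nrow(train),
      n_val = nrow(val))
  })
  m <- do.call(rbind, metrics)
  data.frame(
    r = r_mean, bias = bias_mean,
    r2_train = mean(m[, "r2_train"]), r2_val = mean(m[, "r2_val"]),
    mae = mean(m[, "mae"]), rmse = mean(m[, "rmse"]),
    mape = mean(m[, "mape"]), n_sets = nrow(cv_sets),
    n_train = as.integer(m[1, "n_train"]), n_val = as.integer(m[1, "n_val"])
  )
}

#' Ranked condition comparison table
#'
#' Binds per-condition reports, sorts them by validation R2 (descending,
#' `NA` last; falling back to correlation when no CV was run) and labels
#' the scheme's reference conditions: `LC`, the low-cost case (-60
#' degrees, no RTK, no GCP, method M3) and `HC`, the highest-cost case
#' (-60 degrees, RTK, GCP, method M1).
#'
#' @param reports data frame of [run_condition()] lines with condition
#'   columns `camera_angle`, `rtk`, `gcp`, `method`.
#' @return the sorted table with a `label` column.
#' @export
condition_table <- function(reports) {
  if (!nrow(reports)) stop("no condition reports")
  key <- if (all(is.na(reports$r2_val))) reports$r else reports$r2_val
  out <- reports[order(-key, na.last = TRUE), ]
  out$label <- ""
  lc <- out$camera_angle == -60 & !out$rtk & !out$gcp & out$method == "M3"
  hc <- out$camera_angle == -60 & out$rtk & out$gcp & out$method == "M1"
  out$label[lc] <- "LC"
  out$label[hc] <- "HC"
  rownames(out) <- NULL
  out
}
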