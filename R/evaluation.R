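# Evaluation of budbreak predictions against observations: residuals,
# bias / RMSE / r-squared, the binary damage-validation confusion matrix,
# the chill phase-shift experiment, and segmented MDST sensitivity slopes.

#' Budbreak residuals (days)
#'
#' `predicted - observed`: negative values are early predictions, positive
#' values late predictions.
#'
#' @param predicted_doy,observed_doy Day-of-year vectors (aligned).
#' @return Residuals in days.
#' @export
residuals_days <- function(predicted_doy, observed_doy) {
  stopifnot(length(predicted_doy) == length(observed_doy))
  predicted_doy - observed_doy
}

#' Fit statistics for predicted vs observed budbreak
#'
#' Bias is the mean residual; RMSE the root-mean-square residual; r2 the
#' squared Pearson correlation between predicted and observed (default) or
#' `1 - SSE/SST` with `r2_method = "ss"`. Pairs with a missing prediction
#' (FAILED) are excluded and counted in `n_excluded`.
#'
#' @param predicted_doy,observed_doy Aligned day-of-year vectors.
#' @param r2_method `"pearson"` or `"ss"`.
#' @return List of class `fit_stats`: `n`, `n_excluded`, `bias_days`,
#'   `rmse_days`, `r2`.
#' @export
fit_stats <- function(predicted_doy, observed_doy,
                      r2_method = c("pearson", "ss")) {
  r2_method <- match.arg(r2_method)
  stopifnot(length(predicted_doy) == length(observed_doy))
  keep <- !is.na(predicted_doy) & !is.na(observed_doy)
  n_excluded <- sum(!keep)
  p <- predicted_doy[keep]; o <- observed_doy[keep]
  if (length(p) == 0) stop("no usable prediction/observation pairs")
  res <- p - o
  r2 <- if (length(p) >= 2 && stats::sd(p) > 0 && stats::sd(o) > 0) {
    if (r2_method == "pearson") {
      stats::cor(p, o)^2
    } else {
      1 - sum(res^2) / sum((o - mean(o))^2)
    }
  } else if (all(res == 0)) 1 else NA_real_
  structure(list(n = length(p), n_excluded = n_excluded,
                 bias_days = mean(res),
                 rmse_days = sqrt(mean(res^2)),
                 r2 = r2),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("n = %d (excluded %d), bias = %+.2f d, RMSE = %.2f d, r2 = %s\n",
              x$n, x$n_excluded, x$bias_days, x$rmse_days,
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  invisible(x)
}

#' Binary damage-validation confusion matrix
#'
#' Compares per-season predicted damage occurrence (1 = at least one day
#' with `tmin` below the 10th-percentile prediction) with recorded damage
#' occurrence, and reports the standard 2x2 counts and derived fractions.
#' Precision is `NaN` (with a warning) when there are no predicted
#' positives.
#'
#' @param predicted,recorded Aligned 0/1 (or logical) vectors, one entry
#'   per season.
#' @return List of class `damage_confusion`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy`, `n`.
#' @export
damage_confusion <- function(predicted, recorded) {
  if (length(predicted) != length(recorded)) {
    stop("predicted and recorded season vectors differ in length")
  }
  p <- as.integer(as.logical(predicted))
  r <- as.integer(as.logical(recorded))
  if (anyNA(p) || anyNA(r)) stop("binary vectors must not contain NA")
  tp <- sum(p == 1 & r == 1); fp <- sum(p == 1 & r == 0)
  tn <- sum(p == 0 & r == 0); fn <- sum(p == 0 & r == 1)
  if (tp + fp == 0) warning("no predicted positives: precision is NaN")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 precision = tp / (tp + fp),
                 accuracy = (tp + tn) / length(p),
                 n = length(p)),
            class = "damage_confusion")
}

#' @export
print.damage_confusion <- function(x, ...) {
  cat(sprintf(paste0("n = %d: TP %d FP %d TN %d FN %d | sens %.2f spec %.2f",
                     " prec %.2f acc %.2f\n"),
              x$n, x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
              x$precision, x$accuracy))
  invisible(x)
}

#' Chill phase-shift experiment
#'
#' Re-predicts budbreak for every season x cultivar under each chill phase
#' shift (default -6..+6 degC by 1) with no other changes, and reports the
#' RMSE against the observations at each shift.
#'
#' @param seasons List of `dormant_season` objects.
#' @param observations data.frame with `site_id`, `cultivar`, `season_year`,
#'   `observed_doy`, `convention`.
#' @param cultivars Cultivars to evaluate.
#' @param shifts Phase shifts in degC.
#' @param floor,params_tbl Passed to [simulate_with_damage()].
#' @return data.frame with one row per shift: `shift_c`, `rmse_days`, `n`.
#' @export
phase_shift_experiment <- function(seasons, observations,
                                   cultivars = .cultivars,
                                   shifts = -6:6,
                                   floor = spring_floor(),
                                   params_tbl = load_cultivar_params()) {
  rows <- lapply(shifts, function(s) {
    preds <- predict_budbreak_many(seasons, cultivars, shift_c = s,
                                   floor = floor, params_tbl = params_tbl)
    m <- merge(preds, observations,
               by = c("site_id", "cultivar", "season_year"))
    fs <- fit_stats(m$doy_fdc, m$observed_doy)
    data.frame(shift_c = s, rmse_days = fs$rmse_days, n = fs$n)
  })
  do.call(rbind, rows)
}

# Predict (initial + FDC) budbreak for every season x cultivar; one row per
# pair. Conventions come from the observations workflow: BBCH07_50 default.
predict_budbreak_many <- function(seasons, cultivars = .cultivars,
                                  convention = "BBCH07_50", shift_c = 0,
                                  floor = spring_floor(),
                                  params_tbl = load_cultivar_params()) {
  rows <- list()
  for (season in seasons) {
    chill <- chill_for_season(season, shift_c = shift_c)
    for (cv in cultivars) {
      res <- simulate_with_damage(cv, season, chill, convention = convention,
                                  floor = floor, params_tbl = params_tbl)
      rows[[length(rows) + 1]] <- data.frame(
        site_id = season$site_id, cultivar = cv,
        season_year = season$season_year, convention = convention,
        threshold_c = res$budbreak_initial$threshold_c,
        doy_initial = res$budbreak_initial$doy,
        doy_fdc = res$budbreak_fdc$doy,
        status = res$budbreak_fdc$status,
        n_events = nrow(res$events))
    }
  }
  do.call(rbind, rows)
}

#' Segmented MDST sensitivity slopes
#'
#' Ordinary-least-squares slope of budbreak day of year on mean
#' dormant-season temperature, per temperature segment and pooled. Default
#' segments follow the published analysis: \[-1, 3\], (3, 10\], (10, 12\]
#' degC. Segments with fewer than 3 points are flagged `insufficient` and
#' get no slope.
#'
#' @param mdst_c Mean dormant-season temperatures, degC.
#' @param doy Budbreak day of year (FDC), same length.
#' @param segments List of 2-vectors `c(lo, hi)`; the first segment is
#'   closed on both ends, later segments are `(lo, hi]`.
#' @return data.frame with `segment`, `lo`, `hi`, `n`, `slope_d_per_c`,
#'   `insufficient`; last row is the pooled fit (`segment = "overall"`).
#' @export
sensitivity_slopes <- function(mdst_c, doy,
                               segments = list(c(-1, 3), c(3, 10), c(10, 12))) {
  stopifnot(length(mdst_c) == length(doy))
  keep <- !is.na(mdst_c) & !is.na(doy)
  mdst_c <- mdst_c[keep]; doy <- doy[keep]
  ols_slope <- function(x, y) {
    if (length(unique(x)) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ x))[2])
  }
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    inseg <- if (i == 1) mdst_c >= seg[1] & mdst_c <= seg[2]
             else mdst_c > seg[1] & mdst_c <= seg[2]
    n <- sum(inseg)
    data.frame(segment = sprintf("(%g, %g]", seg[1], seg[2]),
               lo = seg[1], hi = seg[2], n = n,
               slope_d_per_c = if (n >= 3) ols_slope(mdst_c[inseg], doy[inseg])
                               else NA_real_,
               insufficient = n < 3)
  })
  rows[[length(rows) + 1]] <- data.frame(
    segment = "overall", lo = NA_real_, hi = NA_real_, n = length(mdst_c),
    slope_d_per_c = if (length(mdst_c) >= 3) ols_slope(mdst_c, doy) else NA_real_,
    insufficient = length(mdst_c) < 3)
  do.call(rbind, rows)
}
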