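#' Frame-wise agreement between two angle series
#'
#' RMSE and mean absolute difference over pairwise-complete frames of
#' two series of the same definition and segment.  With zero paired
#' frames both statistics are `NA` with a warning.
#'
#' @param a,b Numeric angle series (degrees) of equal length; frames
#'   missing in either are dropped pairwise.
#' @return List with `rmse`, `mean_abs_diff` (degrees) and `n` paired
#'   frames.
#' @export
series_agreement <- function(a, b) {
  if (length(a) != length(b))
    stop("series must have the same length")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) {
    warning("no paired frames; agreement undefined")
    return(list(rmse = NA_real_, mean_abs_diff = NA_real_, n = 0L))
  }
  d <- a[ok] - b[ok]
  list(rmse = sqrt(mean(d^2)), mean_abs_diff = mean(abs(d)), n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented `x_ml - x_ref` (positive bias = the
#' markerless method reads higher).  Bias is the mean difference, the
#' spread is the sample SD of the differences (n - 1 denominator), and
#' the 95% limits of agreement are `bias +/- 1.96 * SD`.
#'
#' @param x_ml Measurements from the method under test (e.g. markerless
#'   TAF values), degrees.
#' @param x_ref Paired reference measurements (e.g. marker-based TAF),
#'   degrees.
#' @return List with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `n`,
#'   and per-pair `means` and `diffs` for plotting.
#' @export
bland_altman <- function(x_ml, x_ref) {
  if (length(x_ml) != length(x_ref))
    stop("paired vectors must have the same length")
  ok <- !is.na(x_ml) & !is.na(x_ref)
  x_ml <- x_ml[ok]; x_ref <- x_ref[ok]
  n <- length(x_ml)
  if (n < 3L)
    stop("Bland-Altman limits of agreement require at least 3 pairs")
  d <- x_ml - x_ref
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  list(bias = bias, sd_diff = sd_diff,
       loa_lower = bias - 1.96 * sd_diff,
       loa_upper = bias + 1.96 * sd_diff,
       n = n, means = (x_ml + x_ref) / 2, diffs = d)
}

#' Ordinary least squares of method-under-test on reference
#'
#' Closed-form simple linear regression of `x_ml` on `x_ref`;
#' `r2` is the squared Pearson correlation.  A zero-variance predictor
#' leaves the slope undefined (`NA`) with a warning.
#'
#' @inheritParams bland_altman
#' @return List with `slope`, `intercept`, `r2` and `n`.
#' @export
linreg_r2 <- function(x_ml, x_ref) {
  ok <- !is.na(x_ml) & !is.na(x_ref)
  x <- x_ref[ok]; y <- x_ml[ok]
  n <- length(x)
  if (n < 2L) stop("regression requires at least 2 pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    warning("zero variance in predictor; slope undefined")
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                n = n))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy == 0) NA_real_ else (sxy^2) / (sxx * syy)
  list(slope = slope, intercept = intercept, r2 = r2, n = n)
}

#' Aggregate agreement results across a validation batch
#'
#' Builds the summary tables of a validation run from the per-series
#' RMSE table and the per-segment TAF table:
#' * `rmse_by_digit`: RMSE distribution per activity x digit (the strip
#'   chart layout), with per-group mean and SD;
#' * `bland_altman`: per-activity Bland-Altman statistics pooled over the
#'   TAF values of the 2nd--5th digits of both hands (thumb-involving
#'   angles are excluded from the pooled plot, matching the reported
#'   layout), using repetition-mean TAF per angle;
#' * `regression`: per-activity OLS of markerless on marker-based TAF on
#'   the same pooled pairs;
#' * `ba_pairs`: the pooled pairs with means/differences for plotting.
#'
#' @param rmse_df Data frame with columns `participant`, `hand`,
#'   `activity`, `repetition`, `angle_name`, `rmse`, `mean_abs_diff`.
#' @param taf_df Data frame with columns `participant`, `hand`,
#'   `activity`, `repetition`, `angle_name`, `source`, `taf`.
#' @return List of data frames `rmse_by_digit`, `bland_altman`,
#'   `regression`, `ba_pairs`.
#' @export
aggregate_report <- function(rmse_df, taf_df) {
  empty <- list(
    rmse_by_digit = data.frame(), bland_altman = data.frame(),
    regression = data.frame(), ba_pairs = data.frame())
  if (is.null(rmse_df) || nrow(rmse_df) == 0L) return(empty)

  lead_digit <- function(name) sub("[-_].*$", "", name)
  rmse_df$digit <- lead_digit(rmse_df$angle_name)
  agg <- stats::aggregate(rmse ~ activity + digit, rmse_df,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  rmse_by_digit <- data.frame(activity = agg$activity, digit = agg$digit,
                              mean_rmse = agg$rmse[, "mean"],
                              sd_rmse = agg$rmse[, "sd"],
                              n = agg$rmse[, "n"])

  ba_rows <- list(); reg_rows <- list(); pair_rows <- list()
  if (!is.null(taf_df) && nrow(taf_df)) {
    taf_df$digit <- lead_digit(taf_df$angle_name)
    pooled <- taf_df[taf_df$digit != "thumb", ]
    # repetition-mean TAF per participant/hand/activity/angle/source
    m <- stats::aggregate(
      taf ~ participant + hand + activity + angle_name + source, pooled,
      mean, na.rm = TRUE)
    wide <- stats::reshape(m, idvar = c("participant", "hand", "activity",
                                        "angle_name"),
                           timevar = "source", direction = "wide")
    ml_col <- "taf.markerless"; ref_col <- "taf.projected_marker"
    for (act in intersect(activity_levels(), unique(wide$activity))) {
      w <- wide[wide$activity == act, ]
      if (!all(c(ml_col, ref_col) %in% names(w))) next
      ok <- !is.na(w[[ml_col]]) & !is.na(w[[ref_col]])
      w <- w[ok, ]
      if (nrow(w) < 3L) next
      ba <- bland_altman(w[[ml_col]], w[[ref_col]])
      lr <- linreg_r2(w[[ml_col]], w[[ref_col]])
      ba_rows[[act]] <- data.frame(
        activity = act, bias = ba$bias, sd_diff = ba$sd_diff,
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper, n = ba$n)
      reg_rows[[act]] <- data.frame(
        activity = act, slope = lr$slope, intercept = lr$intercept,
        r2 = lr$r2, n = lr$n)
      pair_rows[[act]] <- data.frame(
        activity = act, participant = w$participant, hand = w$hand,
        angle_name = w$angle_name, taf_markerless = w[[ml_col]],
        taf_marker = w[[ref_col]], mean = ba$means, diff = ba$diffs)
    }
  }
  list(rmse_by_digit = rmse_by_digit,
       bland_altman = if (length(ba_rows)) do.call(rbind, ba_rows)
                      else data.frame(),
       regression = if (length(reg_rows)) do.call(rbind, reg_rows)
                    else data.frame(),
       ba_pairs = if (length(pair_rows)) do.call(rbind, pair_rows)
                  else data.frame())
}
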