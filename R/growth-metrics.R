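## Tumor doubling time from volume time series.

#' Estimate tumor doubling time in an exponential growth window
#'
#' Fits a least-squares line to (day, log2 volume) over the observations
#' whose volume lies inside the window (inclusive bounds, default
#' 200-400 mm3, the conventional exponential phase for subcutaneous models);
#' the doubling time is 1/slope. The estimate is invariant to rescaling all
#' volumes or shifting all times.
#'
#' Window membership decided on raw measured volumes is biased under
#' measurement noise: points near the window edges are included or excluded
#' according to the sign of their error, which flattens the fitted slope and
#' inflates the doubling time. Membership is therefore refined on the fitted
#' curve: after an initial fit on the raw in-window points, membership is
#' recomputed from the fitted volumes and the line refit, iterating to a
#' fixed point (`refine_window = 0` disables this and reproduces the naive
#' raw-volume selection).
#'
#' @param times observation days (strictly increasing).
#' @param volumes volumes in mm3 (> 0), same length as `times`.
#' @param window volume window `c(v_lo, v_hi)` in mm3.
#' @param refine_window maximum number of fitted-curve membership
#'   refinements (default 10; iteration stops at a fixed point).
#' @return list with `td_days`, `slope` (doublings/day), `r_squared`,
#'   `n_points`, and `flag` in `ok` / `too_few_points` / `nonpositive_slope`.
#'   `td_days` is NA unless `flag == "ok"`.
#' @export
doubling_time <- function(times, volumes, window = c(200, 400),
                          refine_window = 10L) {
  stopifnot(length(times) == length(volumes))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  ly <- log2(volumes)
  lw <- log2(window)
  inw <- ly >= lw[1] & ly <= lw[2]
  fit_in <- function(inw) lm(ly[inw] ~ times[inw])
  bad <- function(flag, inw, slope = NA_real_, r2 = NA_real_)
    list(td_days = NA_real_, slope = slope, r_squared = r2,
         n_points = sum(inw), flag = flag)
  if (sum(inw) < 2) return(bad("too_few_points", inw))
  fit <- fit_in(inw)
  for (i in seq_len(refine_window)) {
    cf <- coef(fit)
    if (!is.finite(cf[2]) || cf[2] <= 0) break
    fitted_all <- cf[1] + cf[2] * times
    new_inw <- fitted_all >= lw[1] & fitted_all <= lw[2]
    if (sum(new_inw) < 2 || identical(new_inw, inw)) break
    inw <- new_inw
    fit <- fit_in(inw)
  }
  slope <- unname(coef(fit)[2])
  y <- ly[inw]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  if (!is.finite(slope) || slope <= 0)
    return(bad("nonpositive_slope", inw, slope, r2))
  list(td_days = 1 / slope, slope = slope, r_squared = r2,
       n_points = sum(inw), flag = "ok")
}

#' Doubling times for a cohort volume table
#'
#' @param volumes_table data.frame with `mouse_id`, `day`, `volume_mm3`.
#' @param window passed to [doubling_time()].
#' @return data.frame with `mouse_id`, `td_days`, `r_squared`, `n_points`,
#'   `flag`.
#' @export
doubling_time_table <- function(volumes_table, window = c(200, 400)) {
  out <- lapply(split(volumes_table, volumes_table$mouse_id), function(v) {
    v <- v[order(v$day), ]
    td <- doubling_time(v$day, v$volume_mm3, window)
    data.frame(mouse_id = v$mouse_id[1], td_days = td$td_days,
               r_squared = td$r_squared, n_points = td$n_points,
               flag = td$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out); rownames(out) <- NULL
  out
}
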