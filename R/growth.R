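#' Blank-subtracted OD600 growth curve
#'
#' @param strain_id Strain identifier.
#' @param medium Growth medium, one of `"LB"`, `"MAA"`, `"M63"`.
#' @param times Measurement times in hours, strictly increasing.
#' @param od Blank-subtracted OD600 readings. Non-positive readings are
#'   dropped (with their time points) before analysis.
#' @return An object of class `growth_curve` with fields `strain_id`,
#'   `medium`, `times`, `od`.
#' @export
growth_curve <- function(strain_id = "strain", medium = c("LB", "MAA", "M63"),
                         times, od) {
  medium <- match.arg(medium)
  stopifnot(is.numeric(times), is.numeric(od), length(times) == length(od))
  keep <- !is.na(od) & od > 0
  times <- times[keep]
  od <- od[keep]
  if (length(times) < 2) {
    stop("growth curve needs at least 2 positive readings", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(strain_id = as.character(strain_id), medium = medium,
                 times = as.numeric(times), od = as.numeric(od)),
            class = "growth_curve")
}

as_growth_curve <- function(curve) {
  if (inherits(curve, "growth_curve")) return(curve)
  if (is.data.frame(curve) && all(c("time_h", "od600") %in% names(curve))) {
    return(growth_curve(times = curve$time_h, od = curve$od600))
  }
  stop("expected a growth_curve or a data frame with time_h/od600 columns",
       call. = FALSE)
}

# All O(1)-per-window regression statistics from cumulative sums.
window_stats <- function(tt, yy, i, j) {
  n <- j - i + 1
  sx <- sum(tt[i:j]); sy <- sum(yy[i:j])
  sxx <- sum(tt[i:j]^2); syy <- sum(yy[i:j]^2); sxy <- sum(tt[i:j] * yy[i:j])
  den_x <- n * sxx - sx^2
  den_y <- n * syy - sy^2
  slope <- if (den_x > 0) (n * sxy - sx * sy) / den_x else 0
  r2 <- if (den_x > 0 && den_y > .Machine$double.eps * n) {
    (n * sxy - sx * sy)^2 / (den_x * den_y)
  } else NA_real_
  list(slope = slope, r2 = r2)
}

#' Locate the exponential-phase window of a growth curve
#'
#' Scans contiguous windows of at least `min_points` readings whose OD lies
#' inside `od_range` and returns the window whose log-linear fit has the
#' largest slope among windows with r-squared at or above `r2_threshold`.
#' When no window reaches the threshold the best-r-squared window is returned
#' and flagged. A zero-variance (flat) response has undefined r-squared and is
#' likewise returned flagged with slope 0.
#'
#' `min_points` may also be given as a fraction of the in-range readings via
#' `min_frac` (the larger of the two is used); wide windows suppress the
#' upward slope bias that short noisy windows incur under max-slope selection.
#'
#' @param curve A [growth_curve()] (or data frame with `time_h`, `od600`).
#' @param min_points Minimum readings per candidate window.
#' @param od_range OD600 interval treated as early-exponential.
#' @param r2_threshold Minimum r-squared for an unflagged window.
#' @param min_frac Optional minimum window length as a fraction of the
#'   in-range readings (e.g. `0.7`); `NULL` disables it.
#' @return List with `start`, `end` (indices into the curve), `slope`
#'   (d ln OD / dt over the window), `r2` and `flagged`.
#' @export
detect_exponential_window <- function(curve, min_points = 5,
                                      od_range = c(0.01, 0.1),
                                      r2_threshold = 0.99, min_frac = NULL) {
  curve <- as_growth_curve(curve)
  sel <- curve$od >= od_range[1] & curve$od <= od_range[2]
  if (sum(sel) < min_points) {
    stop("no exponential window: fewer than ", min_points,
         " readings inside OD range [", od_range[1], ", ", od_range[2], "]",
         call. = FALSE)
  }
  # contiguous runs of in-range readings
  runs <- rle(sel)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- NULL      # best qualifying (r2 >= threshold) window, by slope
  best_any <- NULL  # best window overall, by r2 (fallback)
  best_any_r2 <- -Inf
  tt <- curve$times
  yy <- log(curve$od)
  for (k in which(runs$values & runs$lengths >= min_points)) {
    lo <- starts[k]; hi <- ends[k]
    mp <- min_points
    if (!is.null(min_frac)) {
      mp <- max(mp, ceiling(min_frac * (hi - lo + 1)))
    }
    if (hi - lo + 1 < mp) next
    for (i in lo:(hi - mp + 1)) {
      for (j in (i + mp - 1):hi) {
        st <- window_stats(tt, yy, i, j)
        cand <- list(start = i, end = j, slope = st$slope, r2 = st$r2)
        if (!is.na(st$r2) && st$r2 >= r2_threshold) {
          if (is.null(best) || st$slope > best$slope) best <- cand
        }
        r2cmp <- if (is.na(st$r2)) -1 else st$r2
        if (r2cmp > best_any_r2) {
          best_any <- cand
          best_any_r2 <- r2cmp
        }
      }
    }
  }
  if (is.null(best) && is.null(best_any)) {
    stop("no exponential window: no candidate window of ", min_points,
         " readings", call. = FALSE)
  }
  out <- if (!is.null(best)) c(best, flagged = FALSE) else
    c(best_any, flagged = TRUE)
  out$r2 <- if (is.na(out$r2)) 0 else out$r2
  out
}

#' Exponential growth rate from an OD600 curve
#'
#' The growth rate is the slope of `ln(OD)` against time over the selected
#' exponential window, in 1/h: the multi-point generalisation of
#' `mu = ln(Cj/Ci) / (tj - ti)`, to which it reduces exactly when the window
#' has two points.
#'
#' @inheritParams detect_exponential_window
#' @return An object of class `growth_estimate`: list with `mu` (1/h),
#'   `window_start`, `window_end`, `r2` and `flagged`.
#' @examples
#' cv <- growth_curve(times = 0:5, od = 0.01 * 2^(0:5))
#' growth_rate(cv)$mu  # log(2)
#' @export
growth_rate <- function(curve, min_points = 5, od_range = c(0.01, 0.1),
                        r2_threshold = 0.99, min_frac = NULL) {
  curve <- as_growth_curve(curve)
  w <- detect_exponential_window(curve, min_points = min_points,
                                 od_range = od_range,
                                 r2_threshold = r2_threshold,
                                 min_frac = min_frac)
  structure(list(mu = w$slope, window_start = w$start, window_end = w$end,
                 r2 = w$r2, flagged = w$flagged),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("mu = %.4g /h (window %d..%d, r2 = %.4f%s)\n", x$mu,
              x$window_start, x$window_end, x$r2,
              if (x$flagged) ", flagged" else ""))
  invisible(x)
}
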