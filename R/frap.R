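#' Construct a FRAP trace
#'
#' Bundles one fluorescence-recovery-after-photobleaching record: frame
#' times, the bleached region-of-interest intensity, an unbleached reference
#' intensity (used for acquisition-bleaching correction), and the index of
#' the first post-bleach frame.
#'
#' @param time Frame times in seconds, strictly increasing.
#' @param roi ROI mean intensity per frame (arbitrary units, >= 0).
#' @param reference Reference-region mean intensity per frame (> 0).
#' @param bleach_frame 1-based index of the first frame acquired after the
#'   bleach pulse; frames before it form the pre-bleach baseline, so it
#'   must be at least 2.
#' @return A tibble of class `"frap_trace"` with columns `time`, `roi`,
#'   `reference` and attribute `bleach_frame`.
#' @export
frap_trace <- function(time, roi, reference, bleach_frame) {
  n <- length(time)
  if (length(roi) != n || length(reference) != n) {
    stop("time, roi and reference must have equal length", call. = FALSE)
  }
  if (n < 2L || any(diff(time) <= 0)) {
    stop("time must be strictly increasing with >= 2 frames", call. = FALSE)
  }
  if (any(roi < 0)) stop("roi intensities must be >= 0", call. = FALSE)
  bleach_frame <- as.integer(bleach_frame)
  if (bleach_frame < 2L || bleach_frame > n) {
    stop("bleach_frame must lie in [2, n_frames] so that at least one ",
         "pre-bleach frame exists", call. = FALSE)
  }
  structure(
    tibble::tibble(time = as.numeric(time), roi = as.numeric(roi),
                   reference = as.numeric(reference)),
    class = c("frap_trace", class(tibble::tibble())),
    bleach_frame = bleach_frame
  )
}

#' Bleach-correct and normalize a FRAP trace
#'
#' Double normalization: the ROI intensity is divided frame-by-frame by the
#' unbleached reference (removing shared acquisition photobleaching and
#' illumination drift), then scaled so the pre-bleach mean is exactly 1.
#'
#' @param trace A [frap_trace()].
#' @return The trace with an added `normalized` column; pre-bleach mean of
#'   `normalized` is 1.
#' @export
bleach_correct_and_normalize <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (any(trace$reference <= 0)) {
    stop("reference intensity must be > 0 at every frame", call. = FALSE)
  }
  bleach_frame <- attr(trace, "bleach_frame")
  ratio <- trace$roi / trace$reference
  pre <- mean(ratio[seq_len(bleach_frame - 1L)])
  if (pre <= 0) stop("pre-bleach ROI signal is not positive", call. = FALSE)
  trace$normalized <- ratio / pre
  trace
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of the post-bleach portion of a normalized FRAP trace
#' to \deqn{I(t) = F + (P - F)\,(1 - e^{-k (t - t_{bleach})})} where the
#' post-bleach floor `F` is fixed at the first post-bleach value and the
#' plateau `P` and rate `k` are free. Derived quantities: half-time of
#' recovery \eqn{t_{1/2} = \ln 2 / k} and mobile fraction
#' \eqn{M = (P - F)/(1 - F)} (clamped to \[0, 1\]).
#'
#' @param trace A [frap_trace()], normalized with
#'   [bleach_correct_and_normalize()] (done automatically if the
#'   `normalized` column is absent).
#' @param k_bounds Allowed range for the rate constant, per second.
#' @return An object of class `"frap_fit"`: a list with elements `rate_k`,
#'   `plateau`, `post_bleach_floor`, `mobile_fraction`, `half_time`,
#'   `residual_sse`, `n_frames_fit`, and `data` (the post-bleach frames
#'   with fitted values).
#' @details Initialization is deterministic: `k0` is the reciprocal of the
#'   time taken to reach half of the apparent recovery, and `P0` the mean of
#'   the last 10% of frames. If the optimizer fails, a small grid of rescaled
#'   `k0` values is retried before erroring with diagnostics. A post-bleach
#'   segment with zero variance (no recovery at all) short-circuits to
#'   `mobile_fraction = 0` with an undefined (`NA`) rate.
#' @export
fit_recovery <- function(trace, k_bounds = c(1e-4, 1e3)) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!"normalized" %in% names(trace)) {
    trace <- bleach_correct_and_normalize(trace)
  }
  bleach_frame <- attr(trace, "bleach_frame")
  post <- trace[seq(bleach_frame, nrow(trace)), ]
  if (nrow(post) < 5L) {
    stop("need at least 5 post-bleach frames to fit recovery", call. = FALSE)
  }
  t0 <- post$time[1]
  tt <- post$time - t0
  y <- post$normalized
  f_floor <- y[1]

  if (stats::sd(y) == 0) {
    return(new_frap_fit(NA_real_, f_floor, f_floor, 0, post, y))
  }

  # deterministic initialization
  p0 <- mean(y[tt >= stats::quantile(tt, 0.9)])
  half_level <- f_floor + 0.5 * (p0 - f_floor)
  i_half <- if (p0 > f_floor) which(y >= half_level)[1] else NA_integer_
  k0 <- if (!is.na(i_half) && tt[i_half] > 0) 1 / tt[i_half] else 1
  k0 <- min(max(k0, k_bounds[1] * 10), k_bounds[2] / 10)

  fit <- NULL
  for (mult in c(1, 0.1, 10, 0.01, 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f_floor + (P - f_floor) * (1 - exp(-k * tt)),
        start = list(P = p0, k = k0 * mult),
        lower = c(P = -Inf, k = k_bounds[1]),
        upper = c(P = Inf, k = k_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("FRAP recovery fit did not converge (floor = ", signif(f_floor, 4),
         ", init P = ", signif(p0, 4), ", init k = ", signif(k0, 4), ")",
         call. = FALSE)
  }
  est <- stats::coef(fit)
  new_frap_fit(unname(est["k"]), unname(est["P"]), f_floor,
               mobile = NA, post = post, fitted = stats::fitted(fit))
}

#' @noRd
new_frap_fit <- function(k, plateau, floor, mobile = NA, post, fitted) {
  if (is.na(mobile)) {
    mobile <- if (floor >= 1) 0 else (plateau - floor) / (1 - floor)
    mobile <- min(max(mobile, 0), 1)
  }
  post$fitted <- as.numeric(fitted)
  structure(
    list(
      rate_k = k,
      plateau = plateau,
      post_bleach_floor = floor,
      mobile_fraction = mobile,
      half_time = log(2) / k,
      residual_sse = sum((post$normalized - post$fitted)^2),
      n_frames_fit = nrow(post),
      data = post
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP single-exponential recovery fit (", x$n_frames_fit,
      " post-bleach frames)\n", sep = "")
  cat(sprintf("  rate k        : %.4g /s\n", x$rate_k))
  cat(sprintf("  half-time     : %.4g s\n", x$half_time))
  cat(sprintf("  floor / plateau: %.4g / %.4g\n",
              x$post_bleach_floor, x$plateau))
  cat(sprintf("  mobile fraction: %.4g\n", x$mobile_fraction))
  cat(sprintf("  residual SSE  : %.4g\n", x$residual_sse))
  invisible(x)
}

#' Tidy a FRAP fit
#'
#' @param x A `frap_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return One-row tibble of the fitted and derived parameters.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    rate_k = x$rate_k,
    half_time = x$half_time,
    post_bleach_floor = x$post_bleach_floor,
    plateau = x$plateau,
    mobile_fraction = x$mobile_fraction
  )
}

#' One-row fit summary
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-quality measures.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    n_frames_fit = x$n_frames_fit,
    residual_sse = x$residual_sse,
    rmse = sqrt(x$residual_sse / x$n_frames_fit)
  )
}

#' Plot a FRAP fit
#'
#' Normalized post-bleach data with the fitted single-exponential recovery
#' curve overlaid.
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$normalized),
                        colour = "grey40", size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d95f02",
                       linewidth = 1) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity",
                  title = sprintf("FRAP recovery: k = %.3g /s, mobile = %.2f",
                                  object$rate_k, object$mobile_fraction)) +
    ggplot2::theme_minimal()
}
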