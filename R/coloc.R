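#' Derive a region-of-interest mask from the reference channel
#'
#' Thresholds one z-section of the reference (red/mCherry) channel to mark
#' the cytoplasmic foci whose pixels enter the colocalization statistic.
#' `method = "otsu"` picks the threshold automatically from the intensity
#' histogram; `method = "fixed"` uses a user-supplied cutoff.
#'
#' @param section Numeric matrix (y by x) of non-negative intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Cutoff intensity for `method = "fixed"`; pixels strictly
#'   above it are in the mask.
#' @return Logical matrix of the same shape.
#' @export
roi_mask_from_reference <- function(section, method = c("otsu", "fixed"),
                                    threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(section), is.numeric(section))
  if (method == "otsu") {
    rng <- range(section)
    if (rng[1] == rng[2]) {
      stop("Otsu thresholding undefined for a constant image", call. = FALSE)
    }
    threshold <- EBImage::otsu(section, range = rng, levels = 256L)
  } else if (is.null(threshold)) {
    stop("method = 'fixed' requires a threshold", call. = FALSE)
  }
  section > threshold
}

#' Pearson correlation of two channels within a mask
#'
#' Sample Pearson correlation of the two channels' intensities over the
#' masked pixels only — the per-section colocalization statistic.
#'
#' @param ch_a,ch_b Numeric matrices of identical shape.
#' @param mask Logical matrix of the same shape; `TRUE` pixels enter.
#' @return Pearson R in \[-1, 1\].
#' @export
pearson_in_mask <- function(ch_a, ch_b, mask) {
  stopifnot(identical(dim(ch_a), dim(ch_b)), identical(dim(ch_a), dim(mask)))
  a <- ch_a[mask]
  b <- ch_b[mask]
  if (length(a) < 2L) {
    stop("mask must select at least 2 pixels", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: zero variance within mask", call. = FALSE)
  }
  stats::cor(a, b)
}

#' @noRd
as_section_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[1]), function(z) x[z, , ]))
  }
  if (is.matrix(x)) return(list(x))
  stop("expected a matrix, a (z, y, x) array, or a list of matrices",
       call. = FALSE)
}

#' Per-section colocalization of a two-channel stack
#'
#' Splits a two-channel z-stack into single sections and computes the
#' Pearson colocalization of the channels within the per-section ROI mask.
#' Sections whose mask has fewer than 2 pixels or a zero-variance channel
#' are marked unusable and skipped.
#'
#' @param channel_a,channel_b Stacks as (z, y, x) arrays or lists of
#'   matrices.
#' @param masks Matching stack of logical masks, or `NULL` to derive each
#'   section's mask from `channel_b` (the reference channel) by Otsu.
#' @return A tibble with columns `section`, `n_pixels`, `r`, `usable`.
#' @seealso [cell_colocalization()]
#' @export
coloc_sections <- function(channel_a, channel_b, masks = NULL) {
  a <- as_section_list(channel_a)
  b <- as_section_list(channel_b)
  if (length(a) != length(b)) {
    stop("channel stacks must have the same number of sections", call. = FALSE)
  }
  m <- if (is.null(masks)) {
    lapply(b, roi_mask_from_reference)
  } else {
    lapply(as_section_list(masks), function(x) {
      if (!is.logical(x)) x <- x > 0
      x
    })
  }
  purrr::map_dfr(seq_along(a), function(i) {
    r <- tryCatch(pearson_in_mask(a[[i]], b[[i]], m[[i]]),
                  error = function(e) NA_real_)
    tibble::tibble(section = i, n_pixels = sum(m[[i]]),
                   r = r, usable = !is.na(r))
  })
}

#' Per-cell colocalization value
#'
#' Aggregates per-section Pearson R values into one value per cell: the
#' unweighted mean across usable sections. The number of skipped sections
#' is reported with a message.
#'
#' @inheritParams coloc_sections
#' @return Mean Pearson R (a single number).
#' @export
cell_colocalization <- function(channel_a, channel_b, masks = NULL) {
  per_section <- coloc_sections(channel_a, channel_b, masks)
  n_bad <- sum(!per_section$usable)
  if (n_bad > 0L) {
    message(n_bad, " section(s) skipped (too few masked pixels or zero variance)")
  }
  if (all(!per_section$usable)) {
    stop("no usable sections for colocalization", call. = FALSE)
  }
  mean(per_section$r[per_section$usable])
}

#' Sample an intensity profile along a polyline
#'
#' Samples image intensity at equal arc-length steps along a polyline,
#' averaging across a perpendicular width (bilinear interpolation,
#' 0-based pixel-center coordinates). Used to read out fluorescence along
#' an axoneme traced from base to tip; positions are rescaled to the
#' normalized length \[0, 1\].
#'
#' @param section Numeric matrix (y by x).
#' @param polyline Two-column matrix or data frame of (x, y) vertices in
#'   pixels, 0-based, at least 2 points.
#' @param width Perpendicular averaging width in pixels (default 3).
#' @param step Arc-length sampling step in pixels (default 1).
#' @return A tibble with columns `position` (in \[0, 1\]),
#'   `distance_px`, and `intensity`.
#' @export
sample_profile <- function(section, polyline, width = 3, step = 1) {
  stopifnot(is.matrix(section), width >= 1, step > 0)
  pl <- as.matrix(as.data.frame(polyline)[, 1:2])
  if (nrow(pl) < 2L) stop("polyline needs at least 2 points", call. = FALSE)
  nx <- ncol(section)
  ny <- nrow(section)
  if (any(pl[, 1] < 0 | pl[, 1] > nx - 1 | pl[, 2] < 0 | pl[, 2] > ny - 1)) {
    stop("polyline lies outside image bounds", call. = FALSE)
  }
  seg <- diff(pl)
  seg_len <- sqrt(rowSums(seg^2))
  total_len <- sum(seg_len)
  if (total_len <= 0) stop("polyline has zero length", call. = FALSE)
  s_grid <- seq(0, total_len, by = step)
  if (s_grid[length(s_grid)] < total_len) s_grid <- c(s_grid, total_len)
  cum <- c(0, cumsum(seg_len))
  # point and unit tangent at arc length s
  locate <- function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(seg))
    frac <- if (seg_len[i] > 0) (s - cum[i]) / seg_len[i] else 0
    p <- pl[i, ] + frac * seg[i, ]
    u <- seg[i, ] / seg_len[i]
    c(p, u)
  }
  pts <- t(vapply(s_grid, locate, numeric(4)))
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(width, 1))
  # normal = tangent rotated 90 degrees
  xq <- sweep(outer(-pts[, 4], offsets), 1, pts[, 1], `+`)
  yq <- sweep(outer(pts[, 3], offsets), 1, pts[, 2], `+`)
  # clamp perpendicular samples to the image so edge lines stay usable
  xq <- pmin(pmax(xq, 0), nx - 1)
  yq <- pmin(pmax(yq, 0), ny - 1)
  vals <- pracma::interp2(x = 0:(nx - 1), y = 0:(ny - 1), Z = section,
                          xp = as.vector(xq), yp = as.vector(yq),
                          method = "linear")
  vals <- matrix(vals, nrow = nrow(pts))
  tibble::tibble(
    position = s_grid / total_len,
    distance_px = s_grid,
    intensity = rowMeans(vals)
  )
}

#' Normalize a signal profile against a reference profile
#'
#' Pointwise ratio of a signal profile (e.g. a GFP-tagged dynein subunit) to
#' a reference profile (e.g. co-expressed membrane-RFP) sampled along the
#' same polyline, giving an illumination- and geometry-corrected readout
#' along the normalized axoneme length.
#'
#' @param signal,reference Profile tibbles from [sample_profile()] sampled
#'   at identical positions.
#' @param floor Intensities below `floor` in the reference are an error
#'   (guards against dividing by background).
#' @return A tibble of class `"axoneme_profile"` with columns `position`,
#'   `signal`, `reference`, `ratio`.
#' @export
normalize_profile <- function(signal, reference, floor = 0) {
  if (!isTRUE(all.equal(signal$position, reference$position))) {
    stop("signal and reference profiles must share positions", call. = FALSE)
  }
  ref <- reference$intensity
  if (any(ref <= floor)) {
    stop("reference profile is <= floor at some positions; cannot form ratio",
         call. = FALSE)
  }
  sig <- signal$intensity
  structure(
    tibble::tibble(
      position = signal$position,
      signal = sig,
      reference = ref,
      ratio = sig / ref
    ),
    class = c("axoneme_profile", class(tibble::tibble()))
  )
}

#' Plot a normalized axoneme profile
#'
#' @param object An `axoneme_profile` from [normalize_profile()].
#' @param ... Unused.
#' @return A ggplot object of ratio versus normalized axoneme position.
#' @export
autoplot.axoneme_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$ratio)) +
    ggplot2::geom_line(colour = "#1b9e77", linewidth = 0.8) +
    ggplot2::labs(x = "normalized axoneme length",
                  y = "signal / membrane reference") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of enrichment scores
#'
#' @param object An `apms_scores` object from [score_experiment()].
#' @param ... Unused.
#' @return A ggplot of Z score against log2 fold-change, significant groups
#'   and the bait highlighted.
#' @export
autoplot.apms_scores <- function(object, ...) {
  d <- tibble::as_tibble(unclass2(object))
  d$class <- ifelse(d$is_bait, "bait",
                    ifelse(d$significant, "significant", "background"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = .data$z,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "z_threshold"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(bait = "#d95f02",
                                            significant = "#1b9e77",
                                            background = "grey60")) +
    ggplot2::labs(x = "log2 fold-change (bait / control)", y = "Z score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
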