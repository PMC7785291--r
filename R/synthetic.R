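#' Simulate a spectral-count pulldown experiment
#'
#' Generates PSM count tables for a bait pulldown and its GFP-only control
#' under a multinomial sampling model with known ground truth. Each control
#' run draws `depth_ctrl` PSMs from the background binding propensities `w`;
#' each bait run draws `depth_expt` PSMs from `w` re-weighted by the
#' configured enrichment factors (the bait's own group by
#' `bait_enrichment`, designated preys by their factors, all other groups
#' unchanged). Conditioning on a fixed total per run mirrors the
#' compositional normalization of the fold-change statistic.
#'
#' @param n_groups Number of protein groups in the simulated proteome.
#' @param abundance_weights Positive background propensities, one per
#'   group (normalized internally). Default: log-uniform over two orders
#'   of magnitude, drawn once per call under `seed`.
#' @param bait_group Group id of the bait (default the first group).
#' @param prey_enrichments Named numeric vector mapping group ids to
#'   enrichment factors `e >= 1` in the bait pulldown.
#' @param bait_enrichment Enrichment factor of the bait's own group.
#' @param depth_expt,depth_ctrl Total PSMs per bait / control run.
#' @param n_bait_runs,n_ctrl_runs Number of replicate runs per side.
#' @param bait_label Label given to the bait runs (controls are labelled
#'   `"GFP_control"`).
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A list with elements `psm` (PSM tibble of all runs, zero counts
#'   omitted), `pairing` (a [pairing_spec()] tibble), and `truth`
#'   (tibble of `group_id`, `weight`, `enrichment`, `is_bait`).
#' @export
simulate_psm_experiment <- function(n_groups = 200,
                                    abundance_weights = NULL,
                                    bait_group = NULL,
                                    prey_enrichments = NULL,
                                    bait_enrichment = 1,
                                    depth_expt = 10000,
                                    depth_ctrl = 10000,
                                    n_bait_runs = 1,
                                    n_ctrl_runs = 2,
                                    bait_label = "bait",
                                    seed = 1) {
  stopifnot(n_groups >= 1, depth_expt >= 1, depth_ctrl >= 1,
            n_bait_runs >= 1, n_ctrl_runs >= 1, bait_enrichment >= 1)
  if (!is.null(prey_enrichments) && any(prey_enrichments < 1)) {
    stop("prey enrichment factors must be >= 1", call. = FALSE)
  }
  wd <- max(3L, nchar(n_groups))
  ids <- sprintf("g%0*d", wd, seq_len(n_groups))
  if (is.null(bait_group)) bait_group <- ids[1]
  if (!bait_group %in% ids) {
    stop("bait_group must be one of the simulated group ids", call. = FALSE)
  }
  if (!is.null(prey_enrichments) &&
      !all(names(prey_enrichments) %in% ids)) {
    stop("prey_enrichments names must be simulated group ids", call. = FALSE)
  }
  withr::with_seed(seed, {
    w <- if (is.null(abundance_weights)) {
      10^stats::runif(n_groups, 0, 2)
    } else {
      if (length(abundance_weights) != n_groups || any(abundance_weights <= 0)) {
        stop("abundance_weights must be ", n_groups, " positive values",
             call. = FALSE)
      }
      as.numeric(abundance_weights)
    }
    w <- w / sum(w)
    e <- rep(1, n_groups)
    names(e) <- ids
    e[bait_group] <- bait_enrichment
    if (!is.null(prey_enrichments)) {
      e[names(prey_enrichments)] <- pmax(e[names(prey_enrichments)],
                                         prey_enrichments)
    }
    w_expt <- w * e
    w_expt <- w_expt / sum(w_expt)

    draw_run <- function(run_id, label, depth, prob) {
      counts <- as.integer(stats::rmultinom(1, depth, prob))
      keep <- counts > 0L
      tibble::tibble(run_id = run_id, bait_label = label,
                     protein_id = ids[keep], psm_count = counts[keep])
    }
    bait_runs <- sprintf("expt_%d", seq_len(n_bait_runs))
    ctrl_runs <- sprintf("ctrl_%d", seq_len(n_ctrl_runs))
    psm <- dplyr::bind_rows(
      purrr::map(bait_runs, ~draw_run(.x, bait_label, depth_expt, w_expt)),
      purrr::map(ctrl_runs, ~draw_run(.x, "GFP_control", depth_ctrl, w))
    )
    list(
      psm = psm,
      pairing = pairing_spec(bait_label, bait_runs, ctrl_runs),
      truth = tibble::tibble(group_id = ids, weight = w,
                             enrichment = unname(e),
                             is_bait = ids == bait_group)
    )
  })
}

#' Simulate a FRAP trace with known kinetics
#'
#' Generates a time-intensity record following single-exponential recovery
#' \eqn{I(t) = F + (P-F)(1 - e^{-k t'})} after the bleach (with floor
#' \eqn{F = 1 - } `bleach_depth` and plateau \eqn{P = F + M(1-F)}),
#' multiplied by an acquisition-photobleaching decay
#' \eqn{e^{-b t}} that also affects the unbleached reference region, with
#' additive Gaussian noise on both recorded traces.
#'
#' @param k Recovery rate constant, per second.
#' @param mobile_fraction Mobile fraction `M` in \[0, 1\].
#' @param frame_interval Seconds between frames (default 0.2 s).
#' @param n_frames Number of frames (default 300).
#' @param noise_sd Gaussian noise standard deviation, as a fraction of the
#'   pre-bleach intensity.
#' @param acq_bleach_rate Acquisition photobleaching rate `b`, per second.
#' @param pre_bleach_frames Number of baseline frames before the bleach.
#' @param bleach_depth Fraction of ROI fluorescence removed by the bleach
#'   pulse (floor is `1 - bleach_depth`).
#' @param base_intensity Pre-bleach intensity in arbitrary units.
#' @param seed Integer seed.
#' @return A [frap_trace()] with attribute `truth` (list of the generating
#'   parameters).
#' @export
simulate_frap_trace <- function(k = 0.1, mobile_fraction = 0.8,
                                frame_interval = 0.2, n_frames = 300,
                                noise_sd = 0.02, acq_bleach_rate = 0.005,
                                pre_bleach_frames = 10, bleach_depth = 0.8,
                                base_intensity = 100, seed = 1) {
  stopifnot(k > 0, mobile_fraction >= 0, mobile_fraction <= 1,
            frame_interval > 0, n_frames > pre_bleach_frames + 4,
            noise_sd >= 0, acq_bleach_rate >= 0,
            pre_bleach_frames >= 1, bleach_depth > 0, bleach_depth <= 1)
  withr::with_seed(seed, {
    time <- (seq_len(n_frames) - 1) * frame_interval
    bleach_frame <- pre_bleach_frames + 1L
    t_bleach <- time[bleach_frame]
    floor_f <- 1 - bleach_depth
    plateau <- floor_f + mobile_fraction * (1 - floor_f)
    true_norm <- ifelse(
      time < t_bleach, 1,
      floor_f + (plateau - floor_f) * (1 - exp(-k * (time - t_bleach)))
    )
    decay <- exp(-acq_bleach_rate * time)
    roi <- base_intensity * true_norm * decay +
      stats::rnorm(n_frames, 0, noise_sd * base_intensity)
    reference <- base_intensity * decay +
      stats::rnorm(n_frames, 0, noise_sd * base_intensity)
    roi <- pmax(roi, 0)
    reference <- pmax(reference, 1e-6)
    tr <- frap_trace(time, roi, reference, bleach_frame)
    attr(tr, "truth") <- list(k = k, mobile_fraction = mobile_fraction,
                              floor = floor_f, plateau = plateau,
                              acq_bleach_rate = acq_bleach_rate)
    tr
  })
}

#' Type-I-error calibration of the enrichment Z test under the null
#'
#' Simulates replicate bait/control pulldown pairs with equal-abundance
#' groups and no enriched preys, scores every group with the enrichment Z
#' statistic, and reports how often the one-sided test at `z_threshold`
#' (nominal 5% level by default) rejects. Used to verify that the test's
#' false-positive rate stays at or below its nominal level.
#'
#' @param n_pairs Number of independent bait/control pairs.
#' @param n_groups Groups per simulated proteome (equal abundances).
#' @param depth Total PSMs sampled per run (one bait and one control run
#'   per pair).
#' @param z_threshold One-sided critical value.
#' @param seed Integer seed; per-pair seeds are derived from it.
#' @return A list with `n_tests`, `n_significant`,
#'   `fraction_significant` and `fraction_not_significant`.
#' @export
simulate_null_calibration <- function(n_pairs = 1000, n_groups = 200,
                                      depth = 10000, z_threshold = 1.645,
                                      seed = 1) {
  pair_seeds <- withr::with_seed(seed, sample.int(2^31 - 2, n_pairs))
  w <- rep(1, n_groups)
  n_tests <- 0L
  n_sig <- 0L
  for (i in seq_len(n_pairs)) {
    sim <- simulate_psm_experiment(
      n_groups = n_groups, abundance_weights = w,
      depth_expt = depth, depth_ctrl = depth,
      n_bait_runs = 1, n_ctrl_runs = 1, seed = pair_seeds[i])
    cp <- combine_runs(sim$psm, sim$pairing, "bait")
    z <- z_score(cp)
    n_tests <- n_tests + length(z)
    n_sig <- n_sig + sum(z >= z_threshold)
  }
  list(n_tests = n_tests, n_significant = n_sig,
       fraction_significant = n_sig / n_tests,
       fraction_not_significant = 1 - n_sig / n_tests)
}

# Foci-phantom geometry constants, calibrated once so that under default
# noise the per-cell Pearson R lands near 0.85 at full sub-structure
# overlap and near 0.45 at complete partitioning.
foci_defaults <- list(
  sep_max = 3.2,    # centre-to-centre lobe separation at overlap = 0, px
  noise_sd = 24     # additive Gaussian noise, intensity units
)

#' Simulate a two-channel foci image pair
#'
#' Generates a two-channel z-stack of cytoplasmic foci emulating organelles
#' whose internal sub-structure overlap between the two labels is tunable:
#' at `overlap = 1` both channels label the same Gaussian sub-region of
#' every focus; at `overlap = 0` the two channels occupy lobes displaced to
#' opposite sides of the focus centre. Sections are independent.
#'
#' @param dim Stack dimensions `c(z, y, x)`.
#' @param n_foci Foci per section.
#' @param focus_radius Gaussian sigma of each sub-region lobe, pixels.
#' @param overlap Shared fraction of each focus's sub-structure, in
#'   \[0, 1\].
#' @param noise_sd Additive Gaussian noise (intensity units); the default
#'   is calibrated together with the lobe separation so the per-cell
#'   Pearson R is about 0.85 at `overlap = 1` and 0.45 at `overlap = 0`.
#' @param sep_max Centre-to-centre lobe separation at `overlap = 0`, in
#'   pixels (calibrated default; changing it changes the meaning of the
#'   `overlap` scale).
#' @param amplitude Peak lobe intensity above background.
#' @param background Constant background level.
#' @param seed Integer seed.
#' @return A list with `channel_a`, `channel_b` (arrays `(z, y, x)`),
#'   `masks` (logical array marking each focus's ROI), and `truth`
#'   (list of generator parameters and per-focus centres).
#' @export
simulate_foci_pair <- function(dim = c(4, 96, 96), n_foci = 12,
                               focus_radius = 3, overlap = 1,
                               noise_sd = foci_defaults$noise_sd,
                               sep_max = foci_defaults$sep_max,
                               amplitude = 200, background = 10,
                               seed = 1) {
  stopifnot(length(dim) == 3, overlap >= 0, overlap <= 1, n_foci >= 1,
            focus_radius > 0, noise_sd >= 0, sep_max >= 0)
  nz <- dim[1]; ny <- dim[2]; nx <- dim[3]
  sep <- sep_max * (1 - overlap)
  mask_r <- 2 * focus_radius + sep_max / 2
  margin <- ceiling(mask_r) + 1
  if (2 * margin >= min(ny, nx)) {
    stop("image too small for the focus geometry", call. = FALSE)
  }
  withr::with_seed(seed, {
    ch_a <- array(0, dim); ch_b <- array(0, dim); masks <- array(FALSE, dim)
    xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    yg <- matrix(rep(seq_len(ny), nx), ny, nx)
    centres <- vector("list", nz)
    for (z in seq_len(nz)) {
      cx <- stats::runif(n_foci, margin, nx - margin)
      cy <- stats::runif(n_foci, margin, ny - margin)
      th <- stats::runif(n_foci, 0, 2 * pi)
      a <- matrix(0, ny, nx); b <- matrix(0, ny, nx); m <- matrix(FALSE, ny, nx)
      for (i in seq_len(n_foci)) {
        ux <- cos(th[i]); uy <- sin(th[i])
        ax <- cx[i] - ux * sep / 2; ay <- cy[i] - uy * sep / 2
        bx <- cx[i] + ux * sep / 2; by <- cy[i] + uy * sep / 2
        a <- a + amplitude * exp(-((xg - ax)^2 + (yg - ay)^2) /
                                   (2 * focus_radius^2))
        b <- b + amplitude * exp(-((xg - bx)^2 + (yg - by)^2) /
                                   (2 * focus_radius^2))
        m <- m | ((xg - cx[i])^2 + (yg - cy[i])^2 <= mask_r^2)
      }
      ch_a[z, , ] <- background + a + stats::rnorm(ny * nx, 0, noise_sd)
      ch_b[z, , ] <- background + b + stats::rnorm(ny * nx, 0, noise_sd)
      masks[z, , ] <- m
      centres[[z]] <- cbind(x = cx, y = cy, theta = th)
    }
    list(channel_a = ch_a, channel_b = ch_b, masks = masks,
         truth = list(overlap = overlap, separation_px = sep,
                      focus_radius = focus_radius, noise_sd = noise_sd,
                      centres = centres))
  })
}

#' Simulate an axoneme phantom with a proximal-only signal
#'
#' Generates a two-channel single section containing a straight axoneme:
#' the reference channel (membrane label) is uniform along the full length,
#' while the signal channel is present only over the proximal fraction of
#' the length, emulating the proximally restricted localization of outer
#' dynein arm markers after assembly-factor knockdown. The transition edge
#' is smoothed over about one pixel.
#'
#' @param length_px Axoneme length in pixels.
#' @param proximal_fraction Fraction of the length (from the base) carrying
#'   signal, in \[0, 1\].
#' @param signal_level,reference_level Peak on-axis intensities above
#'   background.
#' @param noise_sd Additive Gaussian noise (intensity units).
#' @param width_sigma Gaussian cross-section sigma of the axoneme, pixels.
#' @param background Constant background level.
#' @param seed Integer seed.
#' @return A list with `signal`, `reference` (matrices), `polyline`
#'   (tibble of 0-based x, y tracing base to tip) and `truth`.
#' @export
simulate_axoneme_image <- function(length_px = 120, proximal_fraction = 1,
                                   signal_level = 150, reference_level = 100,
                                   noise_sd = 2, width_sigma = 1.5,
                                   background = 5, seed = 1) {
  stopifnot(length_px >= 10, proximal_fraction >= 0, proximal_fraction <= 1,
            signal_level > 0, reference_level > 0, noise_sd >= 0)
  ny <- 31L
  nx <- as.integer(length_px + 21L)
  x0 <- 10; y0 <- 15  # 0-based base of the axoneme
  withr::with_seed(seed, {
    xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
    yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
    cross <- exp(-(yg - y0)^2 / (2 * width_sigma^2))
    along <- (xg - x0) / length_px           # normalized axoneme position
    on_axoneme <- along >= 0 & along <= 1
    cut_x <- x0 + proximal_fraction * length_px
    envelope <- stats::plogis(cut_x - xg)    # ~1 px smooth edge
    reference <- background + reference_level * cross * on_axoneme +
      stats::rnorm(ny * nx, 0, noise_sd)
    signal <- background + signal_level * cross * on_axoneme * envelope +
      stats::rnorm(ny * nx, 0, noise_sd)
    polyline <- tibble::tibble(x = c(x0, x0 + length_px), y = c(y0, y0))
    list(signal = signal, reference = reference, polyline = polyline,
         truth = list(proximal_fraction = proximal_fraction,
                      signal_level = signal_level,
                      reference_level = reference_level))
  })
}
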