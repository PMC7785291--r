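#' Collapse protein-level PSMs to orthology groups
#'
#' Sums PSM counts of proteins belonging to the same orthology group within
#' each run, replacing `protein_id` by `group_id`. This mirrors the use of a
#' composite proteome in which homeologs and highly related entries are
#' merged into vertebrate-level orthology groups before any statistics.
#'
#' Proteins absent from the map are kept as singleton groups whose group id
#' equals the protein id (with a warning), so user-supplied partial maps do
#' not silently drop data.
#'
#' @param psm PSM tibble (see [read_psm_table()]).
#' @param ortho_map Mapping tibble with columns `protein_id`, `group_id`
#'   (see [read_ortho_map()]).
#' @return A PSM tibble whose `protein_id` column now holds group ids, with
#'   counts summed within `(run_id, group_id)`.
#' @export
collapse_to_groups <- function(psm, ortho_map) {
  psm <- validate_psm_table(psm, where = "in-memory table")
  idx <- match(psm$protein_id, ortho_map$protein_id)
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    warning(sum(unmapped), " protein id(s) absent from the orthogroup map; ",
            "kept as singleton groups", call. = FALSE)
  }
  gid <- ifelse(unmapped, psm$protein_id, ortho_map$group_id[idx])
  psm |>
    dplyr::mutate(protein_id = gid) |>
    dplyr::group_by(.data$run_id, .data$bait_label, .data$protein_id) |>
    dplyr::summarise(psm_count = as.integer(sum(.data$psm_count)),
                     .groups = "drop")
}

#' Pool bait and control replicate runs into a count pair
#'
#' Sums PSMs per group across the bait runs ("expt") and across the matched
#' GFP-only control runs ("ctrl") of one pairing. The statistical universe is
#' the union of groups observed (>= 1 PSM) on either side; groups absent on
#' one side enter with a zero there, and groups absent on both sides are
#' excluded.
#'
#' @param psm PSM tibble, typically already collapsed with
#'   [collapse_to_groups()] (the protein id column then holds group ids).
#' @param pairing Pairing tibble from [pairing_spec()] or
#'   [read_pairing_spec()].
#' @param bait_label Which bait's pairing to use when `pairing` covers
#'   several baits.
#' @return A count-pair tibble with columns `group_id`, `psm_expt`,
#'   `psm_ctrl` (sorted by `group_id`) and attributes `total_expt`,
#'   `total_ctrl`, `n_groups`, `bait_label`.
#' @export
combine_runs <- function(psm, pairing, bait_label) {
  pairing <- pairing[pairing$bait_label == bait_label, ]
  if (nrow(pairing) == 0L) {
    stop("No pairing entries for bait label ", dQuote(bait_label), call. = FALSE)
  }
  unknown <- setdiff(pairing$run_id, unique(psm$run_id))
  if (length(unknown) > 0L) {
    stop("Pairing references run id(s) absent from the PSM table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bait_runs <- pairing$run_id[pairing$role == "bait"]
  ctrl_runs <- pairing$run_id[pairing$role == "control"]
  pool <- function(runs) {
    psm[psm$run_id %in% runs, ] |>
      dplyr::group_by(group_id = .data$protein_id) |>
      dplyr::summarise(n = as.integer(sum(.data$psm_count)), .groups = "drop")
  }
  cp <- dplyr::full_join(pool(bait_runs), pool(ctrl_runs),
                         by = "group_id", suffix = c("_expt", "_ctrl")) |>
    dplyr::mutate(
      psm_expt = dplyr::coalesce(.data$n_expt, 0L),
      psm_ctrl = dplyr::coalesce(.data$n_ctrl, 0L)
    ) |>
    dplyr::filter(.data$psm_expt + .data$psm_ctrl >= 1L) |>
    dplyr::arrange(.data$group_id) |>
    dplyr::select("group_id", "psm_expt", "psm_ctrl")
  attr(cp, "total_expt") <- sum(cp$psm_expt)
  attr(cp, "total_ctrl") <- sum(cp$psm_ctrl)
  attr(cp, "n_groups") <- nrow(cp)
  attr(cp, "bait_label") <- bait_label
  cp
}

#' @noRd
as_count_vectors <- function(psm_expt, psm_ctrl) {
  if (is.data.frame(psm_expt)) {
    cp <- psm_expt
    psm_expt <- cp$psm_expt
    psm_ctrl <- cp$psm_ctrl
  }
  if (length(psm_expt) != length(psm_ctrl)) {
    stop("psm_expt and psm_ctrl must have equal length", call. = FALSE)
  }
  if (any(psm_expt < 0) || any(psm_ctrl < 0)) {
    stop("PSM counts must be non-negative", call. = FALSE)
  }
  list(expt = as.numeric(psm_expt), ctrl = as.numeric(psm_ctrl))
}

#' Pseudocounted log2 fold-change of spectral counts
#'
#' For each group i of a bait-versus-control count pair,
#' \deqn{FC_i = \log_2\frac{(PSM_{i,expt}+1)/\sum_j (PSM_{j,expt}+1)}
#'                         {(PSM_{i,ctrl}+1)/\sum_k (PSM_{k,ctrl}+1)}}
#' The +1 pseudocounts keep every fold-change finite, including for groups
#' seen on only one side.
#'
#' @param psm_expt Either a count-pair tibble from [combine_runs()] or a
#'   numeric vector of pooled bait PSM counts.
#' @param psm_ctrl Numeric vector of pooled control counts (ignored when a
#'   count pair is given).
#' @return Numeric vector of log2 fold-changes, one per group.
#' @export
fold_change <- function(psm_expt, psm_ctrl = NULL) {
  v <- as_count_vectors(psm_expt, psm_ctrl)
  log2(((v$expt + 1) / sum(v$expt + 1)) / ((v$ctrl + 1) / sum(v$ctrl + 1)))
}

#' One-sided enrichment Z statistic for spectral counts
#'
#' Two-proportion Z statistic on raw (un-pseudocounted) PSM frequencies.
#' With \eqn{f_i = PSM_i/\sum_j PSM_j} on each side and the pooled frequency
#' \eqn{f_{i,comb} = (PSM_{i,expt}+PSM_{i,ctrl})/(T_{expt}+T_{ctrl})},
#' \deqn{Z_i = \frac{f_{i,expt}-f_{i,ctrl}}
#'   {\sqrt{f_{i,comb}(1-f_{i,comb})/T_{expt} +
#'          f_{i,comb}(1-f_{i,comb})/T_{ctrl}}}}
#' where \eqn{T} are the per-side totals. When the denominator vanishes
#' (\eqn{f_{i,comb}} is 0 or 1) the statistic is set to 0 by convention.
#'
#' @inheritParams fold_change
#' @return Numeric vector of Z scores, one per group.
#' @export
z_score <- function(psm_expt, psm_ctrl = NULL) {
  v <- as_count_vectors(psm_expt, psm_ctrl)
  te <- sum(v$expt)
  tc <- sum(v$ctrl)
  if (te < 1 || tc < 1) {
    stop("z_score requires at least one PSM on each side", call. = FALSE)
  }
  f_comb <- (v$expt + v$ctrl) / (te + tc)
  se <- sqrt(f_comb * (1 - f_comb) * (1 / te + 1 / tc))
  z <- (v$expt / te - v$ctrl / tc) / se
  z[se == 0] <- 0
  z
}

#' One-sided upper-tail normal p-value
#'
#' \eqn{p = 1 - \Phi(z)} with \eqn{\Phi} the standard-normal CDF; tests for
#' enrichment in the bait pulldown relative to control.
#'
#' @param z Numeric vector of Z scores.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
p_value <- function(z) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard BH step-up adjustment across the groups of one experiment.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values (FDR, q-values) in original
#'   order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Score one APMS experiment against its GFP-only control
#'
#' Full enrichment pipeline for one bait: collapse proteins to orthology
#' groups, pool replicate runs into bait and control counts, then compute
#' for every group the pseudocounted log2 fold-change, one-sided Z score,
#' normal-tail p-value and BH FDR. Rows are ranked by Z (descending), ties
#' broken by fold-change then group id, the bait's own group is flagged
#' (retained as a positive control, not removed), and significance is
#' called at `z >= z_threshold`.
#'
#' @param psm PSM tibble (protein level).
#' @param ortho_map Protein-to-group mapping tibble, or `NULL` to skip
#'   collapsing (protein ids are then used as group ids directly).
#' @param pairing Pairing tibble from [pairing_spec()].
#' @param bait_label Bait whose pairing to score.
#' @param bait_group_id Group id of the bait protein itself.
#' @param z_threshold One-sided critical value for significance; the
#'   default 1.645 is the standard-normal 95% critical value.
#' @return A tibble of class `"apms_scores"` with one row per group and
#'   columns `group_id`, `psm_expt`, `psm_ctrl`, `f_expt`, `f_ctrl`,
#'   `f_comb`, `log2_fc`, `z`, `p`, `fdr`, `significant`, `is_bait`,
#'   plus attributes `bait_label`, `bait_group_id`, `z_threshold`,
#'   `total_expt`, `total_ctrl`, `n_groups`.
#' @examples
#' sim <- simulate_psm_experiment(n_groups = 50, depth_expt = 2000,
#'                                depth_ctrl = 2000, bait_enrichment = 50,
#'                                seed = 1)
#' scores <- score_experiment(sim$psm, NULL, sim$pairing,
#'                            bait_label = "bait", bait_group_id = "g001")
#' head(scores)
#' @export
score_experiment <- function(psm, ortho_map, pairing, bait_label,
                             bait_group_id, z_threshold = 1.645) {
  stopifnot(is.numeric(z_threshold), length(z_threshold) == 1L)
  if (!is.null(ortho_map)) {
    psm <- collapse_to_groups(psm, ortho_map)
  }
  cp <- combine_runs(psm, pairing, bait_label)
  te <- attr(cp, "total_expt")
  tc <- attr(cp, "total_ctrl")
  f_comb <- (cp$psm_expt + cp$psm_ctrl) / (te + tc)
  z <- z_score(cp)
  p <- p_value(z)
  p[f_comb %in% c(0, 1)] <- 1  # statistic undefined there; conservative
  res <- tibble::tibble(
    group_id = cp$group_id,
    psm_expt = cp$psm_expt,
    psm_ctrl = cp$psm_ctrl,
    f_expt = cp$psm_expt / te,
    f_ctrl = cp$psm_ctrl / tc,
    f_comb = f_comb,
    log2_fc = fold_change(cp),
    z = z,
    p = p,
    fdr = bh_adjust(p),
    significant = z >= z_threshold,
    is_bait = cp$group_id == bait_group_id
  ) |>
    dplyr::arrange(dplyr::desc(.data$z), dplyr::desc(.data$log2_fc),
                   .data$group_id)
  structure(res,
            class = c("apms_scores", class(res)),
            bait_label = bait_label,
            bait_group_id = bait_group_id,
            z_threshold = z_threshold,
            total_expt = te,
            total_ctrl = tc,
            n_groups = nrow(res))
}

#' @export
print.apms_scores <- function(x, ...) {
  cat("APMS enrichment scores - bait:", attr(x, "bait_label"),
      "(group", paste0(attr(x, "bait_group_id"), ")"), "\n")
  cat("  universe:", attr(x, "n_groups"), "groups;",
      "total PSMs expt/ctrl:", attr(x, "total_expt"), "/",
      attr(x, "total_ctrl"), "\n")
  cat("  significant at z >=", attr(x, "z_threshold"), ":",
      sum(x$significant), "group(s)\n")
  NextMethod()
  invisible(x)
}

#' Tidy an enrichment score table
#'
#' Returns the per-group results as a plain tibble (broom convention).
#'
#' @param x An `apms_scores` object from [score_experiment()].
#' @param ... Unused.
#' @return A tibble, one row per group.
#' @export
tidy.apms_scores <- function(x, ...) {
  tibble::as_tibble(unclass2(x))
}

#' One-row summary of an enrichment experiment
#'
#' @param x An `apms_scores` object.
#' @param ... Unused.
#' @return A one-row tibble: bait, universe size, totals, number of
#'   significant groups, top-ranked group and whether the bait ranked
#'   first.
#' @export
glance.apms_scores <- function(x, ...) {
  tibble::tibble(
    bait_label = attr(x, "bait_label"),
    n_groups = attr(x, "n_groups"),
    total_expt = attr(x, "total_expt"),
    total_ctrl = attr(x, "total_ctrl"),
    z_threshold = attr(x, "z_threshold"),
    n_significant = sum(x$significant),
    top_group = x$group_id[1],
    bait_ranked_first = isTRUE(x$is_bait[1])
  )
}

#' @noRd
unclass2 <- function(x) {
  class(x) <- setdiff(class(x), "apms_scores")
  attr(x, "bait_label") <- NULL
  attr(x, "bait_group_id") <- NULL
  attr(x, "z_threshold") <- NULL
  attr(x, "total_expt") <- NULL
  attr(x, "total_ctrl") <- NULL
  attr(x, "n_groups") <- NULL
  x
}
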