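#' Read a PSM count table
#'
#' Reads a long-form table of peptide-spectral-match (PSM) counts as exported
#' from an upstream search pipeline: one row per run, bait and protein, with
#' the number of PSMs observed for that protein in that run. The file must be
#' UTF-8, tab-separated, with a header line naming the columns `run_id`,
#' `bait_label`, `protein_id` and `psm_count`.
#'
#' @param path Path to a tab-separated file.
#'
#' @return A tibble with columns `run_id`, `bait_label`, `protein_id`
#'   (character) and `psm_count` (integer), in file order.
#'
#' @details Validation is strict: a missing column, a negative or
#'   non-integer count, or a duplicated `(run_id, protein_id)` pair each
#'   abort with an error naming the offending column or data line.
#'
#' @seealso [write_psm_table()], [collapse_to_groups()]
#' @export
read_psm_table <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("PSM table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_psm_table(raw, where = path)
}

#' @noRd
validate_psm_table <- function(raw, where = "psm table") {
  needed <- c("run_id", "bait_label", "protein_id", "psm_count")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("Malformed PSM table (", where, "): missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- suppressWarnings(as.numeric(raw$psm_count))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad) > 0L) {
    # +1 for the header line so the number matches the file
    stop("Invalid psm_count ", dQuote(raw$psm_count[bad[1]]),
         " at data line ", bad[1] + 1L, " of ", where,
         ": counts must be non-negative integers", call. = FALSE)
  }
  key <- paste(raw$run_id, raw$protein_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("Duplicate (run_id, protein_id) pair (",
         raw$run_id[dup[1]], ", ", raw$protein_id[dup[1]],
         ") at data line ", dup[1] + 1L, " of ", where, call. = FALSE)
  }
  tibble::tibble(
    run_id = as.character(raw$run_id),
    bait_label = as.character(raw$bait_label),
    protein_id = as.character(raw$protein_id),
    psm_count = as.integer(counts)
  )
}

#' Write a PSM count table
#'
#' Inverse of [read_psm_table()]: writes the tab-separated dialect that
#' `read_psm_table()` reads back unchanged.
#'
#' @param psm A PSM tibble (columns `run_id`, `bait_label`, `protein_id`,
#'   `psm_count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  psm <- validate_psm_table(psm, where = "in-memory table")
  readr::write_tsv(psm, path, progress = FALSE)
  invisible(path)
}

#' Read a protein-to-orthogroup mapping
#'
#' Reads the two-column, tab-separated mapping from protein identifiers to
#' orthology-group identifiers used to collapse homeologs and highly related
#' proteins before enrichment statistics. Duplicate identical rows are
#' tolerated; a protein mapped to two different groups is an error.
#'
#' @param path Path to a tab-separated file with header columns
#'   `protein_id` and `group_id`.
#' @return A tibble with character columns `protein_id` and `group_id`,
#'   one row per protein.
#' @seealso [collapse_to_groups()]
#' @export
read_ortho_map <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("Orthogroup map not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(c("protein_id", "group_id"), names(raw))
  if (length(missing) > 0L) {
    stop("Malformed orthogroup map: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  map <- dplyr::distinct(raw[, c("protein_id", "group_id")])
  conflict <- map$protein_id[duplicated(map$protein_id)]
  if (length(conflict) > 0L) {
    stop("Conflicting orthogroup assignment for protein(s): ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  map
}

#' Define bait/control run pairing
#'
#' Declares which runs of a PSM table form the bait pulldown and which form
#' its matched GFP-only control. Each bait pulldown is compared against its
#' own parallel control runs; bait and control run sets must be non-empty
#' and disjoint.
#'
#' @param bait_label Label of the bait this pairing scores.
#' @param bait_runs Character vector of run ids for the bait pulldown.
#' @param control_runs Character vector of run ids for the GFP-only control.
#' @return A tibble with columns `bait_label`, `run_id`, `role`
#'   (`"bait"` or `"control"`), one row per run.
#' @export
pairing_spec <- function(bait_label, bait_runs, control_runs) {
  stopifnot(is.character(bait_label), length(bait_label) == 1L)
  bait_runs <- as.character(bait_runs)
  control_runs <- as.character(control_runs)
  if (length(bait_runs) == 0L || length(control_runs) == 0L) {
    stop("bait_runs and control_runs must each contain at least one run id",
         call. = FALSE)
  }
  shared <- intersect(bait_runs, control_runs)
  if (length(shared) > 0L) {
    stop("Run id(s) assigned to both bait and control: ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    bait_label = bait_label,
    run_id = c(bait_runs, control_runs),
    role = rep(c("bait", "control"), c(length(bait_runs), length(control_runs)))
  )
}

#' Read a pairing specification from file
#'
#' @param path Tab-separated file with header columns `bait_label`,
#'   `run_id`, `role` where `role` is `bait` or `control`.
#' @return A pairing tibble as returned by [pairing_spec()].
#' @export
read_pairing_spec <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(c("bait_label", "run_id", "role"), names(raw))
  if (length(missing) > 0L) {
    stop("Malformed pairing spec: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(raw$role %in% c("bait", "control"))) {
    stop("Pairing spec role must be 'bait' or 'control'", call. = FALSE)
  }
  by_bait <- split(raw, raw$bait_label)
  out <- lapply(by_bait, function(d) {
    pairing_spec(d$bait_label[1],
                 d$run_id[d$role == "bait"],
                 d$run_id[d$role == "control"])
  })
  dplyr::bind_rows(out)
}

# Numeric columns of the results table, serialized in scientific notation
# with 6 decimal digits for reproducible diffs.
results_real_cols <- c("f_expt", "f_ctrl", "f_comb", "log2_fc", "z", "p", "fdr")

#' Write enrichment results (and optional network edge list)
#'
#' Writes the scored enrichment table produced by [score_experiment()] as a
#' tab-separated file, and optionally an edge list for spoke-diagram style
#' network visualization in which each significant non-bait prey becomes an
#' edge from the bait weighted by its log2 fold-change.
#'
#' @param scores Enrichment tibble from [score_experiment()] (or any tibble
#'   with the same columns plus, for edge export, a `bait_label` attribute
#'   or a single bait row flagged `is_bait`).
#' @param path Output path for the results table.
#' @param edges_path Optional output path for the bait-prey edge list
#'   (columns `bait`, `prey`, `weight`).
#' @return `path`, invisibly.
#' @details Real-valued columns are serialized in scientific notation with
#'   6 decimal digits (relative round-trip error below 1e-6); integer and
#'   logical columns exactly.
#' @export
write_results <- function(scores, path, edges_path = NULL) {
  needed <- c("group_id", "psm_expt", "psm_ctrl", results_real_cols,
              "significant", "is_bait")
  missing <- setdiff(needed, names(scores))
  if (length(missing) > 0L) {
    stop("Results table is incomplete: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(scores[needed])) {
    stop("Results table contains missing values; refusing to write",
         call. = FALSE)
  }
  out <- scores[needed]
  for (cl in results_real_cols) {
    out[[cl]] <- formatC(out[[cl]], digits = 6, format = "e")
  }
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(edges_path)) {
    bait <- attr(scores, "bait_label")
    if (is.null(bait)) {
      bait <- if (any(scores$is_bait)) scores$group_id[scores$is_bait][1] else "bait"
    }
    hits <- scores[scores$significant & !scores$is_bait, ]
    edges <- tibble::tibble(
      bait = rep(bait, nrow(hits)),
      prey = hits$group_id,
      weight = formatC(hits$log2_fc, digits = 6, format = "e")
    )
    readr::write_tsv(edges, edges_path, progress = FALSE)
  }
  invisible(path)
}

#' Read back a written enrichment results table
#'
#' @param path Path written by [write_results()].
#' @return A tibble with the same columns, numeric columns parsed back.
#' @export
read_results <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    group_id = readr::col_character(),
    psm_expt = readr::col_integer(),
    psm_ctrl = readr::col_integer(),
    significant = readr::col_logical(),
    is_bait = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
  raw
}
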