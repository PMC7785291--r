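# Small in-code fixtures shared across test files.

psm_tbl <- function(run_id, bait_label, protein_id, psm_count) {
  tibble::tibble(run_id = run_id, bait_label = bait_label,
                 protein_id = protein_id, psm_count = as.integer(psm_count))
}

# One bait run + one control run holding the given per-group counts.
psm_from_counts <- function(expt, ctrl, ids = sprintf("g%d", seq_along(expt))) {
  dplyr::bind_rows(
    psm_tbl("r_expt", "bait", ids[expt > 0], expt[expt > 0]),
    psm_tbl("r_ctrl", "GFP_control", ids[ctrl > 0], ctrl[ctrl > 0])
  )
}

simple_pairing <- function() pairing_spec("bait", "r_expt", "r_ctrl")

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
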