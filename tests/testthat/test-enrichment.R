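test_that("collapse_to_groups sums PSMs within run and group", {
  tab <- psm_tbl("r1", "b", c("A", "B", "C"), c(3, 4, 5))
  map <- tibble::tibble(protein_id = c("A", "B", "C"),
                        group_id = c("g1", "g1", "g2"))
  out <- collapse_to_groups(tab, map)
  expect_equal(out$psm_count[out$protein_id == "g1"], 7L)
  expect_equal(out$psm_count[out$protein_id == "g2"], 5L)
})

test_that("collapse_to_groups keeps runs separate and honors identity maps", {
  tab <- psm_tbl(c("r1", "r2"), "b", c("A", "A"), c(2, 5))
  map <- tibble::tibble(protein_id = "A", group_id = "g1")
  out <- collapse_to_groups(tab, map)
  expect_equal(out$psm_count[out$run_id == "r1"], 2L)
  expect_equal(out$psm_count[out$run_id == "r2"], 5L)

  tab2 <- psm_tbl("r1", "b", c("A", "B"), c(1, 2))
  ident <- tibble::tibble(protein_id = c("A", "B"), group_id = c("A", "B"))
  expect_equal(dplyr::arrange(collapse_to_groups(tab2, ident), protein_id),
               dplyr::arrange(tab2, protein_id))
})

test_that("unmapped proteins become singleton groups with a warning", {
  tab <- psm_tbl("r1", "b", c("A", "X"), c(1, 2))
  map <- tibble::tibble(protein_id = "A", group_id = "g1")
  expect_warning(out <- collapse_to_groups(tab, map), "singleton")
  expect_true("X" %in% out$protein_id)
})

test_that("combine_runs pools replicates and builds the union universe", {
  tab <- dplyr::bind_rows(
    psm_tbl("e1", "b", c("g1", "g2"), c(4, 1)),
    psm_tbl("c1", "GFP", "g1", 1),
    psm_tbl("c2", "GFP", c("g1", "g3"), c(2, 6))
  )
  pairing <- pairing_spec("b", "e1", c("c1", "c2"))
  cp <- combine_runs(tab, pairing, "b")
  expect_equal(cp$psm_ctrl[cp$group_id == "g1"], 3L)   # summed across runs
  expect_equal(cp$psm_ctrl[cp$group_id == "g2"], 0L)   # expt-only group kept
  expect_equal(cp$psm_expt[cp$group_id == "g3"], 0L)   # ctrl-only group kept
  expect_equal(attr(cp, "n_groups"), 3L)               # union universe
  expect_equal(attr(cp, "total_expt"), 5L)
  expect_equal(attr(cp, "total_ctrl"), 9L)
  expect_error(combine_runs(tab, pairing_spec("b", "e1", "missing"), "b"),
               "absent")
})

test_that("fold_change matches hand-computed pseudocount values", {
  expect_equal(fold_change(c(5, 5), c(5, 5)), c(0, 0))
  # sums of (PSM+1) are 13 on both sides, so ratios are 10/1, 1/10, 2/2
  expect_equal(fold_change(c(9, 0, 1), c(0, 9, 1)),
               c(log2(10), -log2(10), 0))
  expect_equal(fold_change(c(0, 7), c(0, 7))[1], 0)  # absent in both
})

test_that("z_score matches hand-computed two-proportion values", {
  expect_equal(z_score(c(10, 90), c(10, 90)), c(0, 0))
  # f_comb = 0.055, SE = sqrt(0.055 * 0.945 * 0.02)
  z <- z_score(c(10, 90), c(1, 99))[1]
  expect_equal(z, 0.09 / sqrt(0.055 * 0.945 * 0.02), tolerance = 1e-12)
  expect_equal(round(z, 4), 2.7915)
  # single-group universe: f_comb = 1, conventionally z = 0
  expect_equal(z_score(5, 3), 0)
  expect_error(z_score(c(0, 0), c(1, 2)), "at least one PSM")
})

test_that("p_value is the one-sided upper normal tail", {
  expect_equal(p_value(0), 0.5)
  expect_equal(p_value(1.645), 0.05, tolerance = 1e-3)
  expect_equal(signif(p_value(2.7915), 3), 0.00262)
  expect_equal(p_value(c(-1, 2)), oracle_p(c(-1, 2)), tolerance = 1e-12)
})

test_that("bh_adjust reproduces the step-up adjustment", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("score_experiment ranks a strongly enriched group first", {
  scores <- score_experiment(psm_from_counts(c(30, 5, 5), c(5, 5, 30)),
                             NULL, simple_pairing(), "bait", "g1")
  expect_equal(scores$group_id[1], "g1")
  expect_equal(scores$log2_fc[1], log2(31 / 6), tolerance = 1e-12)
  # f_comb = 0.4375, totals 40/40
  expect_equal(scores$z[1],
               0.625 / sqrt(0.4375 * 0.5625 * 0.05), tolerance = 1e-12)
  expect_equal(round(scores$z[1], 3), 5.634)
  expect_true(scores$significant[1])
  expect_true(scores$is_bait[1])
})

test_that("score_experiment calls nothing significant under exact symmetry", {
  scores <- score_experiment(psm_from_counts(c(8, 8, 8), c(8, 8, 8)),
                             NULL, simple_pairing(), "bait", "g1")
  expect_equal(sum(scores$significant), 0L)
  expect_true(all(scores$z == 0))
  expect_true(all(scores$fdr >= 0 & scores$fdr <= 1))
})

test_that("the simulated bait is recovered as the top hit", {
  sim <- simulate_psm_experiment(n_groups = 100, depth_expt = 5000,
                                 depth_ctrl = 5000, bait_enrichment = 50,
                                 seed = 1)
  scores <- score_experiment(sim$psm, NULL, sim$pairing, "bait", "g001")
  expect_true(scores$is_bait[1])
  g <- glance(scores)
  expect_true(g$bait_ranked_first)
  expect_equal(g$n_groups, nrow(scores))
})

test_that("tidy and glance return plain tibbles", {
  scores <- score_experiment(psm_from_counts(c(9, 1), c(1, 9)), NULL,
                             simple_pairing(), "bait", "g1")
  td <- tidy(scores)
  expect_false(inherits(td, "apms_scores"))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(glance(scores)), 1L)
})

test_that("swapping expt and ctrl negates fold-changes and z exactly", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    e <- stats::rpois(n, 5)
    c2 <- stats::rpois(n, 5)
    keep <- e + c2 >= 1
    e <- e[keep]; c2 <- c2[keep]
    if (sum(e) < 1 || sum(c2) < 1) next
    expect_equal(fold_change(e, c2), -fold_change(c2, e), tolerance = 1e-14)
    expect_equal(z_score(e, c2), -z_score(c2, e), tolerance = 1e-14)
  }
})

test_that("pseudocounted frequencies are normalized to 1", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    e <- stats::rpois(n, 3)
    expect_equal(sum((e + 1) / sum(e + 1)), 1, tolerance = 1e-12)
  }
})

test_that("z is strictly increasing in the group's bait count at fixed totals", {
  # move counts from group 2 into group 1, totals unchanged
  zs <- sapply(0:20, function(x) z_score(c(x, 20 - x, 30), c(10, 10, 30))[1])
  expect_true(all(diff(zs) > 0))
})

test_that("implementation matches brute-force oracles on random universes", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    e <- stats::rpois(n, 4)
    c2 <- stats::rpois(n, 4)
    keep <- e + c2 >= 1
    e <- e[keep]; c2 <- c2[keep]
    if (length(e) == 0 || sum(e) < 1 || sum(c2) < 1) next
    expect_equal(fold_change(e, c2), oracle_fc(e, c2), tolerance = 1e-9)
    z <- z_score(e, c2)
    expect_equal(z, oracle_z(e, c2), tolerance = 1e-9)
    p <- p_value(z)
    expect_equal(p, oracle_p(z), tolerance = 1e-9)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-9)
  }
})
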