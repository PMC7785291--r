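test_that("PSM simulation is bit-reproducible and respects depths", {
  s1 <- simulate_psm_experiment(n_groups = 50, depth_expt = 1234,
                                depth_ctrl = 777, n_ctrl_runs = 2, seed = 9)
  s2 <- simulate_psm_experiment(n_groups = 50, depth_expt = 1234,
                                depth_ctrl = 777, n_ctrl_runs = 2, seed = 9)
  expect_identical(s1$psm, s2$psm)
  totals <- s1$psm |>
    dplyr::group_by(run_id) |>
    dplyr::summarise(n = sum(psm_count))
  expect_equal(totals$n[totals$run_id == "expt_1"], 1234L)
  expect_true(all(totals$n[grepl("^ctrl", totals$run_id)] == 777L))
})

test_that("PSM simulation validates enrichment factors and weights", {
  expect_error(simulate_psm_experiment(prey_enrichments = c(g002 = 0.5)),
               ">= 1")
  expect_error(simulate_psm_experiment(n_groups = 5,
                                       abundance_weights = c(1, 2)),
               "positive values")
  expect_error(simulate_psm_experiment(n_groups = 5, bait_group = "nope"),
               "group ids")
})

test_that("empirical frequencies converge to the enriched weights", {
  n <- 100
  sim <- simulate_psm_experiment(n_groups = n,
                                 abundance_weights = rep(1, n),
                                 bait_enrichment = 10,
                                 prey_enrichments = c(g050 = 5),
                                 depth_expt = 1e6, depth_ctrl = 1e6,
                                 n_ctrl_runs = 1, seed = 3)
  e <- rep(1, n); e[1] <- 10; e[50] <- 5
  w_expt <- e / sum(e)
  counts <- sim$psm |>
    dplyr::filter(run_id == "expt_1") |>
    dplyr::arrange(protein_id)
  freq <- counts$psm_count / sum(counts$psm_count)
  expect_lt(max(abs(freq - w_expt[match(counts$protein_id,
                                        sim$truth$group_id)])), 0.005)
})

test_that("detection power is non-decreasing in the enrichment factor", {
  n <- 50
  power_at <- function(e) {
    hits <- sapply(1:40, function(s) {
      sim <- simulate_psm_experiment(
        n_groups = n, abundance_weights = rep(1, n),
        prey_enrichments = c(g025 = e), depth_expt = 5000,
        depth_ctrl = 5000, n_ctrl_runs = 1, seed = 1000 * e + s)
      cp <- combine_runs(sim$psm, sim$pairing, "bait")
      z <- z_score(cp)
      z[cp$group_id == "g025"] >= 1.645
    })
    mean(hits)
  }
  pw <- sapply(c(1, 2, 5, 10, 50), power_at)
  expect_true(all(diff(pw) >= 0))
  expect_lt(pw[1], 0.3)      # near the nominal level under the null
  expect_equal(pw[5], 1)     # a 50x prey is always caught at this depth
})

test_that("FRAP trace simulation is reproducible and analytic when clean", {
  t1 <- simulate_frap_trace(seed = 5)
  t2 <- simulate_frap_trace(seed = 5)
  expect_identical(t1$roi, t2$roi)

  tr <- simulate_frap_trace(k = 0.2, mobile_fraction = 0.5, noise_sd = 0,
                            acq_bleach_rate = 0, bleach_depth = 0.9,
                            base_intensity = 1, n_frames = 50,
                            pre_bleach_frames = 5, seed = 1)
  tb <- tr$time[6]
  model <- ifelse(tr$time < tb, 1,
                  0.1 + (0.55 - 0.1) * (1 - exp(-0.2 * (tr$time - tb))))
  expect_equal(tr$roi, model, tolerance = 1e-12)
  expect_equal(tr$reference, rep(1, 50), tolerance = 1e-12)
})

test_that("acquisition bleaching decays both channels multiplicatively", {
  tr <- simulate_frap_trace(noise_sd = 0, acq_bleach_rate = 0.01,
                            base_intensity = 100, seed = 1)
  expect_equal(tr$reference, 100 * exp(-0.01 * tr$time), tolerance = 1e-12)
  norm <- bleach_correct_and_normalize(tr)
  expect_equal(norm$normalized[1:10], rep(1, 10), tolerance = 1e-12)
})

test_that("foci phantoms are reproducible and perfectly correlated when clean", {
  f1 <- simulate_foci_pair(seed = 21)
  f2 <- simulate_foci_pair(seed = 21)
  expect_identical(f1$channel_a, f2$channel_a)
  expect_identical(f1$masks, f2$masks)

  clean <- simulate_foci_pair(dim = c(2, 96, 96), overlap = 1, noise_sd = 0,
                              seed = 2)
  r <- suppressMessages(
    cell_colocalization(clean$channel_a, clean$channel_b, clean$masks))
  expect_equal(r, 1, tolerance = 1e-9)
})

test_that("full overlap always correlates above complete partitioning", {
  for (s in 1:8) {
    sim1 <- simulate_foci_pair(dim = c(2, 96, 96), overlap = 1, seed = s)
    r1 <- suppressMessages(
      cell_colocalization(sim1$channel_a, sim1$channel_b, sim1$masks))
    sim0 <- simulate_foci_pair(dim = c(2, 96, 96), overlap = 0, seed = s)
    r0 <- suppressMessages(
      cell_colocalization(sim0$channel_a, sim0$channel_b, sim0$masks))
    expect_gt(r1, r0)
  }
})

test_that("axoneme phantoms are reproducible with the stated geometry", {
  a1 <- simulate_axoneme_image(seed = 6)
  a2 <- simulate_axoneme_image(seed = 6)
  expect_identical(a1$signal, a2$signal)

  full <- simulate_axoneme_image(proximal_fraction = 1, noise_sd = 0, seed = 1)
  np <- normalize_profile(sample_profile(full$signal, full$polyline),
                          sample_profile(full$reference, full$polyline))
  # on-axis ratio approaches signal_level / reference_level
  mid <- np$ratio[np$position > 0.1 & np$position < 0.9]
  expect_lt(max(abs(mid - 150 / 100)), 0.05)

  prox <- simulate_axoneme_image(proximal_fraction = 0.2, noise_sd = 0,
                                 seed = 1)
  npp <- normalize_profile(sample_profile(prox$signal, prox$polyline),
                           sample_profile(prox$reference, prox$polyline))
  expect_true(all(npp$ratio[npp$position > 0.3] < 0.2))
  expect_true(all(npp$ratio[npp$position < 0.15] > 1))
})
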