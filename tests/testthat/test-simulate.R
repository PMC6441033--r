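test_that("simulated maps are symmetric, integer, non-negative and reproducible", {
  cfg <- simulation_config(seed = 5, n_bins = 80, depth = 2e5)
  r1 <- simulate_contact_map(cfg)
  r2 <- simulate_contact_map(cfg)
  M <- r1$map$counts
  expect_identical(M, t(M))
  expect_true(all(M >= 0))
  expect_identical(M, round(M))
  expect_identical(M, r2$map$counts)
  r3 <- simulate_contact_map(simulation_config(seed = 6, n_bins = 80, depth = 2e5))
  expect_false(identical(M, r3$map$counts))
})

test_that("bare-decay expected counts are proportional to 1/|i-j| and empirically flat", {
  cfg <- simulation_config(seed = 2, n_bins = 60, decay_exponent = -1, depth = 5e6)
  E <- expected_contact_map(cfg)$counts
  d <- abs(outer(1:60, 1:60, "-"))
  off <- d > 0
  expect_equal(E[off] * d[off] / (E[1, 2] * 1), rep(1, sum(off)), tolerance = 1e-12)
  # empirical mean count at distance s, divided by configured decay, is flat
  M <- simulate_contact_map(cfg)$map$counts
  ratio <- sapply(1:30, function(s) {
    i <- 1:(60 - s)
    mean(M[cbind(i, i + s)]) * s
  })
  expect_lt(diff(range(ratio)) / mean(ratio), 0.15)
})

test_that("TAD intra boost shows up at the configured magnitude", {
  cfg <- simulation_config(seed = 9, n_bins = 60, depth = 1e6,
                           tad_spec = data.frame(start_bin = 20, end_bin = 30,
                                                 intra_boost = 3))
  r <- simulate_contact_map(cfg)
  E <- r$truth$expected
  M <- r$map$counts
  inside <- matrix(FALSE, 60, 60)
  inside[21:30, 21:30] <- TRUE
  off <- abs(outer(1:60, 1:60, "-")) > 0 & upper.tri(M)
  # observed/expected-at-unit-boost ratio: compare against the generative means
  base <- E / ifelse(inside, 3, 1)
  ratio_in <- sum(M[inside & off]) / sum(base[inside & off])
  ratio_out <- sum(M[!inside & off]) / sum(base[!inside & off])
  se <- 3 * sqrt(sum(E[inside & off])) / sum(base[inside & off])
  expect_lt(abs(ratio_in - 3 * ratio_out), 3 * se + 0.1)
})

test_that("perturbation weakens TAD boosts and drops loops before sampling", {
  tads <- data.frame(start_bin = 10, end_bin = 20, intra_boost = 3)
  loops <- data.frame(bin_i = c(2, 30), bin_j = c(8, 40), loop_boost = 5)
  cfg <- simulation_config(seed = 3, n_bins = 50, depth = 1e5,
                           tad_spec = tads, loop_spec = loops)
  r <- simulate_contact_map(cfg, perturbation_config(border_weaken_factor = 0.5,
                                                     loop_retention = 0))
  expect_equal(r$truth$true_tads$intra_boost, 2)  # 1 + 0.5 * (3 - 1)
  expect_true(is.null(r$truth$true_loops) || nrow(r$truth$true_loops) == 0)
})

test_that("peak sets honour dropout, jitter and novelty contracts", {
  cfg <- simulation_config(seed = 4, n_bins = 2000, depth = 1e5)
  ident <- simulate_peak_sets(cfg, perturbation_config(), n_peaks = 200)
  expect_equal(ident$treated[, c("start", "end")],
               ident$control[, c("start", "end")])
  allgone <- simulate_peak_sets(
    cfg, perturbation_config(peak_dropout = 1, novel_peak_rate = 0.5),
    n_peaks = 200)
  expect_true(all(grepl("^novel_", allgone$treated$name)))
  # dropout 0.4: dropped count is Binomial(1000, 0.4); 3 s.e. check
  pk <- simulate_peak_sets(cfg, perturbation_config(peak_dropout = 0.4),
                           n_peaks = 1000)
  frac <- length(pk$truth$dropped_peak_ids) / 1000
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 1000))
  # ground truth resolves into the emitted sets
  expect_true(all(pk$truth$kept_peak_ids %in% pk$treated$name))
  expect_true(all(pk$truth$dropped_peak_ids %in% pk$control$name))
  expect_false(any(pk$truth$dropped_peak_ids %in% pk$treated$name))
})

test_that("contact sets honour retention contracts", {
  cfg <- simulation_config(seed = 8, n_bins = 3000, depth = 1e5)
  ident <- simulate_contact_sets(cfg, perturbation_config(contact_retention = 1),
                                 n_contacts = 300)
  expect_identical(ident$control, ident$treated)
  gone <- simulate_contact_sets(cfg, perturbation_config(contact_retention = 0,
                                                         de_novo_rate = 1),
                                n_contacts = 300)
  expect_false(any(gone$control$id %in% gone$treated$id))
  cs <- simulate_contact_sets(cfg, perturbation_config(contact_retention = 0.3),
                              n_contacts = 2000)
  frac <- length(cs$truth$retained_contact_ids) / 2000
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  # minimum separation respected
  expect_true(all(cs$control$bin2 - cs$control$bin1 >= 2))
})

test_that("genome annotation keeps deserts gene-free with near-zero RNA", {
  cfg <- simulation_config(seed = 6, n_bins = 500)
  all_desert <- simulate_genome_annotation(
    cfg, deserts = data.frame(start = 0, end = 500 * 20000))
  expect_equal(nrow(all_desert$genes), 0)
  ann1 <- simulate_genome_annotation(cfg)
  ann2 <- simulate_genome_annotation(cfg)
  expect_identical(ann1$rna, ann2$rna)
  expect_false(any(ann1$genes$start < ann1$deserts$end &
                     ann1$genes$end > ann1$deserts$start))
  in_desert <- ann1$genes$start >= ann1$deserts$start  # none expected; bins:
  bins <- seq(0, by = 20000, length.out = 500)
  desert_bins <- bins >= ann1$deserts$start & (bins + 20000) <= ann1$deserts$end
  expect_lt(mean(ann1$rna[desert_bins]), 0.05 * mean(ann1$rna))
})

test_that("FRET event generation inverts the proximity-ratio formula exactly", {
  preset <- list(weights = c(s = 1), means = 0.3, sds = 0)
  ev <- simulate_fret_events(preset, 50, seed = 1)
  expect_equal(ev$proximity_ratio, rep(0.3, 50), tolerance = 1e-9)
  # two states: label fraction within 3 s.e. of the weight
  ev2 <- simulate_fret_events(fret_preset("minus_drug"), 4000, seed = 2)
  w <- mean(ev2$state == "open")
  expect_lt(abs(w - 0.27), 3 * sqrt(0.27 * 0.73 / 4000))
  # round trip through the formula
  expect_equal(ev2$proximity_ratio,
               proximity_ratio(ev2$I_acceptor, ev2$I_donor), tolerance = 1e-12)
  expect_true(all(ev2$I_donor >= 0 & ev2$I_acceptor >= 0))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(tad_spec = data.frame(
    start_bin = c(0, 5), end_bin = c(10, 15), intra_boost = 2), n_bins = 20),
    "non-overlapping")
  expect_error(simulation_config(n_bins = 20, loop_spec = data.frame(
    bin_i = 5, bin_j = 25, loop_boost = 2)), "anchors")
  expect_error(simulation_config(n_bins = 20, bias_vector = rep(0, 20)),
               "positive")
  expect_error(perturbation_config(peak_dropout = 1.2), "probabilities")
  expect_error(perturbation_config(border_weaken_factor = 0), "border_weaken")
})
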