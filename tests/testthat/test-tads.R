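test_that("two dense blocks on weak background are segmented exactly", {
  n <- 10
  W <- matrix(0.1, n, n)
  W[1:5, 1:5] <- 5
  W[6:10, 6:10] <- 5
  diag(W) <- 0
  map <- as_balanced(contact_map(W, 20000))
  seg <- armatus_segment(map, gamma = 0.3, min_size = 2, max_size = 10)
  expect_equal(seg$domains$start_bin, c(0, 5))
  expect_equal(seg$domains$end_bin, c(5, 10))
  # exhaustive enumeration confirms the DP score is optimal
  brute <- armatus_brute_force(W, gamma = 0.3, min_size = 2, max_size = 10)
  expect_equal(seg$aggregate_score, brute, tolerance = 1e-10)
})

test_that("a uniform map yields no domains and zero aggregate score", {
  W <- matrix(3, 12, 12); diag(W) <- 0
  seg <- armatus_segment(as_balanced(contact_map(W, 20000)),
                         gamma = 0.3, min_size = 2, max_size = 12)
  expect_equal(nrow(seg$domains), 0)
  expect_equal(seg$aggregate_score, 0)
})

test_that("DP score equals brute-force enumeration on 50 fuzzed 8-bin maps", {
  for (s in 1:50) {
    m <- random_count_map(8, seed = 100 + s, lambda = 10)
    seg <- armatus_segment(as_balanced(m), gamma = 0.3,
                           min_size = 2, max_size = 8)
    brute <- armatus_brute_force(m$counts, gamma = 0.3,
                                 min_size = 2, max_size = 8)
    expect_equal(seg$aggregate_score, brute, tolerance = 1e-9)
  }
})

test_that("maps smaller than the minimum domain size give empty segmentations", {
  m <- as_balanced(random_count_map(2, seed = 1))
  seg <- armatus_segment(m, min_size = 3)
  expect_equal(nrow(seg$domains), 0)
})

test_that("border strength matches hand computations and is homogeneous", {
  # 4 bins, domains [0,2) and [2,4): within cells 4, between cells 1
  W <- matrix(1, 4, 4)
  W[1:2, 1:2] <- 4; W[3:4, 3:4] <- 4
  diag(W) <- 0
  map <- as_balanced(contact_map(W, 20000))
  seg <- structure(list(domains = data.frame(start_bin = c(0, 2),
                                             end_bin = c(2, 4),
                                             quality = c(1, 1)),
                        gamma = 0.3, aggregate_score = 2),
                   class = "tad_segmentation")
  b <- border_strength(map, seg)
  expect_equal(nrow(b), 1)
  expect_equal(b$strength, (4 + 4) / 4)  # = 2.0
  expect_equal(b$border_bin, 2)

  # uniform map, adjacent 2-bin domains: (c + c) / 4c = 0.5
  Wu <- matrix(7, 4, 4); diag(Wu) <- 0
  bu <- border_strength(as_balanced(contact_map(Wu, 20000)), seg)
  expect_equal(bu$strength, 0.5)

  # multiplying between-domain cells by k divides strength by k
  Wk <- W
  Wk[1:2, 3:4] <- Wk[1:2, 3:4] * 5
  Wk[3:4, 1:2] <- t(Wk[1:2, 3:4])
  bk <- border_strength(as_balanced(contact_map(Wk, 20000)), seg)
  expect_equal(bk$strength, b$strength / 5)

  # global rescaling leaves strength unchanged
  b10 <- border_strength(as_balanced(contact_map(W * 10, 20000)), seg)
  expect_equal(b10$strength, b$strength)
})

test_that("zero inter-domain sum flags the border invalid", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 3; W[3, 4] <- W[4, 3] <- 3
  seg <- structure(list(domains = data.frame(start_bin = c(0, 2),
                                             end_bin = c(2, 4), quality = 1),
                        gamma = 0.3, aggregate_score = 1),
                   class = "tad_segmentation")
  b <- border_strength(as_balanced(contact_map(W, 20000)), seg)
  expect_false(b$valid)
  expect_true(is.na(b$strength))
})

test_that("paired border comparison: identity, weakening replicates, hand t-test", {
  m <- as_balanced(random_count_map(30, seed = 42, lambda = 30))
  seg <- structure(list(domains = data.frame(
    start_bin = c(0, 10, 20), end_bin = c(10, 20, 30), quality = 1),
    gamma = 0.3, aggregate_score = 1), class = "tad_segmentation")
  cmpI <- compare_borders(m, m, seg)
  expect_equal(cmpI$summary$fraction_below_diagonal, 0)
  expect_null(cmpI$test)  # zero-variance differences: no t-test

  # the t-statistic matches a textbook hand computation on a 5-pair toy:
  # control (2.0, 2.5, 3.0, 2.2, 2.8), treated each 0.4 lower except one
  ctrl_s <- c(2.0, 2.5, 3.0, 2.2, 2.8)
  trt_s <- c(1.6, 2.1, 2.6, 1.8, 2.9)
  d <- trt_s - ctrl_s
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  tt <- t.test(trt_s, ctrl_s, paired = TRUE)
  expect_equal(unname(tt$statistic), t_hand, tolerance = 1e-12)

  # weakening only TAD boosts lowers the median treated border strength
  lower <- sapply(1:20, function(rep_i) {
    seed <- 300 + rep_i
    tads <- data.frame(start_bin = c(0, 25, 50, 75),
                       end_bin = c(25, 50, 75, 100),
                       intra_boost = 3)
    cfg <- simulation_config(seed = seed, n_bins = 100, depth = 2e6,
                             tad_spec = tads)
    ctrl <- simulate_contact_map(cfg)$map
    trt <- simulate_contact_map(cfg, perturbation_config(
      border_weaken_factor = 0.5))$map
    segc <- structure(list(domains = data.frame(
      start_bin = tads$start_bin, end_bin = tads$end_bin, quality = 1),
      gamma = 0.3, aggregate_score = 1), class = "tad_segmentation")
    cmp <- compare_borders(as_balanced(ctrl), as_balanced(trt), segc)
    cmp$summary$treated[2] < cmp$summary$control[2]
  })
  expect_gte(mean(lower), 0.95)
})

test_that("segmentation recovers generator TADs on the study configuration", {
  sim <- study_simulation_config(seed = 21, n_bins = 200, depth = 4e6)
  r <- simulate_contact_map(sim)
  bal <- iterative_correction(r$map)
  seg <- armatus_segment(bal, gamma = 0.3)
  expect_gt(nrow(seg$domains), 3)
  # most recovered borders sit within 2 bins of a true TAD edge
  true_edges <- sort(unique(c(r$truth$true_tads$start_bin,
                              r$truth$true_tads$end_bin)))
  found_edges <- sort(unique(c(seg$domains$start_bin, seg$domains$end_bin)))
  near <- sapply(found_edges, function(e) min(abs(true_edges - e)) <= 2)
  expect_gt(mean(near), 0.8)
})
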