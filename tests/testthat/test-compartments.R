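checkerboard_oe <- function(n = 40, eps = 0.4, block = 10) {
  lab <- rep(rep(c(1, -1), each = block), length.out = n)
  M <- 1 + eps * outer(lab, lab)
  diag(M) <- NA
  m <- as_balanced(contact_map(matrix(1, n, n) - diag(1, n), 20000))
  m$counts <- M
  m$oe <- TRUE
  list(map = m, lab = lab)
}

test_that("first principal component recovers a two-block checkerboard exactly", {
  cb <- checkerboard_oe()
  gc <- 0.4 + 0.05 * cb$lab
  pr <- compartment_profile(cb$map, gc)
  expect_equal(sign(pr$value), cb$lab)
  expect_true(all(pr$label[cb$lab > 0] == "A"))
  # flipping the gc track flips all labels
  pr2 <- compartment_profile(cb$map, 0.4 - 0.05 * cb$lab)
  expect_equal(sign(pr2$value), -cb$lab)
})

test_that("profile recovery on generator maps exceeds 95% sign agreement", {
  n <- 300
  comp <- 0.9 * sin(2 * pi * seq_len(n) / 60)
  cfg <- simulation_config(seed = 13, n_bins = n, depth = 5e6,
                           compartment_profile = comp,
                           compartment_strength = 0.8)
  r <- simulate_contact_map(cfg)
  bal <- iterative_correction(r$map)
  oe <- observed_over_expected(bal)
  pr <- compartment_profile(oe, cfg$gc_track)
  ok <- !is.na(pr$value) & abs(comp) > 0.05  # skip near-zero crossings
  expect_gt(mean(sign(pr$value[ok]) == sign(comp[ok])), 0.95)
})

test_that("recovery accuracy is monotone in compartment strength", {
  n <- 200
  comp <- 0.9 * sin(2 * pi * seq_len(n) / 50)
  agree <- sapply(c(0.1, 0.8), function(str) {
    cfg <- simulation_config(seed = 17, n_bins = n, depth = 1e6,
                             compartment_profile = comp,
                             compartment_strength = str)
    oe <- observed_over_expected(iterative_correction(
      simulate_contact_map(cfg)$map))
    pr <- compartment_profile(oe, cfg$gc_track)
    ok <- !is.na(pr$value) & abs(comp) > 0.05
    mean(sign(pr$value[ok]) == sign(comp[ok]))
  })
  expect_gt(agree[2], agree[1])
})

test_that("saddle aggregation: flat input, checkerboard corners, permutation invariance", {
  # all-ones O/E gives an all-ones saddle
  flat <- checkerboard_oe(eps = 0)
  prof <- list(value = seq(-1, 1, length.out = 40), label = rep(c("B", "A"), each = 20))
  sdl <- saddle(flat$map, prof, n_agg = 4)
  expect_equal(sdl$matrix, matrix(1, 4, 4))

  cb <- checkerboard_oe(n = 40, eps = 0.4)
  pr <- compartment_profile(cb$map, 0.4 + 0.05 * cb$lab)
  s <- saddle(cb$map, pr, n_agg = 4)
  expect_gt(s$matrix[1, 1], 1)  # (B,B) corner
  expect_gt(s$matrix[4, 4], 1)  # (A,A) corner
  expect_lt(s$matrix[1, 4], 1)  # anti-corner
  expect_lt(s$matrix[4, 1], 1)

  # permuting bins together with the profile leaves the saddle unchanged
  set.seed(9)
  perm <- sample(40)
  mp <- cb$map
  mp$counts <- cb$map$counts[perm, perm]
  prp <- pr
  prp$value <- pr$value[perm]
  sp <- saddle(mp, prp, n_agg = 4)
  expect_equal(sp$matrix, s$matrix, tolerance = 1e-12)

  expect_error(saddle(cb$map, pr, n_agg = 100), "n_agg")
})

test_that("saddle of a profile-shuffled map is flat", {
  n <- 300
  comp <- 0.9 * sin(2 * pi * seq_len(n) / 60)
  cfg <- simulation_config(seed = 19, n_bins = n, depth = 5e6,
                           compartment_profile = comp,
                           compartment_strength = 0.8)
  oe <- observed_over_expected(iterative_correction(
    simulate_contact_map(cfg)$map))
  pr <- compartment_profile(oe, cfg$gc_track)
  shuf <- pr
  set.seed(7)
  shuf$value <- sample(pr$value)
  s <- saddle(oe, shuf, n_agg = 10)
  expect_lt(max(abs(s$matrix - 1), na.rm = TRUE), 0.25)
  expect_lt(abs(compartmentalization_strength(s) - 1), 0.1)
})

test_that("compartment contact fractions: degenerate, hand-computed and perturbed cases", {
  # all bins labelled A
  m <- normalize_depth(random_count_map(6, seed = 3))
  allA <- list(value = rep(1, 6), label = rep("A", 6))
  expect_warning(fr <- compartment_contact_fractions(m, allA))
  expect_equal(unname(fr["AA"]), 1)

  # hand computation on a 4-bin map with labels (A, A, B, B), min distance 2
  W <- matrix(0, 4, 4)
  W[1, 3] <- W[3, 1] <- 2  # A-B
  W[1, 4] <- W[4, 1] <- 4  # A-B
  W[2, 4] <- W[4, 2] <- 6  # A-B
  m4 <- contact_map(W, 20000)
  m4$depth_normalized <- TRUE
  lab4 <- list(value = c(1, 1, -1, -1), label = c("A", "A", "B", "B"))
  fr4 <- suppressWarnings(compartment_contact_fractions(m4, lab4))
  expect_equal(unname(fr4), c(0, 0, 1))  # only AB pairs at distance >= 2

  # compartment mixing raises the AB fraction in >= 95% of replicates
  n <- 150
  comp <- 0.9 * sin(2 * pi * seq_len(n) / 50)
  up <- sapply(1:20, function(i) {
    cfg <- simulation_config(seed = 500 + i, n_bins = n, depth = 1e6,
                             compartment_profile = comp,
                             compartment_strength = 0.8)
    ctrl <- normalize_depth(simulate_contact_map(cfg)$map)
    trt <- normalize_depth(simulate_contact_map(
      cfg, perturbation_config(compartment_mix = 0.5))$map)
    truth <- list(value = comp, label = ifelse(comp > 0, "A", "B"))
    compartment_contact_fractions(trt, truth)["AB"] >
      compartment_contact_fractions(ctrl, truth)["AB"]
  })
  expect_gte(mean(up), 0.95)
})

test_that("compartmentalization strength summarizes segregation", {
  flat <- structure(list(matrix = matrix(1, 20, 20)), class = "saddle_matrix")
  expect_equal(compartmentalization_strength(flat), 1)
  cb <- checkerboard_oe(n = 60, eps = 0.4)
  pr <- compartment_profile(cb$map, 0.4 + 0.05 * cb$lab)
  expect_gt(compartmentalization_strength(saddle(cb$map, pr, 10)), 1)

  # mixing lowers the treated score in >= 95% of replicates
  n <- 150
  comp <- 0.9 * sin(2 * pi * seq_len(n) / 50)
  lower <- sapply(1:20, function(i) {
    cfg <- simulation_config(seed = 700 + i, n_bins = n, depth = 1e6,
                             compartment_profile = comp,
                             compartment_strength = 0.8)
    oec <- observed_over_expected(iterative_correction(
      simulate_contact_map(cfg)$map))
    oet <- observed_over_expected(iterative_correction(
      simulate_contact_map(cfg, perturbation_config(compartment_mix = 0.5))$map))
    prc <- compartment_profile(oec, cfg$gc_track)
    compartmentalization_strength(saddle(oet, prc, 10)) <
      compartmentalization_strength(saddle(oec, prc, 10))
  })
  expect_gte(mean(lower), 0.95)
})
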