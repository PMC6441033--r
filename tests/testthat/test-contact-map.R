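test_that("triplet I/O: hand-written file, round trip, empty list, parse errors", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "bins.bed")
  writeLines(c("chrS\t0\t20000", "chrS\t20000\t40000", "chrS\t40000\t60000"), bed)
  trip <- file.path(dir, "m.tsv")
  writeLines(c("0\t1\t5", "1\t2\t2"), trip)
  m <- read_triplets(trip, bed)
  expect_equal(m$counts, matrix(c(0, 5, 0, 5, 0, 2, 0, 2, 0), 3))
  expect_equal(m$resolution, 20000)

  writeLines(character(0), file.path(dir, "empty.tsv"))
  m0 <- read_triplets(file.path(dir, "empty.tsv"), bed)
  expect_equal(m0$counts, matrix(0, 3, 3))

  writeLines("0\t5\t1", file.path(dir, "bad1.tsv"))
  expect_error(read_triplets(file.path(dir, "bad1.tsv"), bed), "out of range")
  writeLines("0\t1\t-2", file.path(dir, "bad2.tsv"))
  expect_error(read_triplets(file.path(dir, "bad2.tsv"), bed), "negative")
  writeLines("0\t1", file.path(dir, "bad3.tsv"))
  expect_error(read_triplets(file.path(dir, "bad3.tsv"), bed), "malformed")

  rmap <- random_count_map(12, seed = 1)
  write_triplets(rmap, file.path(dir, "rt.tsv"), file.path(dir, "rt.bed"))
  back <- read_triplets(file.path(dir, "rt.tsv"), file.path(dir, "rt.bed"))
  expect_equal(back$counts, rmap$counts)
})

test_that("depth normalization is a plain division with the documented default", {
  m <- random_count_map(10, seed = 2)
  expect_equal(normalize_depth(m, total = 1)$counts, m$counts)
  nm <- normalize_depth(m)
  expect_equal(sum(nm$counts[upper.tri(nm$counts, diag = TRUE)]), 1)
  expect_error(normalize_depth(m, total = 0), "positive")
  # two Poisson samples of one system at different depths agree once normalized
  cfg1 <- simulation_config(seed = 11, n_bins = 50, depth = 1e5)
  cfg2 <- simulation_config(seed = 12, n_bins = 50, depth = 1e6)
  a <- normalize_depth(simulate_contact_map(cfg1)$map)
  b <- normalize_depth(simulate_contact_map(cfg2)$map)
  d <- 5
  i <- 1:(50 - d)
  ma <- mean(a$counts[cbind(i, i + d)]); mb <- mean(b$counts[cbind(i, i + d)])
  expect_lt(abs(ma - mb) / mb, 0.2)
})

test_that("iterative correction: fixed point, bias recovery, masking, idempotence", {
  # uniform off-diagonal matrix already has uniform marginals
  U <- matrix(4, 20, 20); diag(U) <- 0
  mu <- contact_map(U, 20000)
  bal <- iterative_correction(mu, mask_low_coverage_fraction = 0)
  expect_equal(bal$bias, rep(1, 20), tolerance = 1e-9)
  expect_equal(bal$counts, U, tolerance = 1e-9)

  # constructive oracle: U[i,j] * b_i * b_j recovers b to 1e-6
  set.seed(3)
  b <- runif(20, 0.5, 2)
  W <- U * outer(b, b)
  bal2 <- iterative_correction(contact_map(W, 20000), tol = 1e-9,
                               mask_low_coverage_fraction = 0)
  ratio <- bal2$bias / b
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-6)
  # raw recoverable as balanced * bias_i * bias_j
  expect_equal(bal2$counts * outer(bal2$bias, bal2$bias), W, tolerance = 1e-6)

  # masking contract: zeroed rows and sentinel bias
  W2 <- W; W2[5, ] <- 0; W2[, 5] <- 0
  bal3 <- iterative_correction(contact_map(W2, 20000),
                               mask_low_coverage_fraction = 0)
  expect_true(all(bal3$counts[5, ] == 0))
  expect_true(is.na(bal3$bias[5]))
  expect_true(bal3$mask[5])

  # unmasked marginals equal within tolerance after balancing
  marg <- rowSums(bal3$counts)[!bal3$mask]
  expect_lt(max(abs(marg / mean(marg) - 1)), 1e-6)

  # idempotence: rebalancing changes biases by < tol
  m <- random_count_map(30, seed = 4, lambda = 50)
  bal4 <- iterative_correction(m, tol = 1e-10)
  rebal <- iterative_correction(
    {x <- m; x$counts <- bal4$counts; x}, tol = 1e-10,
    mask_low_coverage_fraction = 0)
  expect_lt(max(abs(rebal$bias[!bal4$mask] - 1)), 1e-6)

  expect_error(iterative_correction(contact_map(matrix(0, 5, 5), 20000)),
               "all-zero")
})

test_that("observed/expected: per-diagonal means are one, masked cells stay masked", {
  # constant-per-diagonal matrix maps to all ones
  n <- 8
  M <- matrix(0, n, n)
  for (d in 1:(n - 1)) for (i in 1:(n - d)) M[i, i + d] <- M[i + d, i] <- d^-1
  oe <- observed_over_expected(as_balanced(contact_map(M, 20000)))
  off <- abs(outer(1:n, 1:n, "-")) > 0
  expect_equal(unname(oe$counts[off]), rep(1, sum(off)), tolerance = 1e-12)

  # brute-force per-diagonal means on a random 6x6 map
  m6 <- as_balanced(random_count_map(6, seed = 5))
  oe6 <- observed_over_expected(m6)
  for (d in 1:5) {
    i <- 1:(6 - d)
    manual <- m6$counts[cbind(i, i + d)] / mean(m6$counts[cbind(i, i + d)])
    expect_equal(unname(oe6$counts[cbind(i, i + d)]), unname(manual))
    expect_equal(mean(oe6$counts[cbind(i, i + d)]), 1, tolerance = 1e-6)
  }

  # masked bins propagate as NA
  m <- random_count_map(10, seed = 6)
  m$counts[3, ] <- 0; m$counts[, 3] <- 0
  bal <- iterative_correction(m, mask_low_coverage_fraction = 0)
  oem <- observed_over_expected(bal)
  expect_true(all(is.na(oem$counts[3, ])))
})

test_that("difference map is an antisymmetric cellwise log ratio", {
  a <- normalize_depth(random_count_map(6, seed = 7))
  b <- normalize_depth(random_count_map(6, seed = 8))
  expect_equal(difference_map(a, a), matrix(0, 6, 6))
  expect_equal(difference_map(a, b), -difference_map(b, a))
  # hand computation on a 2x2 pair
  A <- contact_map(matrix(c(0, 4, 4, 0), 2), 20000)
  B <- contact_map(matrix(c(0, 1, 1, 0), 2), 20000)
  d <- difference_map(A, B, pseudocount = 0)
  expect_equal(d[1, 2], 2)  # log2(4/1)
  c3 <- contact_map(matrix(0, 3, 3), 20000)
  expect_error(difference_map(a, c3), "bin tables")
})
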