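# Shared fixtures and independent oracles used across test files.

# Symmetric random count map with zero diagonal.
random_count_map <- function(n, seed, lambda = 20, resolution = 20000L) {
  set.seed(seed)
  M <- matrix(0, n, n)
  ut <- upper.tri(M)
  M[ut] <- rpois(sum(ut), lambda)
  contact_map(M + t(M), resolution = resolution)
}

# Mark a map as balanced with unit biases, bypassing correction (for tests
# that need a "balanced" map with exactly known values).
as_balanced <- function(map) {
  map$balanced <- TRUE
  map$bias <- rep(1, nrow(map$counts))
  map$mask <- rep(FALSE, nrow(map$counts))
  map
}

# Independent Armatus oracle: recursive enumeration of all segmentations.
# Window quality follows the same published definition as the DP but is
# computed with naive loops, independent of the package's prefix sums.
armatus_brute_force <- function(W, gamma, min_size, max_size) {
  n <- nrow(W)
  S_win <- function(k, l) {
    s <- 0
    for (i in k:l) for (j in i:l) if (j > i) s <- s + W[i, j]
    s
  }
  scaled <- list()
  for (d in seq_len(min(max_size, n))) {
    v <- numeric(0)
    for (k in seq_len(n - d + 1)) v <- c(v, S_win(k, k + d - 1) / d^gamma)
    scaled[[d]] <- v
  }
  mu <- sapply(scaled, mean)
  q <- function(k, l) {
    d <- l - k + 1
    scaled[[d]][k] - mu[d]
  }
  best <- function(i) {  # best score for bins 1..i
    if (i <= 0) return(0)
    b <- best(i - 1)
    if (i >= min_size) {
      for (d in min_size:min(max_size, i)) {
        qv <- q(i - d + 1, i)
        if (qv > 0) b <- max(b, best(i - d) + qv)
      }
    }
    b
  }
  best(n)
}

# Brute-force all-pairs peak persistence classifier (oracle for the
# IRanges-backed sweep).
classify_peaks_brute <- function(control, treated, threshold = 0.5) {
  pi_one <- function(s1, e1, s2, e2) {
    ov <- max(0, min(e1, e2) - max(s1, s2))
    ov / max(e1 - s1, e2 - s2)
  }
  best_vs <- function(q, s) {
    sapply(seq_len(nrow(q)), function(i) {
      if (!nrow(s)) return(0)
      max(sapply(seq_len(nrow(s)), function(j)
        pi_one(q$start[i], q$end[i], s$start[j], s$end[j])))
    })
  }
  remaining <- best_vs(control, treated) > threshold
  novel <- !(best_vs(treated, control) > threshold)
  list(n_remaining = sum(remaining), n_lost = sum(!remaining),
       n_novel = sum(novel))
}

# Brute-force greedy persistence matcher for contact sets.
classify_persistence_brute <- function(control, treated, tol_bins = 1L) {
  nc <- nrow(control); nt <- nrow(treated)
  cand <- NULL
  for (i in seq_len(nc)) for (j in seq_len(nt)) {
    d1 <- abs(control$bin1[i] - treated$bin1[j])
    d2 <- abs(control$bin2[i] - treated$bin2[j])
    if (d1 <= tol_bins && d2 <= tol_bins)
      cand <- rbind(cand, data.frame(ci = i, ti = j, dist = d1 + d2))
  }
  matched <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist, cand$ci, cand$ti), ]
    uc <- logical(nc); ut <- logical(nt)
    for (r in seq_len(nrow(cand))) {
      if (!uc[cand$ci[r]] && !ut[cand$ti[r]]) {
        matched <- matched + 1L
        uc[cand$ci[r]] <- TRUE; ut[cand$ti[r]] <- TRUE
      }
    }
  }
  c(preserved = matched, lost = nc - matched, de_novo = nt - matched)
}
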