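#' Armatus-score optimal TAD segmentation
#'
#' Segments a balanced contact map into topologically associating domains
#' by dynamic programming over the Armatus scoring function. A candidate
#' domain spanning bins `[k, l]` has quality
#' `q(k, l) = S(k, l) / d^gamma - mu_gamma(d)` with `d = l - k + 1`, where
#' `S` is the sum of map cells with both ends inside the window (upper
#' triangle, diagonal excluded) and `mu_gamma(d)` is the mean of
#' `S / d^gamma` over all contiguous windows of size `d`. The DP maximizes
#' the sum of `max(q, 0)` over disjoint chosen domains, allowing unassigned
#' gap bins, and returns the single optimal segmentation.
#'
#' @param map a balanced [contact_map].
#' @param gamma resolution parameter of the Armatus score (default 0.3).
#' @param min_size,max_size domain size limits in bins.
#' @return An object of class `tad_segmentation` with `domains` (data.frame
#'   `start_bin`, `end_bin`, 0-based half-open, plus the domain `quality`),
#'   `gamma`, `aggregate_score`.
#' @export
armatus_segment <- function(map, gamma = 0.3, min_size = 3L, max_size = 200L) {
  stopifnot(gamma >= 0, min_size >= 1L, max_size >= min_size)
  W <- map$counts
  W[is.na(W)] <- 0
  n <- nrow(W)
  if (n < min_size) {
    return(structure(list(domains = data.frame(start_bin = integer(0),
                                               end_bin = integer(0),
                                               quality = numeric(0)),
                          gamma = gamma, aggregate_score = 0),
                     class = "tad_segmentation"))
  }
  max_size <- min(max_size, n)
  diag(W) <- 0
  # 2D prefix sums for O(1) window sums
  P <- apply(W, 2, cumsum)
  P <- t(apply(P, 1, cumsum))
  P <- rbind(0, cbind(0, P))  # P[i+1, j+1] = sum W[1:i, 1:j]
  block_sum <- function(k, l) {
    # sum of distinct within-window pairs, diagonal excluded (1-based k..l)
    (P[l + 1L, l + 1L] - P[k, l + 1L] - P[l + 1L, k] + P[k, k]) / 2
  }
  # window scores centered by the mean over all windows of the same size
  q_of <- vector("list", max_size)
  for (d in seq_len(max_size)) {
    k <- seq_len(n - d + 1L)
    l <- k + d - 1L
    s <- (P[cbind(l + 1L, l + 1L)] - P[cbind(k, l + 1L)] -
            P[cbind(l + 1L, k)] + P[cbind(k, k)]) / 2
    scaled <- s / d^gamma
    q_of[[d]] <- scaled - mean(scaled)
  }
  # DP over prefixes: opt[i + 1] = best score for bins 1..i
  opt <- c(0, rep(-Inf, n))
  choice <- integer(n + 1L)  # 0 = gap bin, d = domain of size d ends here
  opt[1] <- 0
  for (i in seq_len(n)) {
    best <- opt[i]
    pick <- 0L
    dmax <- min(max_size, i)
    if (dmax >= min_size) {
      for (d in min_size:dmax) {
        qv <- q_of[[d]][i - d + 1L]
        if (qv > 0 && opt[i - d + 1L] + qv > best) {
          best <- opt[i - d + 1L] + qv
          pick <- d
        }
      }
    }
    opt[i + 1L] <- best
    choice[i + 1L] <- pick
  }
  domains <- list()
  i <- n
  while (i > 0L) {
    d <- choice[i + 1L]
    if (d == 0L) { i <- i - 1L } else {
      domains[[length(domains) + 1L]] <-
        data.frame(start_bin = i - d, end_bin = i,
                   quality = q_of[[d]][i - d + 1L])
      i <- i - d
    }
  }
  domains <- if (length(domains)) do.call(rbind, rev(domains)) else
    data.frame(start_bin = integer(0), end_bin = integer(0), quality = numeric(0))
  structure(list(domains = domains, gamma = gamma,
                 aggregate_score = opt[n + 1L]),
            class = "tad_segmentation")
}

#' @export
print.tad_segmentation <- function(x, ...) {
  cat(sprintf("<tad_segmentation> %d domains, gamma = %g, score = %.4g\n",
              nrow(x$domains), x$gamma, x$aggregate_score))
  invisible(x)
}

# sum of distinct within-domain cell pairs, diagonal excluded
intra_sum <- function(W, start_bin, end_bin) {
  idx <- (start_bin + 1L):end_bin
  sub <- W[idx, idx, drop = FALSE]
  (sum(sub) - sum(diag(sub))) / 2
}

#' TAD border strength
#'
#' For each pair of abutting domains A, B the border strength is the ratio
#' of summed within-domain contacts to summed between-domain contacts:
#' `(intraSum(A) + intraSum(B)) / interSum(A, B)`, intra sums over distinct
#' within-domain pairs (diagonal excluded), inter over all pairs spanning
#' the border. Larger values mean stronger borders.
#'
#' @param map a balanced [contact_map].
#' @param seg a [armatus_segment()] segmentation on the same bins.
#' @param adjacency_tol maximum gap (bins) between domains that still forms
#'   a border (default 0: abutting only).
#' @return A data.frame with one row per border: `border_bin` (first bin of
#'   the right domain), `left_domain`, `right_domain` (indices into
#'   `seg$domains`), `strength`, and `valid` (FALSE where the inter sum is
#'   zero and the strength undefined).
#' @export
border_strength <- function(map, seg, adjacency_tol = 0L) {
  W <- map$counts
  W[is.na(W)] <- 0
  dom <- seg$domains
  out <- NULL
  if (nrow(dom) >= 2L) {
    for (t in seq_len(nrow(dom) - 1L)) {
      A <- dom[t, ]; B <- dom[t + 1L, ]
      if (B$start_bin - A$end_bin > adjacency_tol) next
      ia <- intra_sum(W, A$start_bin, A$end_bin)
      ib <- intra_sum(W, B$start_bin, B$end_bin)
      inter <- sum(W[(A$start_bin + 1L):A$end_bin,
                     (B$start_bin + 1L):B$end_bin, drop = FALSE])
      out <- rbind(out, data.frame(
        border_bin = B$start_bin, left_domain = t, right_domain = t + 1L,
        strength = if (inter > 0) (ia + ib) / inter else NA_real_,
        valid = inter > 0))
    }
  }
  out %||% data.frame(border_bin = integer(0), left_domain = integer(0),
                      right_domain = integer(0), strength = numeric(0),
                      valid = logical(0))
}

#' Paired control-vs-treated comparison of TAD border strength
#'
#' Evaluates border strength on both conditions at the borders annotated in
#' the control segmentation, and tests the paired differences with a
#' two-sided paired t-test.
#'
#' @param control_map,treated_map balanced [contact_map]s on identical bins.
#' @param control_seg the control-condition segmentation.
#' @param adjacency_tol passed to [border_strength()].
#' @return A list with `pairs` (per-border control/treated strengths),
#'   `summary` (medians and quartiles per condition and the fraction of
#'   borders with treated < control), and `test` (the paired t-test, or
#'   `NULL` with fewer than 2 valid pairs).
#' @export
compare_borders <- function(control_map, treated_map, control_seg,
                            adjacency_tol = 0L) {
  if (!same_bins(control_map, treated_map)) stop("bin tables differ")
  bc <- border_strength(control_map, control_seg, adjacency_tol)
  bt <- border_strength(treated_map, control_seg, adjacency_tol)
  pairs <- data.frame(border_bin = bc$border_bin,
                      control = bc$strength, treated = bt$strength)
  ok <- is.finite(pairs$control) & is.finite(pairs$treated)
  valid <- pairs[ok, , drop = FALSE]
  strict <- valid$treated != valid$control
  summ <- list(
    n_borders = nrow(valid),
    control = stats::quantile(valid$control, c(0.25, 0.5, 0.75), na.rm = TRUE),
    treated = stats::quantile(valid$treated, c(0.25, 0.5, 0.75), na.rm = TRUE),
    fraction_below_diagonal =
      if (any(strict)) mean(valid$treated[strict] < valid$control[strict]) else 0)
  test <- NULL
  if (nrow(valid) >= 2L && stats::sd(valid$treated - valid$control) > 0) {
    test <- stats::t.test(valid$treated, valid$control, paired = TRUE)
  }
  list(pairs = pairs, summary = summ, test = test)
}
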