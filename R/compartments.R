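#' A/B compartment profile from an observed/expected map
#'
#' Computes the Pearson correlation matrix of the observed/expected map
#' over unmasked bins, extracts its first principal component, and orients
#' it so it correlates positively with GC content — the A compartment
#' (positive values) then has the higher GC, per convention.
#'
#' @param oe_map an [observed_over_expected()] map.
#' @param gc_track per-bin GC fraction.
#' @return An object of class `compartment_profile`: `value` (per-bin
#'   eigenvector entry, `NA` for masked bins), `label` (`"A"`/`"B"`/`NA`),
#'   `orientation_gc_corr` (correlation of the oriented component with GC).
#' @export
compartment_profile <- function(oe_map, gc_track) {
  n <- n_bins(oe_map)
  stopifnot(length(gc_track) == n)
  keep <- !oe_map$mask & colSums(is.finite(oe_map$counts)) > 0
  if (sum(keep) < 10L) stop("need at least 10 unmasked bins")
  M <- oe_map$counts[keep, keep, drop = FALSE]
  M[!is.finite(M)] <- 1  # neutral O/E where the diagonal/excluded cells sit
  sds <- apply(M, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate (constant) observed/expected map")
  const <- sds == 0
  C <- suppressWarnings(stats::cor(M))
  C[!is.finite(C)] <- 0
  # first principal component (column-centered) of the correlation matrix;
  # the uncentered leading eigenvector of a mostly-positive C is all one
  # sign and carries no compartment signal
  ev <- stats::prcomp(C, center = TRUE, scale. = FALSE)$rotation[, 1]
  ev[const] <- NA_real_
  gc <- gc_track[keep]
  ok <- is.finite(ev)
  r <- suppressWarnings(stats::cor(ev[ok], gc[ok]))
  if (is.finite(r) && r < 0) { ev <- -ev; r <- -r }
  value <- rep(NA_real_, n)
  value[keep] <- ev
  label <- rep(NA_character_, n)
  label[which(value > 0)] <- "A"
  label[which(value < 0)] <- "B"
  structure(list(value = value, label = label,
                 orientation_gc_corr = if (is.finite(r)) r else NA_real_),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat(sprintf("<compartment_profile> %d bins (%d A, %d B), gc corr = %.3f\n",
              length(x$value), sum(x$label == "A", na.rm = TRUE),
              sum(x$label == "B", na.rm = TRUE), x$orientation_gc_corr))
  invisible(x)
}

#' Saddle plot: eigenvector-ordered aggregated observed/expected map
#'
#' Sorts unmasked bins by ascending compartment eigenvector (conventionally
#' the control-condition profile for both conditions), permutes the rows
#' and columns of the observed/expected map accordingly, and aggregates
#' into `n_agg` equal-count groups by mean. With ascending order, the
#' (B,B) corner is top-left and (A,A) bottom-right.
#'
#' @param oe_map an [observed_over_expected()] map.
#' @param profile a [compartment_profile()] on the same bins (control
#'   condition for comparative saddles).
#' @param n_agg number of aggregation groups (default 20).
#' @return A list of class `saddle_matrix` with `matrix` (`n_agg` x
#'   `n_agg` means), `group_of` (per-bin group id, `NA` for masked bins).
#' @export
saddle <- function(oe_map, profile, n_agg = 20L) {
  n <- n_bins(oe_map)
  stopifnot(length(profile$value) == n)
  usable <- which(is.finite(profile$value) & !oe_map$mask)
  if (length(usable) < n_agg) stop("n_agg exceeds the number of usable bins")
  ord <- usable[order(profile$value[usable], usable)]
  grp_sizes <- rep(length(ord) %/% n_agg, n_agg)
  extra <- length(ord) %% n_agg
  if (extra > 0) grp_sizes[seq_len(extra)] <- grp_sizes[seq_len(extra)] + 1L
  grp <- rep(seq_len(n_agg), grp_sizes)
  group_of <- rep(NA_integer_, n)
  group_of[ord] <- grp
  S <- matrix(NA_real_, n_agg, n_agg)
  W <- oe_map$counts
  for (g1 in seq_len(n_agg)) {
    i <- ord[grp == g1]
    for (g2 in g1:n_agg) {
      j <- ord[grp == g2]
      v <- W[i, j, drop = FALSE]
      v <- v[is.finite(v)]
      if (length(v)) S[g1, g2] <- S[g2, g1] <- mean(v)
    }
  }
  structure(list(matrix = S, group_of = group_of, n_agg = n_agg),
            class = "saddle_matrix")
}

#' Compartmentalization strength from a saddle matrix
#'
#' The mean of the two 3x3 same-compartment corner blocks — (B,B) top-left
#' and (A,A) bottom-right — divided by the mean of the two 3x3
#' cross-compartment anti-corner blocks. Values above 1 indicate
#' compartment segregation.
#'
#' @param sdl a [saddle()] result.
#' @return A scalar.
#' @export
compartmentalization_strength <- function(sdl) {
  S <- sdl$matrix
  n <- nrow(S)
  lo <- 1:3; hi <- (n - 2):n
  corner <- c(S[lo, lo], S[hi, hi])
  anti <- c(S[lo, hi], S[hi, lo])
  corner <- corner[is.finite(corner)]
  anti <- anti[is.finite(anti)]
  if (!length(anti) || mean(anti) == 0) stop("anti-corner mean is zero")
  mean(corner) / mean(anti)
}

#' Contact frequencies within and between compartments
#'
#' Partitions the summed (distance-filtered) contacts of a depth-normalized
#' map by the compartment labels of the two endpoints, normalized to sum to
#' 1 over AA, BB and AB.
#'
#' @param map a depth-normalized [contact_map].
#' @param profile a [compartment_profile()] for the same condition.
#' @param min_dist_bins minimum separation in bins (default 2).
#' @return A named numeric vector `c(AA, BB, AB)`.
#' @export
compartment_contact_fractions <- function(map, profile, min_dist_bins = 2L) {
  n <- n_bins(map)
  lab <- profile$label
  W <- map$counts
  idx <- which(upper.tri(W), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  idx <- idx[d >= min_dist_bins, , drop = FALSE]
  li <- lab[idx[, 1]]; lj <- lab[idx[, 2]]
  ok <- !is.na(li) & !is.na(lj)
  idx <- idx[ok, , drop = FALSE]; li <- li[ok]; lj <- lj[ok]
  v <- W[idx]
  sums <- c(AA = sum(v[li == "A" & lj == "A"]),
            BB = sum(v[li == "B" & lj == "B"]),
            AB = sum(v[li != lj]))
  if (any(sums == 0) && sum(sums) > 0)
    warning("empty compartment label class; its fraction reported as 0")
  tot <- sum(sums)
  if (tot == 0) return(c(AA = 0, BB = 0, AB = 0))
  sums / tot
}
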