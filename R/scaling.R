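#' Contact-probability-vs-distance curve P(s)
#'
#' Averages map cells into log-spaced genomic-distance bands and normalizes
#' the curve so its integral over the bands is 1, making curves from
#' different sequencing depths directly comparable.
#'
#' @param map a depth-normalized [contact_map].
#' @param s_min,s_max distance range in bp (defaults: 2 bins to the map
#'   span).
#' @param bins_per_decade number of log-spaced bands per decade (default 8).
#' @return A data.frame of class `scaling_curve` with `band_low`,
#'   `band_high` (bp), `s_mean` (mean separation of the contributing
#'   cells), `probability`, `n_cells`; empty bands are omitted and their
#'   edges recorded in the `empty_bands` attribute.
#' @export
contact_probability_curve <- function(map, s_min = NULL, s_max = NULL,
                                      bins_per_decade = 8L) {
  n <- n_bins(map)
  res <- map$resolution
  s_min <- s_min %||% (2 * res)
  s_max <- s_max %||% ((n - 1) * res)
  if (s_min < 2 * res) stop("s_min must be at least 2 bins")
  edges <- 10^seq(log10(s_min), log10(s_max), by = 1 / bins_per_decade)
  if (edges[length(edges)] < s_max) edges <- c(edges, s_max)
  d_all <- seq_len(n - 1L)
  s_all <- d_all * res
  mask <- map$mask
  # per-diagonal mean and unmasked cell count
  diag_mean <- rep(NA_real_, n - 1L)
  diag_n <- integer(n - 1L)
  for (d in d_all) {
    i <- seq_len(n - d); j <- i + d
    ok <- !mask[i] & !mask[j]
    diag_n[d] <- sum(ok)
    if (diag_n[d]) diag_mean[d] <- mean(map$counts[cbind(i[ok], j[ok])])
  }
  rows <- NULL
  empty <- NULL
  for (b in seq_len(length(edges) - 1L)) {
    lo <- edges[b]; hi <- edges[b + 1L]
    sel <- which(s_all >= lo & (s_all < hi | (b == length(edges) - 1L & s_all <= hi)))
    sel <- sel[diag_n[sel] > 0]
    if (!length(sel)) { empty <- rbind(empty, c(lo, hi)); next }
    wts <- diag_n[sel]
    rows <- rbind(rows, data.frame(
      band_low = lo, band_high = hi,
      s_mean = sum(s_all[sel] * wts) / sum(wts),
      probability = sum(diag_mean[sel] * wts) / sum(wts),
      n_cells = sum(wts)))
  }
  if (is.null(rows)) stop("no cells in the requested distance range")
  integral <- sum(rows$probability * (rows$band_high - rows$band_low))
  rows$probability <- rows$probability / integral
  attr(rows, "empty_bands") <- empty
  class(rows) <- c("scaling_curve", class(rows))
  rows
}

#' Scaling exponent of a contact-probability curve
#'
#' Least-squares slope of `log P(s)` versus `log s` over the bands whose
#' mean separation falls inside `[fit_min, fit_max]`.
#'
#' @param curve a [contact_probability_curve()] result.
#' @param fit_min,fit_max fit range in bp.
#' @return The slope (a power-law `s^alpha` yields `alpha`).
#' @export
scaling_slope <- function(curve, fit_min, fit_max) {
  sel <- curve$s_mean >= fit_min & curve$s_mean <= fit_max &
    curve$probability > 0
  if (sum(sel) < 3L) stop("need at least 3 bands inside the fit range")
  fit <- stats::lm(log(probability) ~ log(s_mean), data = curve[sel, ])
  unname(stats::coef(fit)[2])
}

#' Crossover distance between two scaling curves
#'
#' Finds where the log-ratio of treated over control contact probability
#' changes sign — the distance below which contacts are depleted and above
#' which they are enriched (or vice versa).
#'
#' @param curveA control curve.
#' @param curveB treated curve (bands must match `curveA`).
#' @return The band boundary (bp) nearest the first sign change, or `NULL`
#'   when the log-ratio never changes sign.
#' @export
crossover_report <- function(curveA, curveB) {
  key <- function(cv) paste(cv$band_low, cv$band_high)
  shared <- intersect(key(curveA), key(curveB))
  a <- curveA[match(shared, key(curveA)), ]
  b <- curveB[match(shared, key(curveB)), ]
  lr <- log(b$probability / a$probability)
  lr[!is.finite(lr)] <- 0
  sgn <- sign(lr)
  nz <- which(sgn != 0)
  if (length(nz) < 2L) return(NULL)
  flips <- which(diff(sgn[nz]) != 0)
  if (!length(flips)) return(NULL)
  i <- nz[flips[1]]
  a$band_high[i]
}
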