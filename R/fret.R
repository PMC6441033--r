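#' Cross-talk-corrected proximity ratio
#'
#' `E_PR = (Ia - 0.19 * Id) / (Ia + 0.81 * Id)` for background-corrected
#' acceptor (Cy5) and donor (Cy3) intensities; the factors 0.19 and 0.81
#' correct for donor bleed-through into the acceptor channel. With
#' non-negative intensities the ratio lies in `(-0.19/0.81, 1]`.
#'
#' @param Ia acceptor intensity (arbitrary units), vectorized.
#' @param Id donor intensity (same units).
#' @return The proximity ratio.
#' @export
proximity_ratio <- function(Ia, Id) {
  denom <- Ia + 0.81 * Id
  if (any(denom <= 0)) stop("Ia + 0.81 * Id must be positive")
  (Ia - 0.19 * Id) / denom
}

#' Relative-frequency distribution of proximity ratios
#'
#' Bins the per-event proximity ratios on a fixed grid covering
#' `(-0.25, 1.05]` so that histograms from different samples are directly
#' comparable; frequencies sum to 1.
#'
#' @param events a `fret_events` data.frame (or anything with a
#'   `proximity_ratio` column).
#' @param bin_width histogram bin width (default 0.05).
#' @return A data.frame of class `fret_histogram` with `mid`, `frequency`;
#'   attributes `bin_width`, `n_events`, `breaks`.
#' @export
build_distribution <- function(events, bin_width = 0.05) {
  x <- events$proximity_ratio
  if (!length(x)) stop("no events to bin")
  if (length(x) < 100L)
    warning(sprintf("only %d events; distributions are usually built from hundreds", length(x)))
  breaks <- seq(-0.25, 1.05 + 1e-12, by = bin_width)
  if (breaks[length(breaks)] < 1.05) breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  cuts <- cut(x, breaks = breaks, right = TRUE, include.lowest = FALSE)
  if (anyNA(cuts)) stop("proximity ratios outside (-0.25, 1.05]")
  freq <- as.numeric(table(cuts)) / length(x)
  out <- data.frame(mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    frequency = freq)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_events") <- length(x)
  attr(out, "breaks") <- breaks
  class(out) <- c("fret_histogram", class(out))
  out
}

gaussian_sum <- function(x, pars) {
  k <- length(pars) / 3
  y <- 0
  for (c in seq_len(k)) {
    a <- pars[3 * c - 2]; m <- pars[3 * c - 1]; s <- pars[3 * c]
    y <- y + a * exp(-(x - m)^2 / (2 * s^2))
  }
  y
}

#' Fit a sum of Gaussians to a proximity-ratio histogram
#'
#' Nonlinear least squares of `sum_k a_k exp(-(x - m_k)^2 / (2 s_k^2))` to
#' the binned relative frequencies, with multistart initialization (means
#' at the 25th/75th weighted percentiles, s.d.s at the bin width, five
#' jittered restarts) and s.d.s bounded below at half the bin width. The
#' fraction of events in each conformational state is the analytic area of
#' its component, `a_k s_k sqrt(2 pi)`, over the total fitted area.
#'
#' @param hist a [build_distribution()] histogram.
#' @param n_components 1 or 2.
#' @param init optional list with `means`, `sds`, `amplitudes` overriding
#'   the automatic starts.
#' @return An object of class `mixture_fit`: `components` (data.frame with
#'   `mean`, `sd`, `amplitude`, `area_fraction`, ordered by ascending
#'   mean), `r_squared`, `bin_width`, plus the parameter covariance for
#'   uncertainty propagation.
#' @export
fit_gaussian_mixture <- function(hist, n_components = 2L, init = NULL) {
  stopifnot(n_components %in% c(1L, 2L))
  x <- hist$mid
  y <- hist$frequency
  bw <- attr(hist, "bin_width") %||% (x[2] - x[1])
  wq <- function(p) {
    cw <- cumsum(y) / sum(y)
    x[which(cw >= p)[1]]
  }
  if (is.null(init)) {
    means0 <- if (n_components == 1L) wq(0.5) else c(wq(0.25), wq(0.75))
    sds0 <- rep(bw, n_components)
    amps0 <- rep(max(y), n_components) / n_components
  } else {
    means0 <- init$means; sds0 <- init$sds
    amps0 <- init$amplitudes %||% rep(max(y), n_components) / n_components
  }
  starts <- list(list(a = amps0, m = means0, s = sds0))
  jit <- with_seed(1L, lapply(1:5, function(i)
    list(a = amps0 * stats::runif(n_components, 0.5, 1.5),
         m = means0 + stats::rnorm(n_components, 0, 2 * bw),
         s = sds0 * stats::runif(n_components, 1, 4))))
  starts <- c(starts, jit)
  lower <- rep(c(0, min(x), bw / 2), n_components)
  upper <- rep(c(Inf, max(x), diff(range(x))), n_components)
  best <- NULL
  for (st in starts) {
    p0 <- as.numeric(rbind(st$a, st$m, st$s))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) y - gaussian_sum(x, p),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop("Gaussian mixture fit failed from all starts")
  p <- best$fit$par
  comp <- data.frame(amplitude = p[seq(1, by = 3, length.out = n_components)],
                     mean = p[seq(2, by = 3, length.out = n_components)],
                     sd = p[seq(3, by = 3, length.out = n_components)])
  areas <- comp$amplitude * comp$sd * sqrt(2 * pi)
  comp$area_fraction <- areas / sum(areas)
  ord <- order(comp$mean)
  comp <- comp[ord, c("mean", "sd", "amplitude", "area_fraction")]
  rownames(comp) <- NULL
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - best$ss / ss_tot
  vc <- tryCatch({
    # J'J covariance scaled by residual variance
    J <- best$fit$hessian / 2
    sigma2 <- best$ss / max(1, length(y) - length(p))
    solve(J) * sigma2
  }, error = function(e) NULL)
  structure(list(components = comp, r_squared = r2, bin_width = bw,
                 param_order = ord, vcov = vc, n_obs = length(y)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d component(s), R^2 = %.4f\n",
              nrow(x$components), x$r_squared))
  print(x$components, digits = 3)
  invisible(x)
}

area_fraction_se <- function(fit) {
  k <- nrow(fit$components)
  if (is.null(fit$vcov) || k < 1) return(rep(NA_real_, k))
  # parameters in original (unsorted) order: (a, m, s) per component
  p <- as.numeric(t(fit$components[order(fit$param_order),
                                   c("amplitude", "mean", "sd")]))
  frac <- function(pp) {
    a <- pp[seq(1, by = 3, length.out = k)]
    s <- pp[seq(3, by = 3, length.out = k)]
    ar <- a * s
    (ar / sum(ar))[fit$param_order]
  }
  eps <- 1e-6
  G <- matrix(0, k, length(p))
  for (j in seq_along(p)) {
    dp <- p; dp[j] <- dp[j] + eps
    G[, j] <- (frac(dp) - frac(p)) / eps
  }
  se2 <- diag(G %*% fit$vcov %*% t(G))
  sqrt(pmax(se2, 0))
}

#' Compare conformational-state fractions between two mixture fits
#'
#' Matches components across conditions by nearest fitted mean and reports
#' the per-state area-fraction differences (plus minus minus) with
#' uncertainties propagated from the least-squares parameter covariances.
#'
#' @param fit_minus,fit_plus [fit_gaussian_mixture()] results with the same
#'   number of components.
#' @return A data.frame with per-state `mean_minus`, `mean_plus`,
#'   `fraction_minus`, `fraction_plus`, `delta`, `delta_se`.
#' @export
compare_conditions <- function(fit_minus, fit_plus) {
  km <- nrow(fit_minus$components); kp <- nrow(fit_plus$components)
  if (km != kp) stop("component counts differ between conditions")
  cm <- fit_minus$components; cp <- fit_plus$components
  # nearest-mean one-to-one matching (components are mean-sorted)
  used <- logical(kp)
  match_idx <- integer(km)
  for (i in seq_len(km)) {
    d <- abs(cp$mean - cm$mean[i])
    d[used] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) stop("components could not be matched")
    match_idx[i] <- j
    used[j] <- TRUE
  }
  se_m <- area_fraction_se(fit_minus)
  se_p <- area_fraction_se(fit_plus)
  data.frame(
    mean_minus = cm$mean,
    mean_plus = cp$mean[match_idx],
    fraction_minus = cm$area_fraction,
    fraction_plus = cp$area_fraction[match_idx],
    delta = cp$area_fraction[match_idx] - cm$area_fraction,
    delta_se = sqrt(se_m^2 + se_p[match_idx]^2))
}

#' Read / write spFRET event tables
#'
#' TSV with columns `event_id`, `I_donor`, `I_acceptor`; the proximity
#' ratio is recomputed on read.
#'
#' @param path file path.
#' @return `read_fret_events` returns a `fret_events` data.frame.
#' @export
read_fret_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("event_id", "I_donor", "I_acceptor") %in% names(df)))
  df$proximity_ratio <- proximity_ratio(df$I_acceptor, df$I_donor)
  class(df) <- c("fret_events", class(df))
  df
}

#' @param events a `fret_events` data.frame.
#' @rdname read_fret_events
#' @export
write_fret_events <- function(events, path) {
  utils::write.table(events[, c("event_id", "I_donor", "I_acceptor")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
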