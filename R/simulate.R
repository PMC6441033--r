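#' Simulation configuration for synthetic cis contact maps
#'
#' Describes the generative model for a single-chromosome binned contact
#' map: power-law distance decay, block TADs, focal loop dots, a compartment
#' checkerboard, multiplicative per-bin biases and a target sequencing
#' depth. Counts are later drawn cell-wise from a Poisson at the expected
#' value.
#'
#' @param seed integer master seed streamed to named sub-generators.
#' @param n_bins number of bins.
#' @param resolution bin width in bp (default 20 kb).
#' @param decay_exponent exponent of the distance decay `s^alpha`
#'   (default -1, the fractal-globule reference).
#' @param tad_spec data.frame with columns `start_bin`, `end_bin` (0-based,
#'   half-open) and `intra_boost` (>= 1); TADs must be ordered and
#'   non-overlapping.
#' @param loop_spec data.frame with columns `bin_i`, `bin_j` (0-based) and
#'   `loop_boost` (>= 1).
#' @param compartment_profile per-bin real in `[-1, 1]`; `NULL` for none.
#' @param compartment_strength non-negative checkerboard amplitude.
#' @param bias_vector strictly positive per-bin biases; `NULL` for unit.
#' @param depth expected total read pairs (off-diagonal upper triangle).
#' @param gc_track per-bin GC fraction in `[0, 1]`; defaults to a track
#'   positively tied to the compartment profile, as in real genomes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_bins = 500L, resolution = 20000L,
                              decay_exponent = -1.0,
                              tad_spec = NULL, loop_spec = NULL,
                              compartment_profile = NULL,
                              compartment_strength = 0,
                              bias_vector = NULL,
                              depth = 1e6,
                              gc_track = NULL) {
  stopifnot(n_bins >= 2, resolution > 0, depth > 0)
  if (!is.null(tad_spec)) {
    tad_spec <- as.data.frame(tad_spec)
    stopifnot(all(c("start_bin", "end_bin", "intra_boost") %in% names(tad_spec)))
    o <- order(tad_spec$start_bin)
    tad_spec <- tad_spec[o, , drop = FALSE]
    if (any(tad_spec$end_bin <= tad_spec$start_bin) ||
        any(tad_spec$start_bin < 0) || any(tad_spec$end_bin > n_bins))
      stop("TADs must be non-empty and inside the map")
    if (nrow(tad_spec) > 1 &&
        any(tad_spec$start_bin[-1] < tad_spec$end_bin[-nrow(tad_spec)]))
      stop("TADs must be non-overlapping and ordered")
    if (any(tad_spec$intra_boost < 1)) stop("intra_boost must be >= 1")
  }
  if (!is.null(loop_spec)) {
    loop_spec <- as.data.frame(loop_spec)
    stopifnot(all(c("bin_i", "bin_j", "loop_boost") %in% names(loop_spec)))
    if (any(loop_spec$bin_i < 0) || any(loop_spec$bin_j >= n_bins) ||
        any(loop_spec$bin_i >= loop_spec$bin_j))
      stop("loop anchors must satisfy 0 <= bin_i < bin_j < n_bins")
    if (any(loop_spec$loop_boost < 1)) stop("loop_boost must be >= 1")
  }
  if (!is.null(compartment_profile)) {
    stopifnot(length(compartment_profile) == n_bins,
              all(abs(compartment_profile) <= 1))
  }
  if (!is.null(bias_vector)) {
    stopifnot(length(bias_vector) == n_bins)
    if (any(bias_vector <= 0)) stop("bias_vector must be strictly positive")
  }
  if (is.null(gc_track)) {
    base <- if (is.null(compartment_profile)) rep(0, n_bins) else compartment_profile
    gc_track <- 0.41 + 0.05 * base
  }
  stopifnot(length(gc_track) == n_bins, all(gc_track >= 0), all(gc_track <= 1))
  structure(list(seed = as.integer(seed), n_bins = as.integer(n_bins),
                 resolution = as.integer(resolution),
                 decay_exponent = decay_exponent,
                 tad_spec = tad_spec, loop_spec = loop_spec,
                 compartment_profile = compartment_profile,
                 compartment_strength = compartment_strength,
                 bias_vector = bias_vector, depth = depth,
                 gc_track = gc_track),
            class = "simulation_config")
}

#' Perturbation configuration for the "treated" condition
#'
#' Parameterizes how the treated dataset is derived from the control
#' generative model: TAD border weakening, loop and contact dropout,
#' de-novo contacts, compartment mixing, and peak dropout/jitter. The
#' magnitudes are free parameters of the emulation; [perturbation_preset()]
#' packages the default treated condition.
#'
#' @param border_weaken_factor in (0, 1]; multiplies `(intra_boost - 1)`,
#'   so 1 leaves TADs intact and values near 0 erase them.
#' @param loop_retention probability a control loop dot survives.
#' @param contact_retention probability an annotated control contact survives.
#' @param de_novo_rate expected novel contacts per Mb in the treated set.
#' @param compartment_mix in `[0, 1]`; fraction of each bin's compartment
#'   value swapped with a random permutation of the profile.
#' @param peak_dropout probability a control peak is lost.
#' @param peak_jitter_sd s.d. (bp) of independent boundary jitter on kept peaks.
#' @param novel_peak_rate expected novel peaks per Mb.
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(border_weaken_factor = 1,
                                loop_retention = 1,
                                contact_retention = 1,
                                de_novo_rate = 0,
                                compartment_mix = 0,
                                peak_dropout = 0,
                                peak_jitter_sd = 0,
                                novel_peak_rate = 0) {
  p <- c(loop_retention = loop_retention, contact_retention = contact_retention,
         compartment_mix = compartment_mix, peak_dropout = peak_dropout)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  if (border_weaken_factor <= 0 || border_weaken_factor > 1)
    stop("border_weaken_factor must lie in (0, 1]")
  stopifnot(de_novo_rate >= 0, peak_jitter_sd >= 0, novel_peak_rate >= 0)
  structure(list(border_weaken_factor = border_weaken_factor,
                 loop_retention = loop_retention,
                 contact_retention = contact_retention,
                 de_novo_rate = de_novo_rate,
                 compartment_mix = compartment_mix,
                 peak_dropout = peak_dropout,
                 peak_jitter_sd = peak_jitter_sd,
                 novel_peak_rate = novel_peak_rate),
            class = "perturbation_config")
}

#' Default treated-condition perturbation
#'
#' The treated preset encodes the observed curaxin effects at the
#' magnitudes the downstream comparisons are run at: ~40% of CTCF binding
#' peaks lost (`peak_dropout = 0.4`), ~30% of annotated distal contacts
#' persisting (`contact_retention = 0.3`), and border weakening, loop loss
#' and compartment mixing at 0.5 each.
#'
#' @param name `"treated"` (perturbed) or `"control"` (identity).
#' @return A [perturbation_config].
#' @export
perturbation_preset <- function(name = c("treated", "control")) {
  name <- match.arg(name)
  if (name == "control") return(perturbation_config())
  perturbation_config(border_weaken_factor = 0.5,
                      loop_retention = 0.5,
                      contact_retention = 0.3,
                      de_novo_rate = 2,
                      compartment_mix = 0.5,
                      peak_dropout = 0.4,
                      peak_jitter_sd = 20,
                      novel_peak_rate = 0.5)
}

# Expected (pre-sampling) matrix and the effective (possibly perturbed)
# structures used to build it.
build_expected <- function(config, perturbation = NULL) {
  n <- config$n_bins
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(0, n, n)
  off <- s > 0
  E[off] <- s[off]^config$decay_exponent
  tads <- config$tad_spec
  if (!is.null(tads) && !is.null(perturbation)) {
    tads$intra_boost <- 1 + perturbation$border_weaken_factor * (tads$intra_boost - 1)
  }
  if (!is.null(tads)) {
    for (t in seq_len(nrow(tads))) {
      idx <- (tads$start_bin[t] + 1L):tads$end_bin[t]
      E[idx, idx] <- E[idx, idx] * tads$intra_boost[t]
    }
  }
  loops <- config$loop_spec
  novel_loops <- NULL
  if (!is.null(loops) && !is.null(perturbation)) {
    keep <- with_seed(sub_seed(config$seed, "loop_retention"),
                      stats::runif(nrow(loops)) < perturbation$loop_retention)
    loops <- loops[keep, , drop = FALSE]
  }
  if (!is.null(perturbation) && perturbation$de_novo_rate > 0) {
    mb <- n * config$resolution / 1e6
    novel_loops <- with_seed(sub_seed(config$seed, "de_novo_loops"), {
      k <- stats::rpois(1, perturbation$de_novo_rate * mb)
      if (k > 0) {
        i <- sample.int(n, k, replace = TRUE) - 1L
        d <- sample(3:min(100, n - 1L), k, replace = TRUE)
        j <- pmin(i + d, n - 1L)
        ok <- j > i
        data.frame(bin_i = i[ok], bin_j = j[ok], loop_boost = 4)
      } else NULL
    })
    loops <- rbind(loops, novel_loops)
  }
  if (!is.null(loops) && nrow(loops)) {
    for (k in seq_len(nrow(loops))) {
      i <- loops$bin_i[k] + 1L; j <- loops$bin_j[k] + 1L
      E[i, j] <- E[i, j] * loops$loop_boost[k]
      E[j, i] <- E[i, j]
    }
  }
  cp <- config$compartment_profile
  if (!is.null(cp) && !is.null(perturbation) && perturbation$compartment_mix > 0) {
    perm <- with_seed(sub_seed(config$seed, "compartment_mix"), sample.int(n))
    cp <- (1 - perturbation$compartment_mix) * cp +
      perturbation$compartment_mix * cp[perm]
  }
  if (!is.null(cp) && config$compartment_strength > 0) {
    fac <- pmax(1 + config$compartment_strength * outer(cp, cp), 0.05)
    E[off] <- E[off] * fac[off]
  }
  if (!is.null(config$bias_vector)) {
    b <- config$bias_vector
    E <- E * outer(b, b)
  }
  diag(E) <- 0
  tot <- sum(E[upper.tri(E)])
  if (tot <= 0) stop("configuration yields a non-positive expected map")
  E <- E * (config$depth / tot)
  if (any(E[off] <= 0)) stop("configuration yields non-positive expected cells")
  list(E = E, tads = tads, loops = loops, compartments = cp)
}

#' Expected (noiseless) contact map under a configuration
#'
#' Returns the pre-sampling expected matrix as a [contact_map]; useful for
#' noiseless checks of downstream estimators.
#'
#' @inheritParams simulate_contact_map
#' @return A [contact_map] whose cells are the Poisson means.
#' @export
expected_contact_map <- function(config, perturbation = NULL) {
  parts <- build_expected(config, perturbation)
  contact_map(parts$E, resolution = config$resolution)
}

#' Simulate a binned cis contact map with recorded ground truth
#'
#' Builds the expected matrix `E[i,j] = depth-scaled decay(|i-j|) x TAD
#' boost x loop boost x compartment factor x bias_i bias_j`, applies the
#' perturbation (border weakening, loop dropout, de-novo dots, compartment
#' mixing) to the generative structures if given, and draws each
#' upper-triangle cell independently from `Poisson(E[i,j])`, mirrored to
#' symmetry.
#'
#' @param config a [simulation_config].
#' @param perturbation optional [perturbation_config]; absent for the
#'   control condition.
#' @return A list with `map` (a [contact_map]) and `truth` (effective TADs,
#'   loops, compartment profile, and the expected matrix).
#' @export
simulate_contact_map <- function(config, perturbation = NULL) {
  parts <- build_expected(config, perturbation)
  n <- config$n_bins
  stream <- if (is.null(perturbation)) "map_control" else "map_treated"
  counts <- with_seed(sub_seed(config$seed, stream), {
    ut <- upper.tri(parts$E)
    M <- matrix(0, n, n)
    M[ut] <- stats::rpois(sum(ut), parts$E[ut])
    M + t(M)
  })
  map <- contact_map(counts, resolution = config$resolution)
  list(map = map,
       truth = list(true_tads = parts$tads, true_loops = parts$loops,
                    true_compartments = parts$compartments,
                    expected = parts$E))
}

#' Simulate paired control/treated peak sets
#'
#' Control peaks are placed without overlap along the chromosome; each is
#' independently dropped with probability `peak_dropout`, kept peaks get
#' independent Gaussian boundary jitter, and novel peaks are added at
#' `novel_peak_rate` per Mb. Peaks jittered past the chromosome ends are
#' clipped.
#'
#' @param config a [simulation_config] (defines chromosome size and seed).
#' @param perturbation a [perturbation_config] with the peak parameters set.
#' @param n_peaks number of control peaks.
#' @param peak_width two-element range (bp) of uniform peak widths.
#' @return A list with `control`, `treated` (interval data.frames with
#'   `chrom`, `start`, `end`, `name`, `score`) and `truth` (kept/dropped/
#'   novel peak names).
#' @export
simulate_peak_sets <- function(config, perturbation, n_peaks = 1000L,
                               peak_width = c(200L, 500L)) {
  chrom_len <- config$n_bins * config$resolution
  place <- function(k, avoid = NULL, rng_name) {
    with_seed(sub_seed(config$seed, rng_name), {
      taken <- avoid
      out <- NULL
      tries <- 0L
      while ((is.null(out) || nrow(out) < k) && tries < 50L) {
        tries <- tries + 1L
        need <- k - if (is.null(out)) 0L else nrow(out)
        w <- round(stats::runif(2L * need, peak_width[1], peak_width[2]))
        s <- round(stats::runif(2L * need, 0, chrom_len - w))
        cand <- data.frame(start = s, end = s + w)
        cand <- cand[order(cand$start), , drop = FALSE]
        pool <- rbind(taken, out, cand)
        keep <- rep(TRUE, nrow(cand))
        # accept candidates that overlap nothing already accepted
        acc_s <- c(taken$start, out$start); acc_e <- c(taken$end, out$end)
        for (r in seq_len(nrow(cand))) {
          if (any(cand$start[r] < acc_e & cand$end[r] > acc_s)) {
            keep[r] <- FALSE
          } else {
            acc_s <- c(acc_s, cand$start[r]); acc_e <- c(acc_e, cand$end[r])
          }
        }
        cand <- cand[keep, , drop = FALSE]
        out <- rbind(out, cand)
        if (nrow(out) > k) out <- out[seq_len(k), , drop = FALSE]
      }
      out
    })
  }
  ctrl <- place(n_peaks, rng_name = "peaks_control")
  ctrl <- ctrl[order(ctrl$start), ]
  control <- data.frame(chrom = "chrS", start = ctrl$start, end = ctrl$end,
                        name = sprintf("peak_%04d", seq_len(nrow(ctrl))),
                        score = 0)
  res <- with_seed(sub_seed(config$seed, "peaks_treated"), {
    drop <- stats::runif(nrow(control)) < perturbation$peak_dropout
    kept <- control[!drop, , drop = FALSE]
    if (nrow(kept) && perturbation$peak_jitter_sd > 0) {
      kept$start <- kept$start + round(stats::rnorm(nrow(kept), 0, perturbation$peak_jitter_sd))
      kept$end <- kept$end + round(stats::rnorm(nrow(kept), 0, perturbation$peak_jitter_sd))
      bad <- kept$end <= kept$start
      kept$end[bad] <- kept$start[bad] + 1L
      clipped <- kept$start < 0 | kept$end > chrom_len
      kept$start <- pmax(kept$start, 0)
      kept$end <- pmin(kept$end, chrom_len)
      attr(kept, "n_clipped") <- sum(clipped)
    }
    list(drop = drop, kept = kept)
  })
  n_novel <- with_seed(sub_seed(config$seed, "peaks_novel_n"),
                       stats::rpois(1, perturbation$novel_peak_rate * chrom_len / 1e6))
  novel <- NULL
  if (n_novel > 0) {
    nv <- place(n_novel, avoid = res$kept[, c("start", "end")],
                rng_name = "peaks_novel")
    if (!is.null(nv) && nrow(nv))
      novel <- data.frame(chrom = "chrS", start = nv$start, end = nv$end,
                          name = sprintf("novel_%04d", seq_len(nrow(nv))),
                          score = 0)
  }
  treated <- rbind(res$kept, novel)
  treated <- treated[order(treated$start), , drop = FALSE]
  rownames(treated) <- NULL
  list(control = control, treated = treated,
       truth = list(dropped_peak_ids = control$name[res$drop],
                    kept_peak_ids = control$name[!res$drop],
                    novel_peak_ids = novel$name))
}

#' Simulate paired control/treated distal contact sets
#'
#' Control records are unique anchor-bin pairs separated by at least
#' `min_sep`; the treated set keeps each with probability
#' `contact_retention` and adds de-novo pairs at `de_novo_rate` per Mb.
#'
#' @param config a [simulation_config].
#' @param perturbation a [perturbation_config] with `contact_retention` set.
#' @param n_contacts number of control contact records.
#' @param min_sep minimum anchor separation in bp (default 40 kb).
#' @return A list with `control`, `treated` (data.frames with `bin1`,
#'   `bin2`, `id`) and `truth` (`retained_contact_ids`, `de_novo_ids`).
#' @export
simulate_contact_sets <- function(config, perturbation, n_contacts = 2000L,
                                  min_sep = 40000L) {
  n <- config$n_bins
  min_bins <- ceiling(min_sep / config$resolution)
  if (min_bins >= n) stop("min_sep exceeds the map span")
  draw_pairs <- function(k, exclude_keys = character(0), rng_name) {
    with_seed(sub_seed(config$seed, rng_name), {
      got <- data.frame(bin1 = integer(0), bin2 = integer(0))
      keys <- exclude_keys
      while (nrow(got) < k) {
        need <- 2L * (k - nrow(got))
        b1 <- sample.int(n - min_bins, need, replace = TRUE) - 1L
        d <- min_bins + stats::rgeom(need, prob = 2 / (n - min_bins))
        b2 <- b1 + d
        ok <- b2 < n
        cand <- unique(data.frame(bin1 = b1[ok], bin2 = b2[ok]))
        kk <- paste(cand$bin1, cand$bin2)
        cand <- cand[!(kk %in% keys), , drop = FALSE]
        got <- rbind(got, cand)
        keys <- c(keys, paste(cand$bin1, cand$bin2))
      }
      got[seq_len(k), , drop = FALSE]
    })
  }
  ctrl <- draw_pairs(n_contacts, rng_name = "contacts_control")
  ctrl <- ctrl[order(ctrl$bin1, ctrl$bin2), ]
  ctrl$id <- sprintf("ct_%05d", seq_len(nrow(ctrl)))
  rownames(ctrl) <- NULL
  keep <- with_seed(sub_seed(config$seed, "contacts_retention"),
                    stats::runif(nrow(ctrl)) < perturbation$contact_retention)
  mb <- n * config$resolution / 1e6
  n_novel <- with_seed(sub_seed(config$seed, "contacts_novel_n"),
                       stats::rpois(1, perturbation$de_novo_rate * mb))
  novel <- NULL
  if (n_novel > 0) {
    novel <- draw_pairs(n_novel, exclude_keys = paste(ctrl$bin1, ctrl$bin2),
                        rng_name = "contacts_novel")
    novel$id <- sprintf("dn_%05d", seq_len(nrow(novel)))
  }
  treated <- rbind(ctrl[keep, , drop = FALSE], novel)
  treated <- treated[order(treated$bin1, treated$bin2), , drop = FALSE]
  rownames(treated) <- NULL
  list(control = ctrl, treated = treated,
       truth = list(retained_contact_ids = ctrl$id[keep],
                    lost_contact_ids = ctrl$id[!keep],
                    de_novo_ids = novel$id))
}

#' Simulate a gene annotation with designated gene deserts
#'
#' Genes are placed without overlap outside the designated desert regions;
#' per-bin nascent-RNA counts are Poisson with mean proportional to local
#' gene occupancy plus a small background, so deserts carry near-zero
#' signal.
#'
#' @param config a [simulation_config].
#' @param deserts data.frame with `start`, `end` (bp) of gene-free regions;
#'   defaults to one 1-Mb desert in the middle of the chromosome.
#' @param n_genes number of genes to attempt to place.
#' @param gene_width two-element bp range of uniform gene widths.
#' @param rna_rate expected RNA reads per fully gene-covered bin.
#' @param background_rate expected RNA reads per gene-free bin.
#' @return A list with `genes` (interval data.frame), `rna` (per-bin
#'   counts), `deserts` (the designated regions).
#' @export
simulate_genome_annotation <- function(config, deserts = NULL, n_genes = 120L,
                                       gene_width = c(20000L, 120000L),
                                       rna_rate = 100, background_rate = 0.5) {
  chrom_len <- config$n_bins * config$resolution
  if (is.null(deserts)) {
    mid <- floor(chrom_len / 2 / config$resolution) * config$resolution
    deserts <- data.frame(start = mid - 5e5, end = mid + 5e5)
  }
  genes <- with_seed(sub_seed(config$seed, "genes"), {
    out <- data.frame(start = numeric(0), end = numeric(0))
    tries <- 0L
    while (nrow(out) < n_genes && tries < 50L * n_genes) {
      tries <- tries + 1L
      w <- round(stats::runif(1, gene_width[1], gene_width[2]))
      if (w >= chrom_len) next
      s <- round(stats::runif(1, 0, chrom_len - w))
      e <- s + w
      in_desert <- any(s < deserts$end & e > deserts$start)
      overlaps <- nrow(out) > 0 && any(s < out$end & e > out$start)
      if (!in_desert && !overlaps) out <- rbind(out, data.frame(start = s, end = e))
    }
    out[order(out$start), , drop = FALSE]
  })
  genes_df <- data.frame(chrom = rep("chrS", nrow(genes)),
                         start = genes$start, end = genes$end,
                         name = sprintf("gene_%03d", seq_len(nrow(genes))),
                         score = rep(0, nrow(genes)))
  # fraction of each bin covered by genes
  occ <- rep(0, config$n_bins)
  bin_starts <- (seq_len(config$n_bins) - 1) * config$resolution
  for (g in seq_len(nrow(genes))) {
    lo <- genes$start[g]; hi <- genes$end[g]
    b0 <- floor(lo / config$resolution); b1 <- min(ceiling(hi / config$resolution) - 1, config$n_bins - 1)
    for (b in b0:b1) {
      cov <- min(hi, bin_starts[b + 1] + config$resolution) - max(lo, bin_starts[b + 1])
      occ[b + 1] <- occ[b + 1] + cov / config$resolution
    }
  }
  occ <- pmin(occ, 1)
  rna <- with_seed(sub_seed(config$seed, "rna"),
                   stats::rpois(config$n_bins, rna_rate * occ + background_rate))
  list(genes = genes_df, rna = rna, deserts = deserts)
}

#' spFRET mixture presets
#'
#' Two-state nucleosome-linker mixtures and the free-DNA single state, with
#' component means at the measured proximity-ratio peak positions:
#' untreated nucleosomes 0.04 (open linkers) / 0.47 (closed linkers) at
#' 27%/73%; drug-treated 0.04 / 0.38 at 39%/61%; free DNA a single state at
#' 0.02. Component s.d.s and the event-intensity distribution are
#' generator choices (see the methods vignette).
#'
#' @param name one of `"minus_drug"`, `"plus_drug"`, `"free_dna"`.
#' @return A list with `weights`, `means`, `sds`, `n_default`,
#'   `log_total_mean`, `log_total_sd`.
#' @export
fret_preset <- function(name = c("minus_drug", "plus_drug", "free_dna")) {
  name <- match.arg(name)
  base <- list(log_total_mean = log(100), log_total_sd = 0.3)
  p <- switch(name,
    minus_drug = list(weights = c(open = 0.27, closed = 0.73),
                      means = c(0.04, 0.47), sds = c(0.10, 0.13),
                      n_default = 2832L),
    plus_drug = list(weights = c(open = 0.39, closed = 0.61),
                     means = c(0.04, 0.38), sds = c(0.10, 0.13),
                     n_default = 4310L),
    free_dna = list(weights = c(single = 1),
                    means = 0.02, sds = 0.06, n_default = 2000L))
  c(p, base)
}

#' Simulate single-particle FRET events
#'
#' Per event a latent conformational state is drawn by mixture weight, a
#' target proximity ratio from that state's Gaussian (redrawn while outside
#' the attainable range of the cross-talk-corrected ratio with non-negative
#' intensities), a total intensity from a log-normal, and donor/acceptor
#' intensities solved by inverting the proximity-ratio formula.
#'
#' @param preset a mixture preset as from [fret_preset()] (fields `weights`,
#'   `means`, `sds`, optionally `log_total_mean`, `log_total_sd`).
#' @param n number of events.
#' @param seed integer seed.
#' @return A data.frame of class `fret_events` with `event_id`, `I_donor`,
#'   `I_acceptor`, `proximity_ratio`, `state` (latent label).
#' @export
simulate_fret_events <- function(preset, n, seed = 1L) {
  w <- preset$weights
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (n <= 0) stop("n must be positive")
  k <- length(w)
  stopifnot(length(preset$means) == k, length(preset$sds) == k)
  lo <- -0.23
  hi <- 1 - 1e-6
  with_seed(seed, {
    state <- sample.int(k, n, replace = TRUE, prob = w)
    target <- stats::rnorm(n, preset$means[state], preset$sds[state])
    bad <- which(target <= lo | target >= hi)
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      guard <- guard + 1L
      target[bad] <- stats::rnorm(length(bad), preset$means[state[bad]],
                                  preset$sds[state[bad]])
      bad <- which(target <= lo | target >= hi)
    }
    total <- stats::rlnorm(n, preset$log_total_mean %||% log(100),
                           preset$log_total_sd %||% 0.3)
    # invert E = (Ia - 0.19 Id) / (Ia + 0.81 Id) at fixed Ia + Id = total
    r <- (0.19 + 0.81 * target) / (1 - target)
    Id <- total / (1 + r)
    Ia <- total - Id
    ev <- data.frame(event_id = sprintf("ev_%05d", seq_len(n)),
                     I_donor = Id, I_acceptor = Ia)
    ev$proximity_ratio <- proximity_ratio(ev$I_acceptor, ev$I_donor)
    ev$state <- names(w)[state] %||% as.character(state)
    class(ev) <- c("fret_events", class(ev))
    ev
  })
}
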