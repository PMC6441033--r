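#' Call distal intra-TAD contacts against a domain-conditioned background
#'
#' A deliberately simple over-expected caller: within each TAD, the
#' expected balanced value at separation `s` is the within-domain mean at
#' that separation, shrunk toward the chromosome-wide distance-decay mean
#' with weight proportional to the within-domain cell count. Each
#' within-domain cell at separation >= `min_sep` is tested with an
#' upper-tail Poisson p-value on its raw count (expected rescaled to raw
#' units through the balancing biases) and Benjamini-Hochberg corrected
#' across all tested cells. This is a declared methodological simplification
#' of hierarchical promoter-enhancer callers, not a reimplementation of one.
#'
#' @param map a balanced [contact_map] carrying its `bias` vector.
#' @param seg a [armatus_segment()] segmentation on the same bins.
#' @param fdr discovery threshold on BH-adjusted q-values (default 0.05).
#' @param min_sep minimum anchor separation in bp (default 40 kb).
#' @param prior_strength pseudo-cell weight of the chromosome-wide decay in
#'   the shrinkage (default 10).
#' @return A data.frame of class `contact_set`: `bin1`, `bin2` (0-based),
#'   `enrichment` (observed/expected, balanced units), `q_value`; the number
#'   of tested cells in attribute `n_tested`.
#' @export
call_contacts <- function(map, seg, fdr = 0.05, min_sep = 40000L,
                          prior_strength = 10) {
  if (!isTRUE(map$balanced) || is.null(map$bias))
    stop("call_contacts expects a balanced map with biases")
  W <- map$counts
  n <- nrow(W)
  res <- map$resolution
  min_bins <- as.integer(ceiling(min_sep / res))
  mask <- map$mask
  bias <- map$bias
  # chromosome-wide decay on the balanced map
  chrom_decay <- rep(NA_real_, n - 1L)
  for (d in seq_len(n - 1L)) {
    i <- seq_len(n - d); j <- i + d
    ok <- !mask[i] & !mask[j]
    if (any(ok)) chrom_decay[d] <- mean(W[cbind(i[ok], j[ok])])
  }
  tested <- NULL
  for (t in seq_len(nrow(seg$domains))) {
    a <- seg$domains$start_bin[t] + 1L
    b <- seg$domains$end_bin[t]
    size <- b - a + 1L
    if (size <= min_bins) next
    for (d in min_bins:(size - 1L)) {
      i <- a:(b - d); j <- i + d
      ok <- !mask[i] & !mask[j]
      if (!any(ok)) next
      i <- i[ok]; j <- j[ok]
      vals <- W[cbind(i, j)]
      m_dom <- mean(vals)
      cd <- chrom_decay[d]
      expected_bal <- if (is.finite(cd))
        (length(vals) * m_dom + prior_strength * cd) /
          (length(vals) + prior_strength) else m_dom
      raw <- round(vals * bias[i] * bias[j])
      exp_raw <- expected_bal * bias[i] * bias[j]
      p <- stats::ppois(raw - 1, exp_raw, lower.tail = FALSE)
      tested <- rbind(tested, data.frame(
        bin1 = i - 1L, bin2 = j - 1L,
        enrichment = vals / expected_bal, p_value = p))
    }
  }
  if (is.null(tested)) {
    out <- data.frame(bin1 = integer(0), bin2 = integer(0),
                      enrichment = numeric(0), q_value = numeric(0))
    attr(out, "n_tested") <- 0L
    class(out) <- c("contact_set", class(out))
    return(out)
  }
  tested$q_value <- stats::p.adjust(tested$p_value, method = "BH")
  out <- tested[tested$q_value < fdr,
                c("bin1", "bin2", "enrichment", "q_value"), drop = FALSE]
  out <- out[order(out$bin1, out$bin2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(tested)
  class(out) <- c("contact_set", class(out))
  out
}

#' Classify contact persistence between conditions
#'
#' Matches control and treated contact records one-to-one, greedily by
#' total anchor distance, accepting matches with both anchors within
#' `tol_bins`. Matched control records are preserved, unmatched ones lost;
#' treated records matching no control record are de novo.
#'
#' @param control,treated data.frames with `bin1`, `bin2` columns.
#' @param tol_bins anchor tolerance in bins (default 1).
#' @return A list with `counts` (`preserved`, `lost`, `de_novo`),
#'   `fractions` (`preserved` and `lost` of control, `de_novo` of treated),
#'   and `matches` (paired row indices).
#' @export
classify_persistence <- function(control, treated, tol_bins = 1L) {
  nc <- nrow(control); nt <- nrow(treated)
  cand <- NULL
  if (nc > 0 && nt > 0) {
    # candidate pairs via anchor-window join
    tk <- new.env(parent = emptyenv())
    for (r in seq_len(nt)) {
      k <- paste(treated$bin1[r], treated$bin2[r])
      assign(k, c(get0(k, envir = tk, ifnotfound = integer(0)), r), envir = tk)
    }
    offs <- expand.grid(d1 = -tol_bins:tol_bins, d2 = -tol_bins:tol_bins)
    hits <- vector("list", nrow(offs))
    for (o in seq_len(nrow(offs))) {
      keys <- paste(control$bin1 + offs$d1[o], control$bin2 + offs$d2[o])
      found <- lapply(keys, function(k) get0(k, envir = tk, ifnotfound = NULL))
      ci <- rep(seq_len(nc), lengths(found))
      if (length(ci))
        hits[[o]] <- data.frame(ci = ci, ti = unlist(found),
                                dist = abs(offs$d1[o]) + abs(offs$d2[o]))
    }
    cand <- do.call(rbind, hits)
  }
  matches <- data.frame(ci = integer(0), ti = integer(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist, cand$ci, cand$ti), , drop = FALSE]
    used_c <- logical(nc); used_t <- logical(nt)
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_c[cand$ci[r]] && !used_t[cand$ti[r]]) {
        keep[r] <- TRUE
        used_c[cand$ci[r]] <- TRUE
        used_t[cand$ti[r]] <- TRUE
      }
    }
    matches <- cand[keep, c("ci", "ti"), drop = FALSE]
  }
  preserved <- nrow(matches)
  counts <- c(preserved = preserved, lost = nc - preserved,
              de_novo = nt - preserved)
  fractions <- c(preserved = if (nc) preserved / nc else NA_real_,
                 lost = if (nc) 1 - preserved / nc else NA_real_,
                 de_novo = if (nt) (nt - preserved) / nt else NA_real_)
  list(counts = counts, fractions = fractions, matches = matches)
}

#' Per-gene counts of changed contacts at gene-overlapping anchors
#'
#' Annotates each gene with the number of contact records (e.g. the lost or
#' de-novo sets from [classify_persistence()]) having at least one anchor
#' bin within `tol_bins` bins of the gene.
#'
#' @param contacts data.frame with `bin1`, `bin2` (0-based bins).
#' @param genes interval data.frame (`start`, `end` in bp).
#' @param resolution map resolution in bp.
#' @param tol_bins anchor slack in bins (default 1).
#' @return `genes` with an added `n_contacts` column.
#' @export
anchor_gene_overlap <- function(contacts, genes, resolution, tol_bins = 1L) {
  genes$n_contacts <- 0L
  if (!nrow(contacts) || !nrow(genes)) return(genes)
  anchors <- unique(data.frame(
    row = rep(seq_len(nrow(contacts)), 2L),
    bin = c(contacts$bin1, contacts$bin2)))
  a_start <- (anchors$bin - tol_bins) * resolution
  a_end <- (anchors$bin + 1L + tol_bins) * resolution
  ar <- IRanges::IRanges(start = a_start + 1L, end = a_end)  # 1-based closed
  gr <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  ov <- IRanges::findOverlaps(gr, ar)
  if (length(ov)) {
    hit <- unique(data.frame(gene = S4Vectors::queryHits(ov),
                             row = anchors$row[S4Vectors::subjectHits(ov)]))
    tab <- table(hit$gene)
    genes$n_contacts[as.integer(names(tab))] <- as.integer(tab)
  }
  genes
}
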