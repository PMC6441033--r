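#' Annotate gene deserts
#'
#' Gene deserts are the intergenic gaps — the complement of the merged gene
#' span within the chromosome — of length at least `min_length` (inclusive).
#'
#' @param genes interval data.frame (`start`, `end`, bp, 0-based half-open;
#'   both strands merged).
#' @param chrom_length chromosome length in bp.
#' @param min_length minimum desert length in bp (default 500 kb).
#' @return A data.frame of deserts (`start`, `end`) with attribute
#'   `min_length`.
#' @export
annotate_deserts <- function(genes, chrom_length, min_length = 500000L) {
  if (nrow(genes) == 0) {
    out <- data.frame(start = 0, end = chrom_length)
  } else {
    gr <- IRanges::reduce(IRanges::IRanges(start = genes$start + 1L,
                                           end = genes$end))
    gaps <- IRanges::gaps(gr, start = 1L, end = chrom_length)
    out <- data.frame(start = BiocGenerics::start(gaps) - 1L,
                      end = BiocGenerics::end(gaps))
  }
  out <- out[out$end - out$start >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_length") <- min_length
  out
}

#' Per-bin normalized nascent-RNA signal
#'
#' Divides per-bin read counts by the total mapped reads (default), giving
#' each bin's share of the library; the literal per-bin-count denominator
#' is kept available behind the `denominator` switch.
#'
#' @param bin_counts per-bin read counts.
#' @param bin_size bin width in bp (default 20 kb).
#' @param denominator `"reads"` (total mapped reads) or `"bins"` (number of
#'   bins).
#' @return A data.frame with `start`, `end`, `signal`.
#' @export
bin_rna_signal <- function(bin_counts, bin_size = 20000L,
                           denominator = c("reads", "bins")) {
  denominator <- match.arg(denominator)
  total <- sum(bin_counts)
  if (total <= 0) stop("total mapped reads must be positive")
  denom <- if (denominator == "reads") total else length(bin_counts)
  n <- length(bin_counts)
  data.frame(start = (seq_len(n) - 1) * bin_size,
             end = seq_len(n) * bin_size,
             signal = bin_counts / denom)
}

#' Genome-wide versus desert-restricted RNA signal summary
#'
#' @param signal a [bin_rna_signal()] data.frame.
#' @param deserts an [annotate_deserts()] data.frame.
#' @return A list with per-group `mean`, `sem`, `n` for all bins and for
#'   bins fully inside deserts.
#' @export
rna_signal_summary <- function(signal, deserts) {
  in_desert <- rep(FALSE, nrow(signal))
  for (d in seq_len(nrow(deserts))) {
    in_desert <- in_desert |
      (signal$start >= deserts$start[d] & signal$end <= deserts$end[d])
  }
  smy <- function(x) list(mean = mean(x),
                          sem = stats::sd(x) / sqrt(length(x)),
                          n = length(x))
  list(genome = smy(signal$signal),
       desert = if (any(in_desert)) smy(signal$signal[in_desert]) else
         list(mean = NA_real_, sem = NA_real_, n = 0L))
}

#' Compare TAD border strength inside gene deserts with all borders
#'
#' Evaluates border strength for a (typically treated-condition)
#' segmentation, splits out the borders whose border bin lies inside a
#' desert, and tests desert borders against all borders with an unpaired
#' two-sided t-test — the null being that drug-induced border weakening is
#' independent of transcriptional activity.
#'
#' @param map a balanced [contact_map].
#' @param seg its [armatus_segment()] segmentation.
#' @param deserts an [annotate_deserts()] data.frame.
#' @return A list with `all` and `desert` strength vectors, quartile
#'   `summary`, and `test` (`NULL` with fewer than 2 desert borders).
#' @export
desert_border_comparison <- function(map, seg, deserts) {
  borders <- border_strength(map, seg)
  borders <- borders[borders$valid, , drop = FALSE]
  res <- map$resolution
  mid <- (borders$border_bin + 0.5) * res
  in_desert <- rep(FALSE, nrow(borders))
  for (d in seq_len(nrow(deserts))) {
    in_desert <- in_desert |
      (mid >= deserts$start[d] & mid < deserts$end[d])
  }
  all_s <- borders$strength
  des_s <- borders$strength[in_desert]
  test <- NULL
  if (length(des_s) >= 2L && length(all_s) >= 2L) {
    if (length(des_s) == length(all_s) && all(sort(des_s) == sort(all_s))) {
      test <- list(statistic = c(t = 0), p.value = 1, identical_samples = TRUE)
    } else if (stats::sd(all_s) > 0 || stats::sd(des_s) > 0) {
      test <- stats::t.test(des_s, all_s)
    }
  }
  list(all = all_s, desert = des_s,
       summary = list(
         all = stats::quantile(all_s, c(0.25, 0.5, 0.75), na.rm = TRUE),
         desert = if (length(des_s))
           stats::quantile(des_s, c(0.25, 0.5, 0.75), na.rm = TRUE) else NULL),
       test = test)
}
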