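# Enrichment and coverage QC: per-locus depth, on/off-target averages and
# ratio, 5-kb off-target bins, read-length filtering, down-sampling, and the
# time-lag carryover estimate.

#' Coverage and enrichment statistics
#'
#' Reads at or below `min_read_len` are excluded before any depth
#' computation (the enrichment software ejects rejected molecules early, so
#' very short reads are out-of-target by construction). On-target depth is
#' the mean per-base depth over each target window; the off-target genome is
#' tiled in `bin_bp` bins (bins overlapping a target are excluded) and
#' zero-coverage bins count toward the off-target average.
#'
#' @param alignments Alignment table (see [read_alignments()]).
#' @param bed Target BED data.frame (`chrom, start, end, name`).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param min_read_len Read-length cutoff in bp (default 1000).
#' @param bin_bp Off-target bin width (default 5000).
#' @return A `coverage_stats` list: `per_locus` (data.frame `name, chrom,
#'   start, end, depth`), `off_bins` (BEDGRAPH-style data.frame),
#'   `on_target_avg`, `off_target_avg`, `enrichment_ratio` (`Inf` when no
#'   off-target coverage), `n_reads_filtered`.
#' @export
coverage_stats <- function(alignments, bed, contig_lengths,
                           min_read_len = 1000L, bin_bp = 5000L) {
  if (is.null(bed) || nrow(bed) == 0L) stop_validation("empty target BED")
  al <- alignments[bitwAnd(alignments$flag, 4L) == 0L, , drop = FALSE]
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(al$cigar)
  n_filtered <- sum(qlen <= min_read_len)
  al <- al[qlen > min_read_len, , drop = FALSE]

  rwidth <- if (nrow(al)) GenomicAlignments::cigarWidthAlongReferenceSpace(al$cigar) else integer(0)
  cov <- lapply(names(contig_lengths), function(ct) {
    sel <- al$chrom == ct
    ir <- IRanges::IRanges(start = al$pos[sel], width = rwidth[sel])
    IRanges::coverage(ir, width = contig_lengths[[ct]])
  })
  names(cov) <- names(contig_lengths)

  depth_over <- function(ct, s0, e1) {  # 0-based start, 1-based inclusive end
    if (!ct %in% names(cov)) return(NA_real_)
    v <- cov[[ct]]
    e1 <- min(e1, length(v))
    if (e1 <= s0) return(NA_real_)
    mean(as.numeric(v[seq(s0 + 1L, e1)]))
  }
  per_locus <- data.frame(name = bed$name, chrom = bed$chrom,
                          start = bed$start, end = bed$end,
                          depth = mapply(function(ct, s, e)
                            depth_over(ct, s, e), bed$chrom, bed$start, bed$end),
                          stringsAsFactors = FALSE)
  rownames(per_locus) <- NULL
  on_avg <- mean(per_locus$depth, na.rm = TRUE)

  bins <- list()
  for (ct in names(contig_lengths)) {
    len <- contig_lengths[[ct]]
    starts <- seq(0L, len - 1L, by = bin_bp)
    ends <- pmin(starts + bin_bp, len)
    tgt <- bed[bed$chrom == ct, , drop = FALSE]
    if (nrow(tgt)) {
      ov <- IRanges::overlapsAny(IRanges::IRanges(starts + 1L, ends),
                                 IRanges::IRanges(tgt$start + 1L, tgt$end))
    } else ov <- rep(FALSE, length(starts))
    if (all(ov)) next
    starts <- starts[!ov]; ends <- ends[!ov]
    d <- vapply(seq_along(starts), function(k)
      depth_over(ct, starts[k], ends[k]), numeric(1))
    bins[[ct]] <- data.frame(chrom = ct, start = starts, end = ends, depth = d,
                             stringsAsFactors = FALSE)
  }
  off_bins <- if (length(bins)) do.call(rbind, bins) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               depth = numeric(0))
  rownames(off_bins) <- NULL
  off_avg <- if (nrow(off_bins)) mean(off_bins$depth) else 0
  structure(list(per_locus = per_locus, off_bins = off_bins,
                 on_target_avg = on_avg, off_target_avg = off_avg,
                 enrichment_ratio = enrichment_ratio(on_avg, off_avg),
                 n_reads_filtered = n_filtered),
            class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("coverage_stats: on-target %.2fx over %d window(s), off-target %.4gx, ratio %s; %d short read(s) filtered\n",
              x$on_target_avg, nrow(x$per_locus), x$off_target_avg,
              ifelse(is.infinite(x$enrichment_ratio), "inf",
                     sprintf("%.0f", x$enrichment_ratio)),
              x$n_reads_filtered))
  invisible(x)
}

#' On/off-target enrichment ratio
#'
#' @param on_target_avg Mean on-target depth (x).
#' @param off_target_avg Mean off-target depth (x).
#' @return Dimensionless ratio; `Inf` when off-target depth is zero
#'   (serialized as the string `"inf"` in TSV output).
#' @export
enrichment_ratio <- function(on_target_avg, off_target_avg) {
  if (any(c(on_target_avg, off_target_avg) < 0))
    stop_validation("depths must be non-negative")
  if (off_target_avg == 0) return(Inf)
  on_target_avg / off_target_avg
}

#' Down-sample a read or measurement set
#'
#' Sampling without replacement of `floor(proportion * n)` elements;
#' deterministic for a fixed seed. The virtual depth of the result is
#' `proportion` times the original.
#'
#' @param x data.frame (rows sampled) or vector.
#' @param proportion Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Subset of `x` (identical to `x` when `proportion` is 1).
#' @export
downsample <- function(x, proportion, seed = 1) {
  if (proportion > 1 || proportion <= 0)
    stop_validation("proportion must lie in (0, 1]")
  if (proportion == 1) return(x)
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  k <- as.integer(floor(proportion * n + 1e-9))
  with_seed(seed, {
    idx <- sort(sample.int(n, k))
    if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
  })
}

#' Expected carryover depth of time-lag sampling
#'
#' Sequencing two samples serially on one flow cell with a nuclease wash in
#' between leaves a residual fraction of the first library; the expected
#' contaminating depth in the second run is simply the product of the first
#' run's depth and that residual fraction.
#'
#' @param previous_run_depth Depth of the previous run (x).
#' @param residual_fraction Library fraction surviving the wash.
#' @return Expected carryover depth (x).
#' @export
carryover_estimate <- function(previous_run_depth, residual_fraction) {
  if (previous_run_depth < 0 || residual_fraction < 0)
    stop_validation("inputs must be non-negative")
  previous_run_depth * residual_fraction
}
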