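# Allele-level CpG methylation classification and the in-silico
# bisulfite-like sequence conversion.

#' Bisulfite-like conversion of a read sequence
#'
#' Cytosines whose 5mC probability falls below `threshold` are converted to
#' thymine (as chemical bisulfite treatment would); methylated cytosines and
#' all non-C bases are untouched. Length-preserving and idempotent.
#'
#' @param sequence DNA string.
#' @param probs Numeric vector of per-base 5mC probabilities, same length as
#'   the sequence; `NA` (probability absent) is treated as 0.
#' @param threshold Methylation-probability cutoff (default 0.5).
#' @return Converted sequence string.
#' @export
bisulfite_like_convert <- function(sequence, probs, threshold = 0.5) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(probs) != length(chars))
    stop_validation("probability track length %d does not match sequence length %d",
                    length(probs), length(chars))
  probs[is.na(probs)] <- 0
  conv <- chars == "C" & probs < threshold
  chars[conv] <- "T"
  paste(chars, collapse = "")
}

#' Classify allele-level methylation from a per-read CpG probability table
#'
#' The methylated fraction of an allele is the mean, over its supporting
#' reads' CpG observations, of the indicator that the 5mC probability is at
#' least 0.5. Alleles with fewer than `min_cpg` CpG observations (or no
#' reads) are no-calls.
#'
#' @param meth Methylation table (`read_id, contig, pos, prob`), e.g. from
#'   [simulate_methylation()].
#' @param genotype A `locus_genotype` providing the per-allele
#'   supporting-read partition.
#' @param min_cpg Minimum CpG observations per allele (default 10).
#' @param hyper_min Methylated fraction at or above which an allele is
#'   `hypermethylated` (default 0.6).
#' @param unmeth_max Fraction at or below which it is `unmethylated`
#'   (default 0.2); in between is `partial`.
#' @return data.frame with one row per allele (`locus_id, allele_index,
#'   mean_meth_fraction, n_cpg, n_reads, label`).
#' @export
allele_methylation <- function(meth, genotype, min_cpg = 10L,
                               hyper_min = 0.6, unmeth_max = 0.2) {
  rows <- lapply(seq_along(genotype$supporting_reads), function(ai) {
    ids <- genotype$supporting_reads[[ai]]
    sub <- meth[meth$read_id %in% ids, , drop = FALSE]
    n_reads <- length(unique(sub$read_id))
    n_cpg <- nrow(sub)
    if (length(ids) == 0L || n_reads == 0L || n_cpg < min_cpg) {
      frac <- NA_real_; label <- "no-call"
    } else {
      frac <- mean(sub$prob >= 0.5)
      label <- if (frac >= hyper_min) "hypermethylated"
        else if (frac <= unmeth_max) "unmethylated" else "partial"
    }
    data.frame(locus_id = genotype$locus_id, allele_index = ai - 1L,
               mean_meth_fraction = frac, n_cpg = n_cpg, n_reads = n_reads,
               label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
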