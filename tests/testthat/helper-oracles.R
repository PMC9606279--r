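# Shared fixtures and independent oracles used across the test files.

# Subset of the shipped catalog (keeps SNP targets out unless asked).
sub_catalog <- function(ids, keep_snps = FALSE) {
  cat_ <- default_catalog()
  repeat_catalog(cat_$loci[cat_$loci$locus_id %in% ids, , drop = FALSE],
                 if (keep_snps) cat_$snps else NULL,
                 cat_$genome_size_bp)
}

# Independent minimal-cost segmentation oracle: top-down recursion over all
# segmentations (memoized on the suffix), no tie-breaking, no run tracking.
oracle_decompose_cost <- function(sequence, motifs, max_mm = 1L) {
  n <- nchar(sequence)
  memo <- rep(NA_integer_, n + 1L)
  mchars <- lapply(motifs, function(m) strsplit(m, "")[[1]])
  sc <- strsplit(sequence, "")[[1]]
  rec <- function(j) {
    if (j == n) return(0L)
    if (!is.na(memo[j + 1L])) return(memo[j + 1L])
    best <- 1L + rec(j + 1L)
    for (k in seq_along(motifs)) {
      L <- length(mchars[[k]])
      if (j + L <= n) {
        d <- sum(sc[(j + 1L):(j + L)] != mchars[[k]])
        tol <- if (L >= 4L) max_mm else 0L
        if (d <= tol) best <- min(best, d + rec(j + L))
      }
    }
    memo[j + 1L] <<- best
    best
  }
  rec(0L)
}

# Exhaustive two-cluster oracle: all 2^n binary partitions, minimal
# within-cluster sum of squares.
oracle_two_cluster <- function(x) {
  n <- length(x)
  wss <- function(v) if (length(v) <= 1L) 0 else sum((v - mean(v))^2)
  best <- list(w = Inf, left = x, right = numeric(0))
  for (mask in 1:(2^n - 2)) {
    sel <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L
    w <- wss(x[sel]) + wss(x[!sel])
    if (w < best$w - 1e-12) best <- list(w = w, left = sort(x[sel]), right = sort(x[!sel]))
  }
  best
}

# Hand-built single alignment record.
aln_record <- function(read_id = "r1", chrom = "ctg", pos = 1L, cigar = "100M",
                       seq = strrep("A", 100L), flag = 0L, mapq = 60L,
                       strand = "+") {
  data.frame(read_id = read_id, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, strand = strand,
             stringsAsFactors = FALSE)
}

# A bare locus row for synthetic alignment tests.
toy_locus <- function(locus_id = "L1", chrom = "ctg", start = 2000L, end = 2063L,
                      motif = "CAG", ref_units = 21L) {
  data.frame(locus_id = locus_id, gene = locus_id, disease = "toy",
             chrom = chrom, start = start, end = end,
             pathogenic_motifs = motif, benign_motifs = "",
             interruption_motifs = "", ref_units = ref_units,
             normal_max_units = NA_integer_, pathogenic_min_units = NA_integer_,
             inheritance = "AD", motif_len = nchar(motif),
             stringsAsFactors = FALSE)
}

make_genotype <- function(locus_id, units, hom = FALSE, status = "ok",
                          sup = list(character(0), character(0)),
                          ref_units = NULL) {
  cc <- if (is.null(ref_units)) c(NA_integer_, NA_integer_) else units - ref_units
  structure(list(locus_id = locus_id, status = status, homozygous = hom,
                 allele_units = units, allele_copy_change = cc,
                 supporting_reads = sup, n_spanning = length(unlist(sup)),
                 reason = NA_character_),
            class = "locus_genotype")
}
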