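# Per-read repeat copy-number measurement and two-allele genotyping.
#
# A read's copy-number change at a locus is read directly off its alignment:
# insertions whose reference anchor falls within one motif length of the
# tract boundaries (aligners place tract insertions at either boundary)
# count positive, deletions count by their overlap with the tract. The
# change in repeat units is the bp change divided by the motif length,
# rounded half toward zero so 1-2 bp of alignment jitter keeps unexpanded
# reads at zero.

#' Read an alignment file into a flat alignment table
#'
#' Accepts SAM or BAM; SAM is converted through [Rsamtools::asBam()].
#' Secondary and supplementary records are dropped.
#'
#' @param path SAM or BAM file.
#' @return data.frame (`read_id, flag, chrom, pos, mapq, strand, cigar,
#'   seq`); `pos` is the 1-based SAM POS.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop_data("alignment file not found: %s", path)
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam")
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  out <- data.frame(read_id = x$qname, flag = x$flag,
                    chrom = as.character(x$rname), pos = x$pos,
                    mapq = x$mapq, cigar = x$cigar,
                    seq = as.character(x$seq), stringsAsFactors = FALSE)
  out$strand <- ifelse(bitwAnd(out$flag, 16L) > 0L, "-", "+")
  out[bitwAnd(out$flag, 0x900L) == 0L, , drop = FALSE]
}

# Walk one CIGAR against 0-based reference coordinates.
# Returns per-op: op, len, ref start (0-based), query start (0-based).
cigar_walk <- function(cigar, pos1) {
  co <- cigar_ops(cigar)
  ref_consume <- co$ops %in% c("M", "D", "N", "=", "X")
  qry_consume <- co$ops %in% c("M", "I", "S", "=", "X")
  rstart <- (pos1 - 1L) + c(0L, cumsum(co$lens * ref_consume))[seq_along(co$ops)]
  qstart <- c(0L, cumsum(co$lens * qry_consume))[seq_along(co$ops)]
  list(ops = co$ops, lens = co$lens, rstart = rstart, qstart = qstart,
       ref_end = (pos1 - 1L) + sum(co$lens[ref_consume]))
}

# Query offset (0-based, number of consumed query bases) at reference
# coordinate `refc`, counting insertions anchored before `refc`. When
# `after_ins` is TRUE, insertions anchored exactly at `refc` are consumed too.
query_offset_at <- function(walk, refc, after_ins = FALSE) {
  q <- 0L
  for (k in seq_along(walk$ops)) {
    op <- walk$ops[k]; len <- walk$lens[k]; r <- walk$rstart[k]
    if (op %in% c("M", "=", "X")) {
      if (refc < r + len) return(q + max(0L, refc - r))
      q <- q + len
    } else if (op == "I") {
      if (r > refc || (r == refc && !after_ins)) return(q)
      q <- q + len
    } else if (op %in% c("S", "H")) {
      if (op == "S") q <- q + len
    } else if (op %in% c("D", "N")) {
      if (refc < r + len) return(q)
    }
  }
  q
}

#' Measure a read's repeat copy-number change at one locus
#'
#' @param aln One alignment record: a one-row data.frame or list with fields
#'   `read_id, flag, chrom, pos, mapq, strand, cigar, seq`.
#' @param locus One catalog locus row (see [repeat_catalog()]).
#' @param anchor_bp Anchored flank required on both sides of the tract for a
#'   read to count as spanning (default 100 bp).
#' @param min_mapq Minimum mapping quality (default 1; the panel includes
#'   segmental-duplication loci where stringent MAPQ would drop real reads).
#' @return One-row data.frame (`read_id, locus_id, strand, net_bp_change,
#'   copy_change, spans_tract, map_qual, tract_sequence`), or `NULL` for
#'   skipped (unmapped/secondary/low-MAPQ) records.
#' @export
measure_read_copy_change <- function(aln, locus, anchor_bp = 100L, min_mapq = 1L) {
  if (bitwAnd(aln$flag, 4L) > 0L || bitwAnd(aln$flag, 0x900L) > 0L) {
    message("skipping unmapped/secondary record ", aln$read_id)
    return(NULL)
  }
  if (!identical(as.character(aln$chrom), as.character(locus$chrom)))
    stop_data("record %s is on %s, not on locus contig %s",
              aln$read_id, aln$chrom, locus$chrom)
  if (aln$mapq < min_mapq) {
    message("skipping low-MAPQ record ", aln$read_id)
    return(NULL)
  }
  start <- locus$start; end <- locus$end; mlen <- locus$motif_len
  w <- cigar_walk(aln$cigar, aln$pos)
  ref_start <- aln$pos - 1L

  spans <- ref_start <= start - anchor_bp && w$ref_end >= end + anchor_bp

  net <- 0L
  for (k in seq_along(w$ops)) {
    op <- w$ops[k]; len <- w$lens[k]; r <- w$rstart[k]
    if (op == "I") {
      if (r >= start - mlen && r <= end + mlen) net <- net + len
    } else if (op == "D") {
      ov <- min(r + len, end) - max(r, start)
      if (ov > 0L) net <- net - ov
    }
  }
  copy_change <- round_half_to_zero(net / mlen)

  tract_seq <- NA_character_
  if (spans && !is.na(aln$seq) && nzchar(aln$seq) && aln$seq != "*") {
    qa <- query_offset_at(w, start, after_ins = FALSE)
    qb <- query_offset_at(w, end, after_ins = TRUE)
    if (qb > qa) tract_seq <- substr(aln$seq, qa + 1L, qb)
  }
  data.frame(read_id = aln$read_id, locus_id = locus$locus_id,
             strand = aln$strand, net_bp_change = as.integer(net),
             copy_change = copy_change, spans_tract = spans,
             map_qual = aln$mapq, tract_sequence = tract_seq,
             stringsAsFactors = FALSE)
}

#' Measure all reads of an alignment table at one locus
#'
#' @param alignments Alignment table from [read_alignments()] or a simulated
#'   `sam` table.
#' @param locus One catalog locus row.
#' @inheritParams measure_read_copy_change
#' @return data.frame of per-read measurements (skipped records omitted).
#' @export
measure_reads <- function(alignments, locus, anchor_bp = 100L, min_mapq = 1L) {
  alignments <- alignments[alignments$chrom == locus$chrom |
                             bitwAnd(alignments$flag, 4L) > 0L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(alignments)), function(i)
    suppressMessages(measure_read_copy_change(alignments[i, ], locus,
                                              anchor_bp, min_mapq)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(read_id = character(0), locus_id = character(0),
                      strand = character(0), net_bp_change = integer(0),
                      copy_change = integer(0), spans_tract = logical(0),
                      map_qual = integer(0), tract_sequence = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Measure all catalog loci of an alignment table
#'
#' @param alignments Alignment table.
#' @param catalog A `repeat_catalog` whose loci live on the alignment contigs.
#' @inheritParams measure_read_copy_change
#' @return data.frame of per-read measurements across loci.
#' @export
measure_catalog <- function(alignments, catalog, anchor_bp = 100L, min_mapq = 1L) {
  out <- lapply(seq_len(nrow(catalog$loci)), function(i)
    measure_reads(alignments, catalog$loci[i, ], anchor_bp, min_mapq))
  do.call(rbind, out)
}

# Exhaustive one-dimensional two-cluster split minimizing within-cluster sum
# of squares over sorted values. Deterministic; exact for 1-D.
best_split <- function(x) {
  x <- sort(x)
  n <- length(x)
  wss <- function(v) if (length(v) <= 1L) 0 else sum((v - mean(v))^2)
  best <- list(k = 1L, wss = Inf)
  for (k in seq_len(n - 1L)) {
    w <- wss(x[seq_len(k)]) + wss(x[seq(k + 1L, n)])
    if (w < best$wss - 1e-12) best <- list(k = k, wss = w)
  }
  list(k = best$k, left = x[seq_len(best$k)], right = x[seq(best$k + 1L, n)])
}

median_int <- function(x) round_half_to_zero(stats::median(x))

#' Genotype one locus from spanning-read measurements
#'
#' Two-allele estimation by exhaustive one-dimensional two-cluster split of
#' the per-read copy changes (minimizing within-cluster sum of squares).
#' Cluster centers closer than `max(2, 0.1 x larger center)` collapse to a
#' homozygous call whose allele is the median of all reads. A heterozygous
#' call additionally requires at least `min_support` reads on each allele;
#' with fewer, the two alleles cannot be separated reliably and the genotype
#' is undetermined.
#'
#' @param measurements Per-read measurements for one locus, spanning reads
#'   only (non-spanning rows are dropped with a message).
#' @param locus The catalog locus row.
#' @param min_support Minimum spanning-read support (default 3).
#' @return A `locus_genotype` list: `locus_id`, `status`
#'   (`"ok"`/`"undetermined"`), `homozygous`, `allele_units` (ascending),
#'   `allele_copy_change`, `supporting_reads` (per-allele read_id lists),
#'   `n_spanning`, `reason`.
#' @export
genotype_locus <- function(measurements, locus, min_support = 3L) {
  if (nrow(measurements) && length(unique(measurements$locus_id)) > 1L)
    stop_data("measurements mix loci: %s",
              paste(unique(measurements$locus_id), collapse = ", "))
  m <- measurements[measurements$spans_tract, , drop = FALSE]
  gt <- function(status, hom = FALSE, units = c(NA_integer_, NA_integer_),
                 cc = c(NA_integer_, NA_integer_), sup = list(character(0), character(0)),
                 reason = NA_character_) {
    structure(list(locus_id = locus$locus_id, status = status, homozygous = hom,
                   allele_units = units, allele_copy_change = cc,
                   supporting_reads = sup, n_spanning = nrow(m), reason = reason),
              class = "locus_genotype")
  }
  if (nrow(m) < min_support) return(gt("undetermined", reason = "insufficient-reads"))
  cc <- m$copy_change
  sp <- best_split(cc)
  c1 <- mean(sp$left); c2 <- mean(sp$right)
  if (abs(c2 - c1) < max(2, 0.1 * max(abs(c1), abs(c2)))) {
    a <- median_int(cc)
    return(gt("ok", hom = TRUE,
              units = rep(locus$ref_units + a, 2L), cc = rep(a, 2L),
              sup = list(m$read_id, character(0))))
  }
  a1 <- median_int(sp$left); a2 <- median_int(sp$right)
  ord <- order(cc)
  ids_sorted <- m$read_id[ord]
  sup1 <- ids_sorted[seq_len(sp$k)]
  sup2 <- ids_sorted[seq(sp$k + 1L, length(cc))]
  if (min(length(sup1), length(sup2)) < min_support)
    return(gt("undetermined", reason = "allele-support"))
  gt("ok", hom = FALSE,
     units = locus$ref_units + c(a1, a2), cc = c(a1, a2),
     sup = list(sup1, sup2))
}

#' @export
print.locus_genotype <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("%s: undetermined (%s), %d spanning reads\n",
                x$locus_id, x$reason, x$n_spanning))
  } else {
    cat(sprintf("%s: %d/%d units (%s), %d spanning reads\n", x$locus_id,
                x$allele_units[1], x$allele_units[2],
                if (x$homozygous) "homozygous" else "heterozygous", x$n_spanning))
  }
  invisible(x)
}

#' Repeat units from a tract length
#'
#' Total expanded repeat length divided by the nucleotide count of the
#' repeat unit, floored — the unit-count convention for loci whose expanded
#' tracts carry frequent contaminating sequence.
#'
#' @param tract_length_bp Tract length in bp (>= 0).
#' @param motif_len Repeat-unit length in bp (>= 1).
#' @return Integer unit count.
#' @export
units_from_length <- function(tract_length_bp, motif_len) {
  if (any(motif_len < 1L)) stop_validation("motif_len must be >= 1")
  if (any(tract_length_bp < 0)) stop_validation("tract_length_bp must be >= 0")
  as.integer(tract_length_bp %/% motif_len)
}

#' Per-strand histogram of read copy-number changes
#'
#' The tabulation behind copy-number-change histograms, where forward- and
#' reverse-strand reads are plotted as separate colors.
#'
#' @param measurements Per-read measurement table.
#' @return data.frame (`copy_change, strand, count`), counts summing to the
#'   number of spanning measurements.
#' @export
histogram_table <- function(measurements) {
  m <- measurements[measurements$spans_tract, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(copy_change = integer(0), strand = character(0),
                      count = integer(0)))
  out <- as.data.frame(table(copy_change = m$copy_change, strand = m$strand),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "count"
  out$copy_change <- as.integer(out$copy_change)
  out <- out[out$count > 0L, ]
  out <- out[order(out$copy_change, out$strand), ]
  rownames(out) <- NULL
  out
}
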