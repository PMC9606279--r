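# Synthetic-data generator: mini genomes, long reads with ground-truth
# alignments (the CIGAR is emitted from the known edit script, so no external
# aligner is ever needed), control cohorts and per-read methylation tables.
#
# The generator emulates the statistical structure the pipeline assumes:
# two alleles sampled with equal probability, lognormal read lengths,
# per-base substitution/indel errors, an optional strand-specific whole-unit
# motif miscall artifact (e.g. AAGGG units read as AAGG on one strand), and
# per-allele CpG methylation levels.

#' Simulation specification
#'
#' @param catalog A `repeat_catalog`; usually a mini-genome catalog from
#'   [mini_catalog()] is derived from it downstream.
#' @param alleles Named list (by locus_id). Each element is a list of two
#'   allele compositions; a composition is a named integer vector of ordered
#'   motif unit counts, e.g. `c(TTTCA = 167, TTTTA = 500)`, or a single
#'   unnamed count meaning that many units of the locus' primary pathogenic
#'   motif. Loci absent from `alleles` are homozygous reference.
#' @param depth Target mean spanning coverage per locus (x).
#' @param read_len_mean,read_len_sigma Lognormal read-length parameters: mean
#'   in bp and sigma on the log scale. Lengths are truncated to
#'   `[read_len_min, read_len_max]` and to the haplotype length.
#' @param read_len_min,read_len_max Truncation bounds in bp.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param flank_bp Flank length of the mini-genome contigs (bp).
#' @param anchor_bp Anchored flank (bp) a read must cover on both sides of
#'   the tract to count as spanning.
#' @param motif_miscall Optional list `(source, corrupt, prob, strand)`:
#'   on reads of `strand`, each complete `source` unit in the tract is
#'   replaced by `corrupt` with probability `prob` (motifs given in the
#'   catalog/plus orientation).
#' @param meth_profile Optional per-allele CpG methylation probabilities,
#'   `c(a0, a1)` recycled across loci or a named list by locus_id.
#' @param sample_id Prefix for read names.
#' @param seed Integer seed; fixes the mini genome and all reads.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(catalog, alleles = list(), depth = 20,
                     read_len_mean = 20000, read_len_sigma = 0.5,
                     read_len_min = 2000, read_len_max = 100000,
                     sub_rate = 0.01, ins_rate = 0.005, del_rate = 0.005,
                     flank_bp = 5000, anchor_bp = 100,
                     motif_miscall = NULL, meth_profile = NULL,
                     sample_id = "S1", seed = 1) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 1)) stop_validation("error rates must lie in [0, 1]")
  if (depth <= 0) stop_validation("depth must be > 0")
  loci <- catalog$loci
  norm <- vector("list", nrow(loci))
  names(norm) <- loci$locus_id
  for (i in seq_len(nrow(loci))) {
    row <- loci[i, ]
    spec_i <- alleles[[row$locus_id]]
    if (is.null(spec_i)) spec_i <- list(row$ref_units, row$ref_units)
    if (is.numeric(spec_i) && length(spec_i) == 2L && is.null(names(spec_i)))
      spec_i <- list(spec_i[1], spec_i[2])
    if (length(spec_i) != 2L)
      stop_validation("locus %s: allele spec must describe two alleles", row$locus_id)
    norm[[i]] <- lapply(spec_i, function(a) {
      if (is.numeric(a) && is.null(names(a))) {
        if (length(a) != 1L || a < 0)
          stop_validation("locus %s: unit counts must be single values >= 0", row$locus_id)
        a <- stats::setNames(as.integer(a), primary_motif(row))
      }
      a <- stats::setNames(as.integer(a), names(a))
      if (any(a < 0) || !all(is_valid_motif(names(a))))
        stop_validation("locus %s: bad allele composition", row$locus_id)
      a
    })
  }
  structure(list(catalog = catalog, alleles = norm, depth = depth,
                 read_len_mean = read_len_mean, read_len_sigma = read_len_sigma,
                 read_len_min = read_len_min, read_len_max = read_len_max,
                 sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 flank_bp = flank_bp, anchor_bp = anchor_bp,
                 motif_miscall = motif_miscall, meth_profile = meth_profile,
                 sample_id = sample_id, seed = seed),
            class = "sim_spec")
}

#' Build a synthetic mini genome for a catalog
#'
#' One contig per locus, named by `locus_id`: a seeded-random flank, the
#' reference repeat tract (`ref_units` copies of the primary pathogenic
#' motif), and a second random flank.
#'
#' @param catalog A `repeat_catalog`.
#' @param flank_bp Flank length (bp), at least 1000.
#' @param seed Integer seed; the genome is byte-identical for a fixed seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
build_mini_genome <- function(catalog, flank_bp = 5000, seed = 1) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  if (flank_bp < 1000) stop_validation("flank_bp must be >= 1000")
  flank_bp <- as.integer(flank_bp)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    seqs <- vapply(seq_len(nrow(catalog$loci)), function(i) {
      row <- catalog$loci[i, ]
      left <- paste(sample(bases, flank_bp, replace = TRUE), collapse = "")
      right <- paste(sample(bases, flank_bp, replace = TRUE), collapse = "")
      paste0(left, strrep(primary_motif(row), row$ref_units), right)
    }, character(1))
    names(seqs) <- catalog$loci$locus_id
    Biostrings::DNAStringSet(seqs)
  })
}

#' Recoordinate a catalog onto its mini genome
#'
#' Returns a copy of `catalog` whose loci live on the mini-genome contigs:
#' `chrom` becomes the locus id and the tract spans
#' `[flank_bp, flank_bp + ref_units * motif_len)`.
#'
#' @inheritParams build_mini_genome
#' @return A `repeat_catalog`.
#' @export
mini_catalog <- function(catalog, flank_bp = 5000) {
  loci <- catalog$loci
  loci$chrom <- loci$locus_id
  loci$start <- as.integer(flank_bp)
  loci$end <- as.integer(flank_bp + loci$ref_units * loci$motif_len)
  repeat_catalog(loci, snps = NULL,
                 genome_size_bp = sum(2 * flank_bp + as.numeric(loci$ref_units * loci$motif_len)))
}

comp_sequence <- function(comp) {
  paste(vapply(seq_along(comp), function(k) strrep(names(comp)[k], comp[k]), character(1)),
        collapse = "")
}

# Haplotype-vs-reference edit script for one allele at one locus.
# refmap[i]: 1-based reference coordinate of haplotype position i (NA for the
# inserted expansion block, anchored at the tract 3' boundary);
# del_after[i]: reference bases deleted immediately after haplotype position i.
hap_model <- function(ref_contig_len, flank_bp, ref_len_bp, comp) {
  alen <- sum(nchar(names(comp)) * comp)
  d <- alen - ref_len_bp
  if (d >= 0) {
    refmap <- c(seq_len(flank_bp + ref_len_bp),
                rep(NA_integer_, d),
                seq(flank_bp + ref_len_bp + 1L, ref_contig_len))
    del_after <- integer(length(refmap))
  } else {
    refmap <- c(seq_len(flank_bp + alen),
                seq(flank_bp + ref_len_bp + 1L, ref_contig_len))
    del_after <- integer(length(refmap))
    del_after[flank_bp + alen] <- -d
  }
  list(refmap = refmap, del_after = del_after, alen = alen)
}

# Positions (1-based haplotype coords) of complete `motif` units in the tract.
unit_starts <- function(flank_bp, comp, motif) {
  pos <- flank_bp + 1L
  out <- integer(0)
  for (k in seq_along(comp)) {
    len <- nchar(names(comp)[k])
    if (names(comp)[k] == motif && comp[k] > 0L)
      out <- c(out, pos + (seq_len(comp[k]) - 1L) * len)
    pos <- pos + comp[k] * len
  }
  out
}

#' Simulate targeted long reads with ground-truth alignments
#'
#' Draws reads per locus until the requested spanning depth is realized
#' (alleles sampled with equal probability, read start uniform, strand
#' uniform), applies the motif-miscall artifact and per-base errors, and
#' emits the exact alignment of every read against the mini genome.
#'
#' @param spec A [sim_spec()].
#' @return A `repeat_sim` list: `reads` (read_id, locus_id, strand, sequence
#'   in molecule orientation, qual), `sam` (SAM fields, plus-strand
#'   projection), `truth` (read_id, locus_id, allele_index, true_copy_change,
#'   strand, spans_tract), `genome` (DNAStringSet), `catalog` (mini-genome
#'   coordinates), `warnings` (locus ids with zero spanning reads).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  genome <- build_mini_genome(spec$catalog, spec$flank_bp, seed = spec$seed)
  mcat <- mini_catalog(spec$catalog, spec$flank_bp)
  bases <- c("A", "C", "G", "T")
  meanlog <- log(spec$read_len_mean) - spec$read_len_sigma^2 / 2

  acc <- list(read_id = list(), locus_id = list(), strand = list(), seq = list(),
              flag = list(), pos = list(), cigar = list(), sam_seq = list(),
              allele = list(), change = list(), spans = list())
  warn_loci <- character(0)

  with_seed(spec$seed + 1L, {
    for (i in seq_len(nrow(mcat$loci))) {
      row <- mcat$loci[i, ]
      F <- as.integer(spec$flank_bp)
      ref_len <- row$end - row$start
      contig <- as.character(genome[[row$locus_id]])
      R <- nchar(contig)
      comps <- spec$alleles[[row$locus_id]]
      haps <- lapply(comps, function(comp) {
        hm <- hap_model(R, F, ref_len, comp)
        hm$chars <- strsplit(paste0(substr(contig, 1, F), comp_sequence(comp),
                                    substr(contig, F + ref_len + 1, R)), "")[[1]]
        hm$change <- round_half_to_zero((hm$alen - ref_len) / row$motif_len)
        if (!is.null(spec$motif_miscall))
          hm$miscall_starts <- unit_starts(F, comp, spec$motif_miscall$source)
        hm
      })
      target <- max(1L, as.integer(round(spec$depth)))
      spanning <- 0L
      attempts <- 0L
      max_attempts <- max(200L, 50L * target)
      k <- 0L
      while (spanning < target && attempts < max_attempts) {
        attempts <- attempts + 1L
        ai <- stats::rbinom(1L, 1L, 0.5)
        hm <- haps[[ai + 1L]]
        Hl <- length(hm$chars)
        L <- as.integer(round(stats::rlnorm(1, meanlog, spec$read_len_sigma)))
        L <- min(max(L, spec$read_len_min), spec$read_len_max, Hl)
        s <- sample.int(Hl - L + 1L, 1L)
        e <- s + L - 1L
        strand <- sample(c("+", "-"), 1L)
        spans <- (s <= F + 1L - spec$anchor_bp) && (e >= F + hm$alen + spec$anchor_bp)
        if (spans) spanning <- spanning + 1L
        k <- k + 1L

        rc <- hm$chars[s:e]
        rm_ <- hm$refmap[s:e]
        rd <- hm$del_after[s:e]
        rd[L] <- 0L
        forced_del <- logical(L)

        mc <- spec$motif_miscall
        if (!is.null(mc) && strand == mc$strand && length(hm$miscall_starts)) {
          slen <- nchar(mc$source)
          us <- hm$miscall_starts
          us <- us[us >= s & us + slen - 1L <= e]
          if (length(us)) {
            hit <- us[stats::runif(length(us)) < mc$prob]
            for (u in hit) {
              ls <- u - s + 1L
              cchars <- strsplit(mc$corrupt, "")[[1]]
              for (j in seq_along(cchars))
                rc[ls + j - 1L] <- cchars[j]
              if (nchar(mc$corrupt) < slen)
                forced_del[(ls + nchar(mc$corrupt)):(ls + slen - 1L)] <- TRUE
            }
          }
        }

        del <- forced_del | (stats::runif(L) < spec$del_rate)
        sub <- !del & (stats::runif(L) < spec$sub_rate)
        if (any(sub)) {
          idx <- which(sub)
          shift <- sample.int(3L, length(idx), replace = TRUE)
          rc[idx] <- bases[(match(rc[idx], bases) - 1L + shift) %% 4L + 1L]
        }
        ins_n <- stats::rbinom(L, 1L, spec$ins_rate)

        is_ins <- is.na(rm_)
        core_keep <- !(del & is_ins)
        ops1 <- ifelse(del, "D", ifelse(is_ins, "I", "M"))[core_keep]
        keys1 <- seq_len(L)[core_keep]
        chars1 <- ifelse(del, NA_character_, rc)[core_keep]
        refs1 <- ifelse(is_ins, NA_integer_, rm_)[core_keep]

        d_idx <- which(rd > 0L)
        keys2 <- rep(d_idx + 0.4, rd[d_idx])
        ops2 <- rep("D", length(keys2))

        i_idx <- which(ins_n > 0L)
        keys3 <- i_idx + 0.7
        ops3 <- rep("I", length(keys3))
        chars3 <- sample(bases, length(keys3), replace = TRUE)

        ord <- order(c(keys1, keys2, keys3))
        ops <- c(ops1, ops2, ops3)[ord]
        chars <- c(chars1, rep(NA_character_, length(keys2)), chars3)[ord]
        refs <- c(refs1, rep(NA_integer_, length(keys2)), rep(NA_integer_, length(keys3)))[ord]

        firstM <- match("M", ops)
        k_id <- sprintf("%s_%s_%05d", spec$sample_id, row$locus_id, k)

        if (is.na(firstM)) {
          seq_str <- paste(chars[!is.na(chars)], collapse = "")
          flag <- 4L; pos <- 0L; cigar <- "*"
        } else {
          # Outside the aligned core, deletions vanish and insertions become
          # soft clips; the alignment must start and end on an M column.
          lastM <- max(which(ops == "M"))
          outside <- c(seq_len(firstM - 1L),
                       if (lastM < length(ops)) seq(lastM + 1L, length(ops)))
          dropD <- outside[ops[outside] == "D"]
          if (length(dropD)) {
            ops <- ops[-dropD]; chars <- chars[-dropD]; refs <- refs[-dropD]
            firstM <- match("M", ops)
            lastM <- max(which(ops == "M"))
          }
          if (firstM > 1L) ops[seq_len(firstM - 1L)] <- "S"
          if (lastM < length(ops)) ops[seq(lastM + 1L, length(ops))] <- "S"
          r <- rle(ops)
          cigar <- paste0(r$lengths, r$values, collapse = "")
          seq_str <- paste(chars[!is.na(chars)], collapse = "")
          flag <- if (strand == "-") 16L else 0L
          pos <- refs[firstM]
        }
        acc$read_id[[length(acc$read_id) + 1L]] <- k_id
        acc$locus_id[[length(acc$locus_id) + 1L]] <- row$locus_id
        acc$strand[[length(acc$strand) + 1L]] <- strand
        acc$seq[[length(acc$seq) + 1L]] <- if (strand == "-") revcomp(seq_str) else seq_str
        acc$flag[[length(acc$flag) + 1L]] <- flag
        acc$pos[[length(acc$pos) + 1L]] <- pos
        acc$cigar[[length(acc$cigar) + 1L]] <- cigar
        acc$sam_seq[[length(acc$sam_seq) + 1L]] <- seq_str
        acc$allele[[length(acc$allele) + 1L]] <- ai
        acc$change[[length(acc$change) + 1L]] <- hm$change
        acc$spans[[length(acc$spans) + 1L]] <- spans
      }
      if (spanning == 0L) {
        warn_loci <- c(warn_loci, row$locus_id)
        warning(sprintf("locus %s: no spanning reads drawn", row$locus_id))
      }
    }
  })

  reads <- data.frame(read_id = unlist(acc$read_id), locus_id = unlist(acc$locus_id),
                      strand = unlist(acc$strand), seq = unlist(acc$seq),
                      stringsAsFactors = FALSE)
  reads$qual <- strrep("5", nchar(reads$seq))
  sam <- data.frame(read_id = reads$read_id, flag = unlist(acc$flag),
                    chrom = reads$locus_id, pos = unlist(acc$pos),
                    mapq = 60L, cigar = unlist(acc$cigar),
                    seq = unlist(acc$sam_seq),
                    strand = reads$strand, stringsAsFactors = FALSE)
  truth <- data.frame(read_id = reads$read_id, locus_id = reads$locus_id,
                      allele_index = unlist(acc$allele),
                      true_copy_change = unlist(acc$change),
                      strand = reads$strand, spans_tract = unlist(acc$spans),
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, sam = sam, truth = truth, genome = genome,
                 catalog = mcat, spec = spec, warnings = warn_loci),
            class = "repeat_sim")
}

#' @export
print.repeat_sim <- function(x, ...) {
  cat(sprintf("repeat_sim: %d reads over %d contig(s); %d spanning\n",
              nrow(x$reads), length(x$genome), sum(x$truth$spans_tract)))
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33, constant Q20)
#' @param sim A `repeat_sim`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(sim, path) {
  dna <- Biostrings::DNAStringSet(sim$reads$seq)
  names(dna) <- sim$reads$read_id
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(sim$reads$qual))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(dna, q), path)
  invisible(path)
}

#' Write simulated alignments as SAM
#' @param sim A `repeat_sim`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(sim, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$genome), Biostrings::width(sim$genome)))
  s <- sim$sam
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  s$read_id, s$flag,
                  ifelse(s$flag == 4L, "*", s$chrom),
                  ifelse(s$flag == 4L, 0L, s$pos),
                  ifelse(s$flag == 4L, 0L, s$mapq),
                  s$cigar, s$seq, strrep("5", nchar(s$seq)))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the ground-truth table as TSV
#' @param sim A `repeat_sim`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a control cohort of allele unit counts
#'
#' Per control and locus, two allele unit counts drawn uniformly from
#' `ref_units +/- jitter_units`, truncated at zero.
#'
#' @param catalog A `repeat_catalog`.
#' @param n Number of controls (default 27).
#' @param jitter_units Uniform jitter half-width in repeat units.
#' @param seed Integer seed.
#' @return data.frame (`locus_id, sample_id, allele_index, allele_units,
#'   copy_change`), 2n alleles per locus.
#' @export
simulate_controls <- function(catalog, n = 27L, jitter_units = 3L, seed = 1) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  if (n < 1L) stop_validation("n must be >= 1")
  loci <- catalog$loci
  with_seed(seed, {
    out <- expand.grid(sample_id = sprintf("C%02d", seq_len(n)),
                       allele_index = 0:1, locus_id = loci$locus_id,
                       stringsAsFactors = FALSE)
    out <- out[order(out$locus_id, out$sample_id, out$allele_index), ]
    ref <- loci$ref_units[match(out$locus_id, loci$locus_id)]
    jit <- if (jitter_units > 0L)
      sample(seq(-jitter_units, jitter_units), nrow(out), replace = TRUE) else 0L
    out$allele_units <- pmax(0L, ref + jit)
    out$copy_change <- out$allele_units - ref
    rownames(out) <- NULL
    out[, c("locus_id", "sample_id", "allele_index", "allele_units", "copy_change")]
  })
}

#' Simulate a per-read CpG methylation-probability table
#'
#' For each CpG on each read, a methylation probability is drawn with a
#' bounded beta-shaped spread of half-width 0.15 around the allele's profile
#' value, so an unmethylated allele (profile 0) never emits a probability
#' above 0.2.
#'
#' @param reads data.frame with `read_id`, `locus_id`, `seq` (molecule
#'   orientation), e.g. `sim$reads`.
#' @param truth Truth table with `read_id` and `allele_index`.
#' @param meth_profile Numeric `c(a0, a1)` per-allele methylation
#'   probability, or a named list by locus_id.
#' @param seed Integer seed.
#' @return data.frame (`read_id, contig, pos, prob`), one row per CpG.
#' @export
simulate_methylation <- function(reads, truth, meth_profile, seed = 1) {
  prof_for <- function(locus_id) {
    p <- if (is.list(meth_profile)) meth_profile[[locus_id]] else meth_profile
    if (is.null(p) || length(p) != 2L || any(p < 0 | p > 1))
      stop_validation("meth_profile must give two per-allele probabilities in [0, 1]")
    p
  }
  allele <- truth$allele_index[match(reads$read_id, truth$read_id)]
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(reads)), function(i) {
      cpg <- gregexpr("CG", reads$seq[i], fixed = TRUE)[[1]]
      if (cpg[1] == -1L) return(NULL)
      p <- prof_for(reads$locus_id[i])[allele[i] + 1L]
      prob <- p + (stats::rbeta(length(cpg), 2, 2) - 0.5) * 0.3
      data.frame(read_id = reads$read_id[i], contig = reads$locus_id[i],
                 pos = as.integer(cpg), prob = pmin(1, pmax(0, prob)),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
      return(data.frame(read_id = character(0), contig = character(0),
                        pos = integer(0), prob = numeric(0)))
    do.call(rbind, rows)
  })
}
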