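# Repeat-tract decomposition: consensus over spanning reads, minimal-cost
# segmentation of a tract into catalogued motif units, waterfall matrices
# and interruption calls.
#
# Segmentation is an exact dynamic program: an exact motif unit costs 0, a
# mismatched base inside a unit costs 1 (at most `max_mismatch_per_unit` per
# unit, and only for units of length >= 4 — a one-mismatch trinucleotide
# matches far too much), and an unlabeled (OTHER) base costs 1. Among
# equal-cost segmentations the program prefers earlier-listed motifs, then
# longer motifs, then fewer OTHER runs; pathogenic motifs are listed first
# in the catalog, so they win ties against benign near-duplicates.

#' Decompose a sequence into repeat motif units
#'
#' @param sequence DNA string.
#' @param motifs Ordered character vector of motif units; order breaks
#'   cost ties (earlier wins).
#' @param max_mismatch_per_unit Mismatch tolerance inside one unit (only for
#'   motifs of length >= 4). Default 1.
#' @return A `motif_decomposition`: `units` data.frame (`label, start, end,
#'   mismatches`; 0-based half-open offsets partitioning the sequence
#'   exactly, OTHER runs merged), `composition` (named unit counts per
#'   motif), `other_bp`, `cost`, and the input `sequence`.
#' @export
decompose_motifs <- function(sequence, motifs, max_mismatch_per_unit = 1L) {
  if (!length(motifs)) stop_validation("motifs must be non-empty")
  motifs <- unique(motifs)
  sc <- strsplit(sequence, "")[[1]]
  n <- length(sc)
  empty <- data.frame(label = character(0), start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(structure(list(units = empty,
                          composition = stats::setNames(integer(length(motifs)), motifs),
                          other_bp = 0L, cost = 0L, sequence = sequence),
                     class = "motif_decomposition"))
  mlens <- nchar(motifs)
  mm <- lapply(seq_along(motifs), function(k) {
    L <- mlens[k]
    if (L > n) return(integer(0))
    mc <- strsplit(motifs[k], "")[[1]]
    v <- integer(n - L + 1L)
    for (j in seq_len(L)) v <- v + (sc[j:(j + n - L)] != mc[j])
    v
  })
  tol <- ifelse(mlens >= 4L, as.integer(max_mismatch_per_unit), 0L)

  # dp over (position, state): state 1 = last piece was a unit (or start),
  # state 2 = inside/after an OTHER run. Objective: lexicographic
  # (cost, number of OTHER runs). First-seen optimum is kept, so candidates
  # arriving from smaller positions (longer motifs) and earlier-listed
  # motifs win ties.
  INF <- .Machine$integer.max %/% 2L
  cost <- matrix(INF, n + 1L, 2L)
  runs <- matrix(INF, n + 1L, 2L)
  bk_pos <- matrix(NA_integer_, n + 1L, 2L)
  bk_state <- matrix(NA_integer_, n + 1L, 2L)
  bk_kind <- matrix(NA_integer_, n + 1L, 2L)  # 0 = OTHER, k = motif index
  bk_mm <- matrix(NA_integer_, n + 1L, 2L)
  cost[1L, 1L] <- 0L; runs[1L, 1L] <- 0L

  try_update <- function(tp, ts, c2, r2, fp, fs, kind, d) {
    if (c2 < cost[tp, ts] || (c2 == cost[tp, ts] && r2 < runs[tp, ts])) {
      cost[tp, ts] <<- c2; runs[tp, ts] <<- r2
      bk_pos[tp, ts] <<- fp; bk_state[tp, ts] <<- fs
      bk_kind[tp, ts] <<- kind; bk_mm[tp, ts] <<- d
    }
  }
  for (j in 0:(n - 1L)) {
    for (st in 1:2) {
      c0 <- cost[j + 1L, st]
      if (c0 >= INF) next
      r0 <- runs[j + 1L, st]
      for (k in seq_along(motifs)) {
        L <- mlens[k]
        if (j + L > n) next
        d <- mm[[k]][j + 1L]
        if (d > tol[k]) next
        try_update(j + L + 1L, 1L, c0 + d, r0, j + 1L, st, k, d)
      }
      try_update(j + 2L, 2L, c0 + 1L, r0 + (st != 2L), j + 1L, st, 0L, NA_integer_)
    }
  }
  fin <- if (cost[n + 1L, 1L] < cost[n + 1L, 2L] ||
             (cost[n + 1L, 1L] == cost[n + 1L, 2L] &&
              runs[n + 1L, 1L] <= runs[n + 1L, 2L])) 1L else 2L
  segs <- list()
  p <- n + 1L; st <- fin
  while (p > 1L) {
    kind <- bk_kind[p, st]; fp <- bk_pos[p, st]; fs <- bk_state[p, st]
    d <- bk_mm[p, st]
    segs[[length(segs) + 1L]] <-
      list(label = if (kind == 0L) "OTHER" else motifs[kind],
           start = fp - 1L, end = p - 1L, mismatches = d)
    p <- fp; st <- fs
  }
  segs <- rev(segs)
  units <- data.frame(label = vapply(segs, `[[`, character(1), "label"),
                      start = vapply(segs, `[[`, integer(1), "start"),
                      end = vapply(segs, `[[`, integer(1), "end"),
                      mismatches = vapply(segs, `[[`, integer(1), "mismatches"),
                      stringsAsFactors = FALSE)
  if (nrow(units) > 1L) {  # merge adjacent OTHER bases into runs
    grp <- cumsum(c(TRUE, units$label[-1] != "OTHER" | units$label[-nrow(units)] != "OTHER"))
    units <- do.call(rbind, lapply(split(units, grp), function(g)
      data.frame(label = g$label[1], start = g$start[1], end = g$end[nrow(g)],
                 mismatches = if (g$label[1] == "OTHER") NA_integer_ else g$mismatches[1],
                 stringsAsFactors = FALSE)))
    rownames(units) <- NULL
  }
  comp <- stats::setNames(integer(length(motifs)), motifs)
  tab <- table(units$label[units$label != "OTHER"])
  comp[names(tab)] <- as.integer(tab)
  other_bp <- sum(units$end[units$label == "OTHER"] - units$start[units$label == "OTHER"])
  structure(list(units = units, composition = comp, other_bp = as.integer(other_bp),
                 cost = cost[n + 1L, fin], sequence = sequence),
            class = "motif_decomposition")
}

#' @export
print.motif_decomposition <- function(x, ...) {
  comp <- paste(sprintf("%s:%d", names(x$composition), x$composition), collapse = " ")
  cat(sprintf("motif_decomposition: %d bp, %s, OTHER %d bp (cost %d)\n",
              nchar(x$sequence), comp, x$other_bp, x$cost))
  invisible(x)
}

#' Build a consensus tract sequence from spanning reads
#'
#' The medoid read (minimal summed edit distance to the others) is polished
#' by globally aligning every read to it and taking the per-column majority
#' base; ties keep the medoid base, and a majority gap deletes the column.
#' Deterministic; a single read is returned unchanged.
#'
#' @param tract_sequences Character vector of per-read tract sequences from
#'   one allele's supporting reads.
#' @param ids Optional read ids (for `medoid_read_id`).
#' @param locus_id,allele_index Optional annotation carried through.
#' @return A `consensus_result`: `sequence`, `n_reads_used`,
#'   `medoid_read_id`, `locus_id`, `allele_index`.
#' @export
build_consensus <- function(tract_sequences, ids = NULL,
                            locus_id = NA_character_, allele_index = NA_integer_) {
  seqs <- tract_sequences[!is.na(tract_sequences) & nzchar(tract_sequences)]
  if (!length(seqs)) stop_validation("no sequences to build a consensus from")
  if (is.null(ids)) ids <- paste0("read", seq_along(tract_sequences))
  ids <- ids[!is.na(tract_sequences) & nzchar(tract_sequences)]
  res <- function(sq, n, mid)
    structure(list(locus_id = locus_id, allele_index = allele_index,
                   sequence = sq, n_reads_used = n, medoid_read_id = mid),
              class = "consensus_result")
  if (length(seqs) == 1L) return(res(seqs[1], 1L, ids[1]))

  D <- utils::adist(seqs)
  medoid_i <- which.min(rowSums(D))
  medoid <- seqs[medoid_i]
  mlen <- nchar(medoid)
  counts <- matrix(0L, 5L, mlen, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (i in seq_along(seqs)) {
    if (i == medoid_i) {
      mc <- strsplit(medoid, "")[[1]]
      idx <- match(mc, rownames(counts))
      counts[cbind(idx, seq_len(mlen))] <- counts[cbind(idx, seq_len(mlen))] + 1L
      next
    }
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seqs[i]),
                                        Biostrings::DNAString(medoid),
                                        type = "global")
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    keep <- as_ != "-"
    col_chars <- ap[keep]
    col_chars[!col_chars %in% rownames(counts)] <- "-"
    idx <- match(col_chars, rownames(counts))
    counts[cbind(idx, seq_len(mlen))] <- counts[cbind(idx, seq_len(mlen))] + 1L
  }
  mc <- strsplit(medoid, "")[[1]]
  cons <- vapply(seq_len(mlen), function(j) {
    col <- counts[, j]
    if (col[mc[j]] >= max(col)) return(mc[j])  # ties keep the medoid base
    rownames(counts)[which.max(col)]
  }, character(1))
  res(paste(cons[cons != "-"], collapse = ""), length(seqs), ids[medoid_i])
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d bp from %d read(s), medoid %s\n",
              nchar(x$sequence), x$n_reads_used, x$medoid_read_id))
  invisible(x)
}

#' Waterfall matrix of per-read motif decompositions
#'
#' Reverse-strand reads are reverse-complemented first, so the strand-specific
#' motif-miscall artifact shows up as corrupted unit labels on one strand's
#' rows. Rows are sorted by total unit count, descending.
#'
#' @param tract_sequences Per-read tract sequences.
#' @param motifs Ordered motif set (see [decompose_motifs()]).
#' @param strand Optional per-read strand (`"+"`/`"-"`); minus reads are
#'   reverse-complemented.
#' @param ids Optional read ids.
#' @param max_mismatch_per_unit Passed to [decompose_motifs()].
#' @return A `waterfall_matrix`: `matrix` (character, one row per read,
#'   right-padded with ""), `reads` data.frame (`read_id, strand, n_units,
#'   other_bp`) in row order, `labels` (list of label vectors).
#' @export
waterfall_matrix <- function(tract_sequences, motifs, strand = NULL, ids = NULL,
                             max_mismatch_per_unit = 1L) {
  keep <- !is.na(tract_sequences) & nzchar(tract_sequences)
  seqs <- tract_sequences[keep]
  if (is.null(ids)) ids <- paste0("read", seq_along(tract_sequences))
  ids <- ids[keep]
  if (is.null(strand)) strand <- rep("+", length(tract_sequences))
  strand <- strand[keep]
  if (!length(seqs)) {
    return(structure(list(matrix = matrix(character(0), 0, 0),
                          reads = data.frame(read_id = character(0),
                                             strand = character(0),
                                             n_units = integer(0),
                                             other_bp = integer(0)),
                          labels = list()),
                     class = "waterfall_matrix"))
  }
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  labels <- lapply(seqs, function(s) {
    d <- decompose_motifs(s, motifs, max_mismatch_per_unit)
    d$units$label
  })
  other_bp <- vapply(seqs, function(s)
    decompose_motifs(s, motifs, max_mismatch_per_unit)$other_bp, integer(1))
  n_units <- vapply(labels, function(l) sum(l != "OTHER"), integer(1))
  ord <- order(-n_units)
  labels <- labels[ord]
  width <- max(vapply(labels, length, integer(1)))
  mat <- t(vapply(labels, function(l) c(l, rep("", width - length(l))),
                  character(width)))
  rownames(mat) <- ids[ord]
  structure(list(matrix = mat,
                 reads = data.frame(read_id = ids[ord], strand = strand[ord],
                                    n_units = n_units[ord],
                                    other_bp = unname(other_bp[ord]),
                                    stringsAsFactors = FALSE),
                 labels = labels),
            class = "waterfall_matrix")
}

#' Write a waterfall matrix as TSV of label codes
#' @param w A `waterfall_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waterfall <- function(w, path) {
  utils::write.table(w$matrix, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE, na = "")
  invisible(path)
}

#' Call interruption and benign-motif runs in a decomposition
#'
#' Maximal runs of non-pathogenic catalogued units are reported with their
#' unit counts and position (5', internal, 3') relative to the largest
#' pathogenic-motif block.
#'
#' @param decomposition A `motif_decomposition` computed over the locus
#'   motif set (pathogenic, benign and interruption motifs).
#' @param locus The catalog locus row.
#' @return data.frame (`motif, n_units, position, start, end`); zero rows
#'   when the tract is pure pathogenic motif.
#' @export
detect_interruptions <- function(decomposition, locus) {
  units <- decomposition$units
  empty <- data.frame(motif = character(0), n_units = integer(0),
                      position = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!nrow(units)) return(empty)
  patho <- split_motifs(locus$pathogenic_motifs)
  is_patho <- units$label %in% patho
  grp <- cumsum(c(TRUE, diff(as.integer(is_patho)) != 0L |
                    units$label[-1] != units$label[-nrow(units)]))
  # largest pathogenic block (by bp) anchors 5'/internal/3' classification
  pb <- NULL
  for (g in split(seq_len(nrow(units)), cumsum(c(TRUE, diff(as.integer(is_patho)) != 0L)))) {
    if (!is_patho[g[1]]) next
    if (is.null(pb) || sum(units$end[g] - units$start[g]) >
        sum(units$end[pb] - units$start[pb])) pb <- g
  }
  calls <- list()
  for (g in split(seq_len(nrow(units)), grp)) {
    lab <- units$label[g[1]]
    if (lab == "OTHER" || lab %in% patho) next
    pos <- if (is.null(pb)) NA_character_
      else if (units$end[g[length(g)]] <= units$start[pb[1]]) "5prime"
      else if (units$start[g[1]] >= units$end[pb[length(pb)]]) "3prime"
      else "internal"
    calls[[length(calls) + 1L]] <-
      data.frame(motif = lab, n_units = length(g), position = pos,
                 start = units$start[g[1]], end = units$end[g[length(g)]],
                 stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
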