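# Disease-locus catalog: definition, validation, serialization, target BED.
#
# A catalog holds one row per repeat locus (coordinates of the reference
# repeat tract, motif sets, reference unit count, clinical unit-count
# thresholds, inheritance) plus optional disease-linked SNP targets used for
# adaptive-sampling capture. Coordinates are 0-based half-open throughout.

CATALOG_COLUMNS <- c("locus_id", "gene", "disease", "chrom", "start", "end",
                     "pathogenic_motifs", "benign_motifs", "interruption_motifs",
                     "ref_units", "normal_max_units", "pathogenic_min_units",
                     "inheritance", "motif_len")

SNP_COLUMNS <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele",
                 "linked_disease", "window_bp")

GRCH38_PRIMARY_BP <- 3088269832

#' Construct and validate a repeat-locus catalog
#'
#' @param loci data.frame with the catalog columns (see
#'   [load_catalog()] for the schema).
#' @param snps Optional data.frame of SNP capture targets.
#' @param genome_size_bp Genome size used for target-fraction arithmetic;
#'   defaults to the GRCh38 primary assembly.
#' @return An object of class `repeat_catalog`: a list with elements `loci`,
#'   `snps` and `genome_size_bp`. Loci are sorted by (chrom, start).
#' @export
repeat_catalog <- function(loci, snps = NULL, genome_size_bp = GRCH38_PRIMARY_BP) {
  if (is.null(loci) || !is.data.frame(loci) || nrow(loci) == 0L)
    stop_validation("no loci in catalog")
  missing_cols <- setdiff(CATALOG_COLUMNS, names(loci))
  if (length(missing_cols))
    stop_validation("catalog is missing columns: %s", paste(missing_cols, collapse = ", "))
  loci <- loci[, CATALOG_COLUMNS]
  for (col in c("start", "end", "ref_units", "normal_max_units",
                "pathogenic_min_units", "motif_len"))
    loci[[col]] <- suppressWarnings(as.integer(loci[[col]]))
  for (col in c("benign_motifs", "interruption_motifs")) {
    loci[[col]] <- as.character(loci[[col]])
    loci[[col]][is.na(loci[[col]])] <- ""
  }

  if (anyDuplicated(loci$locus_id))
    stop_validation("duplicate locus_id: %s",
                    paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  for (i in seq_len(nrow(loci))) {
    row <- loci[i, ]
    if (is.na(row$start) || is.na(row$end) || row$end <= row$start)
      stop_validation("locus %s: end must be greater than start", row$locus_id)
    if (is.na(row$ref_units) || row$ref_units < 0)
      stop_validation("locus %s: ref_units must be >= 0", row$locus_id)
    motifs <- c(split_motifs(row$pathogenic_motifs), split_motifs(row$benign_motifs),
                split_motifs(row$interruption_motifs))
    if (length(split_motifs(row$pathogenic_motifs)) == 0L)
      stop_validation("locus %s: at least one pathogenic motif required", row$locus_id)
    bad <- motifs[!is_valid_motif(motifs) | nchar(motifs) < 3L]
    if (length(bad))
      stop_validation("locus %s: invalid motif(s) %s (ACGT only, length >= 3)",
                      row$locus_id, paste(bad, collapse = ", "))
    if (!row$inheritance %in% c("AD", "AR", "XL", "unknown"))
      stop_validation("locus %s: inheritance must be AD, AR, XL or unknown", row$locus_id)
    if (!is.na(row$normal_max_units) && !is.na(row$pathogenic_min_units) &&
        row$pathogenic_min_units <= row$normal_max_units)
      stop_validation("locus %s: pathogenic_min_units (%d) must exceed normal_max_units (%d)",
                      row$locus_id, row$pathogenic_min_units, row$normal_max_units)
    primary <- split_motifs(row$pathogenic_motifs)[1]
    if (is.na(row$motif_len) || row$motif_len != nchar(primary))
      stop_validation("locus %s: motif_len must equal the primary pathogenic motif length",
                      row$locus_id)
    if (abs((row$end - row$start) - row$ref_units * row$motif_len) > row$motif_len)
      warning(sprintf("locus %s: tract width %d differs from ref_units x motif_len by more than one motif",
                      row$locus_id, row$end - row$start))
  }
  loci <- loci[order(loci$chrom, loci$start), ]
  rownames(loci) <- NULL

  if (!is.null(snps) && nrow(snps) > 0L) {
    missing_cols <- setdiff(SNP_COLUMNS, names(snps))
    if (length(missing_cols))
      stop_validation("snp table missing columns: %s", paste(missing_cols, collapse = ", "))
    snps <- snps[, SNP_COLUMNS]
    snps$pos <- as.integer(snps$pos)
    snps$window_bp <- as.integer(snps$window_bp)
    if (any(snps$window_bp <= 0L)) stop_validation("snp window_bp must be > 0")
    if (any(snps$ref_allele == snps$alt_allele))
      stop_validation("snp ref_allele must differ from alt_allele")
    rownames(snps) <- NULL
  } else {
    snps <- data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
                       ref_allele = character(0), alt_allele = character(0),
                       linked_disease = character(0), window_bp = integer(0),
                       stringsAsFactors = FALSE)
  }
  if (!is.numeric(genome_size_bp) || genome_size_bp <= 0)
    stop_validation("genome_size_bp must be positive")

  structure(list(loci = loci, snps = snps, genome_size_bp = genome_size_bp),
            class = "repeat_catalog")
}

#' @export
print.repeat_catalog <- function(x, ...) {
  cat(sprintf("repeat_catalog: %d loci, %d SNP target(s), genome %s bp\n",
              nrow(x$loci), nrow(x$snps), format(x$genome_size_bp, big.mark = ",")))
  cat(paste0("  ", x$loci$locus_id, " (", x$loci$gene, ", ",
             x$loci$pathogenic_motifs, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Load a repeat-locus catalog from TSV or JSON
#'
#' TSV catalogs carry one locus per row with columns `locus_id, gene, disease,
#' chrom, start, end, pathogenic_motifs, benign_motifs, interruption_motifs,
#' ref_units, normal_max_units, pathogenic_min_units, inheritance, motif_len`
#' (motif sets comma-joined; `start`/`end` 0-based half-open). JSON catalogs
#' are an object with fields `loci`, optionally `snps` and `genome_size_bp`.
#'
#' @param path Catalog file (.tsv/.txt or .json).
#' @param snp_path Optional TSV of SNP targets (columns `snp_id, chrom, pos,
#'   ref_allele, alt_allele, linked_disease, window_bp`; `pos` 1-based).
#' @return A validated [repeat_catalog()].
#' @export
load_catalog <- function(path, snp_path = NULL) {
  if (!file.exists(path)) stop_data("catalog file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    loci <- as.data.frame(obj$loci, stringsAsFactors = FALSE)
    snps <- if (!is.null(obj$snps)) as.data.frame(obj$snps, stringsAsFactors = FALSE) else NULL
    gsz <- if (!is.null(obj$genome_size_bp)) obj$genome_size_bp else GRCH38_PRIMARY_BP
  } else {
    loci <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop_data("cannot parse catalog %s: %s", path, conditionMessage(e)))
    bad <- which(is.na(loci$locus_id) | !nzchar(loci$locus_id))
    if (length(bad))
      stop_data("malformed catalog row at line %d of %s", bad[1] + 1L, path)
    snps <- NULL
    gsz <- GRCH38_PRIMARY_BP
  }
  if (!is.null(snp_path)) {
    if (!file.exists(snp_path)) stop_data("snp file not found: %s", snp_path)
    snps <- utils::read.delim(snp_path, stringsAsFactors = FALSE)
  }
  repeat_catalog(loci, snps, gsz)
}

#' Write a catalog to TSV or JSON
#'
#' JSON round-trips the full catalog (loci, SNPs, genome size); TSV writes the
#' loci table only (pass `snp_path` to also write the SNP table).
#'
#' @param catalog A `repeat_catalog`.
#' @param path Output file; format chosen by extension.
#' @param snp_path Optional TSV output for SNP targets.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, snp_path = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(list(loci = catalog$loci, snps = catalog$snps,
                              genome_size_bp = catalog$genome_size_bp),
                         path, auto_unbox = FALSE, digits = NA, na = "null")
  } else {
    utils::write.table(catalog$loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(snp_path))
      utils::write.table(catalog$snps, snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' The shipped default catalog
#'
#' Thirteen loci: the twelve classical repeat-expansion disease loci screened
#' in the validation panel (HTT, ATXN3, CACNA1A, DMPK, ATXN8OS, NOTCH2NLC,
#' PHOX2B, SAMD12, RFC1 with the ACAGG motif variant folded into its
#' pathogenic motif set, BEAN1, NOP56, CSTB) plus the polymorphic TNRC6A
#' repeat, and the SCA31-linked PLEKHG4 SNP capture target.
#'
#' @return A `repeat_catalog`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "repeat_catalog.tsv", package = "repscreen"),
               system.file("extdata", "snp_targets.tsv", package = "repscreen"))
}

#' Fetch one locus row from a catalog by id
#' @param catalog A `repeat_catalog`.
#' @param locus_id Locus identifier.
#' @return One-row data.frame.
#' @export
catalog_locus <- function(catalog, locus_id) {
  i <- match(locus_id, catalog$loci$locus_id)
  if (is.na(i)) stop_data("locus %s not in catalog", locus_id)
  catalog$loci[i, ]
}

primary_motif <- function(locus) split_motifs(locus$pathogenic_motifs)[1]

#' Full ordered motif set of a locus
#'
#' Pathogenic motifs first (so they win decomposition ties), then benign,
#' then interruption motifs.
#'
#' @param locus One catalog locus row.
#' @return Character vector of motifs.
#' @export
locus_motifs <- function(locus) {
  unique(c(split_motifs(locus$pathogenic_motifs), split_motifs(locus$benign_motifs),
           split_motifs(locus$interruption_motifs)))
}
locus_motif_set <- locus_motifs

#' Build the adaptive-sampling target BED for a catalog
#'
#' Each locus gets one capture window and each SNP target a window of its own
#' `window_bp`. In `"total"` mode (the default) the locus window has total
#' width `window_bp` centered on the repeat tract; in `"flank"` mode the
#' window extends `window_bp` on each side of the tract. Windows are clipped
#' at position 0 (and at contig ends when `contig_lengths` is given), sorted,
#' and overlapping windows merged.
#'
#' @param catalog A `repeat_catalog`.
#' @param window_bp Locus window size in bp (default 100 kb).
#' @param mode `"total"` or `"flank"` (see above).
#' @param contig_lengths Optional named integer vector of contig lengths used
#'   to clip windows.
#' @return data.frame of BED6 records (`chrom, start, end, name, score,
#'   strand`), 0-based half-open, sorted and non-overlapping.
#' @export
make_target_bed <- function(catalog, window_bp = 100000L, mode = c("total", "flank"),
                            contig_lengths = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  mode <- match.arg(mode)
  window_bp <- as.integer(window_bp)
  loci <- catalog$loci
  if (mode == "total") {
    too_long <- loci$end - loci$start > window_bp
    if (any(too_long))
      stop_validation("locus longer than window: %s",
                      paste(loci$locus_id[too_long], collapse = ", "))
    center <- (loci$start + loci$end) %/% 2L
    ws <- center - window_bp %/% 2L
    we <- ws + window_bp
  } else {
    ws <- loci$start - window_bp
    we <- loci$end + window_bp
  }
  chroms <- loci$chrom
  names_ <- loci$locus_id
  if (nrow(catalog$snps) > 0L) {
    s <- catalog$snps
    pos0 <- s$pos - 1L
    ws <- c(ws, pos0 - s$window_bp %/% 2L)
    we <- c(we, pos0 - s$window_bp %/% 2L + s$window_bp)
    chroms <- c(chroms, s$chrom)
    names_ <- c(names_, s$snp_id)
  }
  ws <- pmax(ws, 0L)
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[chroms]
    we <- pmin(we, ifelse(is.na(lim), we, lim))
  }
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(start = ws + 1L, end = we))
  names(gr) <- names_
  merged <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  nm <- vapply(merged$revmap, function(ix) paste(names_[ix], collapse = ","), character(1))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged),
                    name = nm, score = 0L, strand = ".",
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Fraction of the genome covered by a target BED
#'
#' @param bed data.frame of merged BED records (`chrom, start, end`).
#' @param genome_size_bp Genome size in bp.
#' @return Dimensionless fraction: total window length / genome size.
#' @export
target_fraction <- function(bed, genome_size_bp) {
  if (!is.numeric(genome_size_bp) || length(genome_size_bp) != 1L || genome_size_bp <= 0)
    stop_validation("genome_size_bp must be positive")
  if (is.null(bed) || nrow(bed) == 0L) return(0)
  sum(as.numeric(bed$end - bed$start)) / genome_size_bp
}

#' Write BED records to a file
#'
#' @param bed data.frame of BED records as produced by [make_target_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
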