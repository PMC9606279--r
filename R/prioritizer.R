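# Locus prioritization against a control cohort.
#
# Each catalog locus is scored by how far the patient's large-allele repeat
# change exceeds anything seen in the controls, on the base-pair scale so a
# pentanucleotide expansion of hundreds of units outranks a trinucleotide
# expansion of a few units. The ranked list is what the diagnostic triage
# walks from rank 1 downward.

#' Build a control copy-change table
#'
#' @param controls data.frame with `locus_id, sample_id, allele_index` and
#'   either `copy_change` or `allele_units` (converted using the catalog's
#'   `ref_units`), e.g. the output of [simulate_controls()].
#' @param catalog A `repeat_catalog`; every catalog locus must be present.
#' @return data.frame (`locus_id, sample_id, allele_index, copy_change`).
#' @export
build_control_table <- function(controls, catalog) {
  if (is.null(controls) || nrow(controls) == 0L) stop_validation("empty control table")
  if (!"copy_change" %in% names(controls)) {
    if (!"allele_units" %in% names(controls))
      stop_validation("controls need copy_change or allele_units")
    ref <- catalog$loci$ref_units[match(controls$locus_id, catalog$loci$locus_id)]
    controls$copy_change <- controls$allele_units - ref
  }
  missing <- setdiff(catalog$loci$locus_id, unique(controls$locus_id))
  if (length(missing))
    stop_data("loci missing from controls: %s", paste(missing, collapse = ", "))
  n_alleles <- table(controls$locus_id)
  if (any(n_alleles < 4L))
    message("fewer than 2 controls at: ",
            paste(names(n_alleles)[n_alleles < 4L], collapse = ", "))
  controls[, c("locus_id", "sample_id", "allele_index", "copy_change")]
}

#' Rank catalog loci for one patient against controls
#'
#' The patient statistic at a locus is the m-th largest spanning-read copy
#' change with `m = max(2, ceiling(0.1 n))`, which is robust to single
#' chimeric or error reads. The score is
#' `(patient_stat - max control copy change) x motif_len` (bp scale). Loci
#' are sorted by score descending, ties broken by (chrom, start); loci with
#' fewer than `min_support` spanning reads are ranked last with a `-Inf`
#' score and flagged.
#'
#' @param measurements Per-read measurement table across loci (spanning reads
#'   are selected internally).
#' @param controls Control table from [build_control_table()].
#' @param catalog A `repeat_catalog`.
#' @param min_support Minimum spanning reads for a scored locus.
#' @return data.frame (`rank, locus_id, gene, patient_stat, control_max,
#'   score, n_spanning, low_support`), ranks a permutation of 1..n loci.
#' @export
rank_loci <- function(measurements, controls, catalog, min_support = 3L) {
  loci <- catalog$loci
  missing <- setdiff(loci$locus_id, unique(controls$locus_id))
  if (length(missing))
    stop_data("loci missing from controls: %s", paste(missing, collapse = ", "))
  m <- measurements[measurements$spans_tract, , drop = FALSE]
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    row <- loci[i, ]
    cc <- m$copy_change[m$locus_id == row$locus_id]
    n <- length(cc)
    cmax <- max(controls$copy_change[controls$locus_id == row$locus_id])
    if (n < min_support) {
      data.frame(locus_id = row$locus_id, gene = row$gene,
                 patient_stat = NA_integer_, control_max = as.integer(cmax),
                 score = -Inf, n_spanning = n, low_support = TRUE,
                 chrom = row$chrom, start = row$start, stringsAsFactors = FALSE)
    } else {
      mth <- max(2L, as.integer(ceiling(0.1 * n)))
      stat <- sort(cc, decreasing = TRUE)[mth]
      data.frame(locus_id = row$locus_id, gene = row$gene,
                 patient_stat = as.integer(stat), control_max = as.integer(cmax),
                 score = (stat - cmax) * row$motif_len, n_spanning = n,
                 low_support = FALSE, chrom = row$chrom, start = row$start,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$chrom, out$start), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "locus_id", "gene", "patient_stat", "control_max",
          "score", "n_spanning", "low_support")]
}
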