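# Rule-based pathogenicity triage of genotyped loci, plus cohort summaries
# and informational SNP genotyping.
#
# The triage walks a fixed rule list:
#   R1  larger-allele pathogenic-motif unit count >= pathogenic_min?
#   R2  long tract whose expansion is composed of benign motifs only
#       (pathogenic units below threshold despite a long tract) -> benign
#   R3  inheritance: AR with both alleles expanded -> pathogenic, AR with
#       one -> carrier; AD/XL with at least one -> pathogenic
#   R4  below threshold but above the normal maximum -> intermediate
# Missing thresholds never guess: the verdict is undetermined.

#' Triage one genotyped locus
#'
#' @param genotype A `locus_genotype` from [genotype_locus()].
#' @param locus The catalog locus row.
#' @param compositions Optional list of one or two `motif_decomposition`
#'   objects (per allele, ascending). When present, the pathogenic-motif
#'   unit count is taken from the decomposition; otherwise the total allele
#'   unit count is used and flagged `composition-unverified`.
#' @return A `triage_call`: `locus_id`, `verdict` (`pathogenic`,
#'   `benign_polymorphic`, `carrier`, `intermediate`, `undetermined`),
#'   `rationale` (ordered rule ids), `allele_units`,
#'   `pathogenic_motif_units`.
#' @export
evaluate_locus <- function(genotype, locus, compositions = NULL) {
  call <- function(verdict, rationale, path_units = NA_integer_)
    structure(list(locus_id = locus$locus_id, verdict = verdict,
                   rationale = rationale,
                   allele_units = genotype$allele_units,
                   pathogenic_motif_units = path_units),
              class = "triage_call")
  if (genotype$status != "ok")
    return(call("undetermined", c("genotype-undetermined")))
  if (is.na(locus$pathogenic_min_units) || is.na(locus$normal_max_units))
    return(call("undetermined", c("no-threshold")))

  patho <- split_motifs(locus$pathogenic_motifs)
  rationale <- character(0)
  path_units <- genotype$allele_units
  if (!is.null(compositions)) {
    if (inherits(compositions, "motif_decomposition"))
      compositions <- list(compositions)
    pu <- vapply(compositions, function(d) sum(d$composition[patho]), numeric(1))
    if (length(pu) == 1L)  # decomposition of the expanded (larger) allele only
      path_units <- c(genotype$allele_units[1], as.integer(pu))
    else path_units <- as.integer(pu)
    rationale <- c(rationale, "motif:composition-confirmed")
  } else {
    rationale <- c(rationale, "motif:composition-unverified")
  }
  larger <- max(path_units)
  if (larger >= locus$pathogenic_min_units) {
    rationale <- c(rationale, "R1:threshold-met")
    n_expanded <- sum(path_units >= locus$pathogenic_min_units)
    if (locus$inheritance == "AR") {
      if (n_expanded >= 2L)
        return(call("pathogenic", c(rationale, "R3:AR-biallelic"), larger))
      return(call("carrier", c(rationale, "R3:AR-monoallelic"), larger))
    }
    return(call("pathogenic",
                c(rationale, sprintf("R3:%s-dominant", locus$inheritance)), larger))
  }
  rationale <- c(rationale, "R1:threshold-not-met")
  total_larger <- max(genotype$allele_units)
  if (total_larger >= locus$pathogenic_min_units)
    return(call("benign_polymorphic", c(rationale, "R2:benign-motifs-only"), larger))
  if (larger > locus$normal_max_units)
    return(call("intermediate", c(rationale, "R4:above-normal-max"), larger))
  call("benign_polymorphic", c(rationale, "R4:within-normal-range"), larger)
}

#' @export
print.triage_call <- function(x, ...) {
  cat(sprintf("%s: %s [%s]\n", x$locus_id, x$verdict,
              paste(x$rationale, collapse = "; ")))
  invisible(x)
}

#' Adjust fragment-analysis unit counts for a co-amplified secondary repeat
#'
#' Fragment analysis of a locus whose PCR amplicon also spans a secondary
#' repeat (e.g. the CCG tract adjacent to a CAG repeat) over-counts by the
#' excess of observed secondary units over the reference. The excess is
#' subtracted from each allele's total, floored at zero.
#'
#' @param total_units_per_allele Integer pair of fragment-analysis totals.
#' @param observed_secondary_units Observed secondary-repeat unit count.
#' @param reference_secondary_units Reference secondary-repeat unit count.
#' @return Adjusted integer pair.
#' @export
adjust_fragment_units <- function(total_units_per_allele, observed_secondary_units,
                                  reference_secondary_units) {
  if (any(c(total_units_per_allele, observed_secondary_units,
            reference_secondary_units) < 0))
    stop_validation("unit counts must be non-negative")
  as.integer(pmax(0L, total_units_per_allele -
                    (observed_secondary_units - reference_secondary_units)))
}

#' Summarize a validation-style cohort of ranked diagnoses
#'
#' @param reports data.frame with one row per patient carrying `patient_id`
#'   and `rank` (the prioritizer rank of the known causal locus).
#' @return list: `pct_rank1`, `pct_top2` (percent of patients with the
#'   causal locus at rank 1 / within ranks 1-2), `n`, and the per-patient
#'   `table`.
#' @export
summarize_cohort <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0L) stop_validation("empty cohort")
  if (any(is.na(reports$rank))) stop_validation("every report needs a causal-locus rank")
  list(pct_rank1 = 100 * mean(reports$rank == 1L),
       pct_top2 = 100 * mean(reports$rank <= 2L),
       n = nrow(reports), table = reports)
}

# Base of a read at 0-based reference coordinate refc, or NA if not aligned.
read_base_at <- function(aln, refc) {
  if (bitwAnd(aln$flag, 4L) > 0L || is.na(aln$seq) || aln$seq == "*") return(NA_character_)
  w <- cigar_walk(aln$cigar, aln$pos)
  for (k in seq_along(w$ops)) {
    op <- w$ops[k]; len <- w$lens[k]; r <- w$rstart[k]
    if (op %in% c("M", "=", "X") && refc >= r && refc < r + len)
      return(substr(aln$seq, w$qstart[k] + (refc - r) + 1L,
                    w$qstart[k] + (refc - r) + 1L))
  }
  NA_character_
}

#' Genotype a disease-linked SNP from a read pileup
#'
#' Informational only: the SNP call is reported alongside the triage but
#' never changes a verdict (a disease-linked SNP cannot exclude a diagnosis).
#'
#' @param alignments Alignment table over the SNP's contig.
#' @param snp One SNP-target row (`chrom, pos` 1-based, `ref_allele,
#'   alt_allele`).
#' @param min_support Minimum informative reads (default 3).
#' @param min_frac Minor-allele fraction for a heterozygous call (default 0.2).
#' @return list: `call` (`hom-ref`/`het`/`hom-alt`/`no-call`), `n_ref`,
#'   `n_alt`, `depth`.
#' @export
genotype_snp <- function(alignments, snp, min_support = 3L, min_frac = 0.2) {
  refc <- snp$pos - 1L
  al <- alignments[alignments$chrom == snp$chrom, , drop = FALSE]
  bases <- vapply(seq_len(nrow(al)), function(i) {
    b <- read_base_at(al[i, ], refc)
    if (is.null(b)) NA_character_ else b
  }, character(1))
  n_ref <- sum(bases == snp$ref_allele, na.rm = TRUE)
  n_alt <- sum(bases == snp$alt_allele, na.rm = TRUE)
  depth <- sum(!is.na(bases))
  n <- n_ref + n_alt
  if (n < min_support)
    return(list(call = "no-call", n_ref = n_ref, n_alt = n_alt, depth = depth))
  callv <- if (min(n_ref, n_alt) / n >= min_frac) "het"
    else if (n_alt > n_ref) "hom-alt" else "hom-ref"
  list(call = callv, n_ref = n_ref, n_alt = n_alt, depth = depth)
}
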