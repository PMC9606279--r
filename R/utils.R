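# Shared helpers: error classes, seeded evaluation, small sequence utilities.

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("repscreen_validation_error", "error", "condition")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("repscreen_data_error", "error", "condition")))
}

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single integer seed makes a whole run reproducible.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("seed must be a single number, got %s", format(seed)[1])
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Round to nearest integer with ties broken toward zero, so 1-2 bp of
# alignment jitter around a repeat boundary keeps unexpanded reads at 0.
round_half_to_zero <- function(x) {
  as.integer(sign(x) * ceiling(abs(x) - 0.5))
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_valid_motif <- function(m) {
  nzchar(m) & !grepl("[^ACGT]", m)
}

split_motifs <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

join_motifs <- function(x) paste(x, collapse = ",")

# Parse one CIGAR string into (ops, lengths).
cigar_ops <- function(cigar) {
  list(ops = GenomicAlignments::explodeCigarOps(cigar)[[1]],
       lens = GenomicAlignments::explodeCigarOpLengths(cigar)[[1]])
}
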