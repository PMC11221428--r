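# Internal helpers shared across modules.
#
# Coordinate convention: 0-based, half-open [start, end) everywhere in memory.
# GFF3 is converted to/from 1-based inclusive at the file boundary, VCF POS is
# 1-based on disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genotype state tokens
#'
#' The on-disk and in-memory genotype alphabet for pan-TE loci. `NA` (the
#' literal string on disk, `NA_character_` in memory) marks an uncertain
#' genotype, i.e. the accession's alignment does not cover the locus.
#' @format Character vector of the three defined states.
#' @export
GT_STATES <- c("0/0", "0/1", "1/1")

#' Convert genotype states to derived-allele dosages
#'
#' Maps `0/0`, `0/1`, `1/1` to dosages 0, 1, 2; anything else (including the
#' uncertain state) becomes `NA`.
#'
#' @param states Character vector or matrix of genotype states.
#' @return Numeric vector or matrix of dosages in `{0, 1, 2, NA}`.
#' @export
state_to_dosage <- function(states) {
  map <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)
  out <- map[as.character(states)]
  if (is.matrix(states)) {
    out <- matrix(out, nrow = nrow(states), dimnames = dimnames(states))
  } else {
    names(out) <- names(states)
  }
  out
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Width of the union of 0-based half-open intervals.
interval_union_width <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  keep <- ends > starts
  if (!any(keep)) return(0L)
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]))))
}

# Population (divide-by-n) standard deviation; the cross-accession variability
# summaries use this convention.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Overlap length of [s1,e1) with [s2,e2).
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Evenly spaced random positions: n positions in [edge, L - edge) with all
# pairwise gaps >= gap. Deterministic under the current RNG state.
spaced_positions <- function(L, n, gap = 100L, edge = 100L) {
  if (n == 0L) return(integer(0))
  span <- L - 2L * edge - (n - 1L) * gap
  if (span < n) {
    stop("cannot place ", n, " non-overlapping positions with gap ", gap,
         " on a sequence of length ", L)
  }
  sort(sample.int(span, n)) + edge + (seq_len(n) - 1L) * gap
}

# Derive a reproducible child seed from a parent seed and a stage label,
# keeping the result below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 100000L) * 17731L + h %% 17713L
}
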