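# Presence/absence variant (PAV) extraction from whole-genome alignments and
# TE-content classification.
#
# One PAV is emitted per I/D CIGAR op longer than the size threshold on the
# primary alignment set: an I op is a `ref_insertion` (sequence present in
# the query, absent at a point of the reference), a D op a `ref_deletion`
# (reference interval absent from the query). The ">50 bp" size rule and the
# ">90% TE sequence" classification rule are read as strict inequalities.

#' Extract PAVs from PAF alignments
#'
#' Walks each usable record's CIGAR to compute reference coordinates, emits
#' one PAV per I/D op with `length > min_len` (strict; `length >= min_len`
#' when `strict = FALSE`), extracts the inserted (query) or deleted
#' (reference) sequence, and returns the union of reference intervals covered
#' by alignment, which the genotyper later needs to distinguish `0/0` from
#' `NA`. Minus-strand records are handled by walking the query in reverse
#' complement. When two primary records overlap on the reference, the longer
#' aligned block wins and the shorter is dropped with a message.
#'
#' @param paf Data.frame from [read_paf()].
#' @param query_seqs Named character vector or `DNAStringSet` of query
#'   sequences (needed for inserted sequence extraction).
#' @param ref_seqs Named character vector or `DNAStringSet` of reference
#'   sequences (needed for deleted sequence extraction).
#' @param accession Accession id stamped on each PAV.
#' @param min_len Size threshold in bp (default 50).
#' @param strict If `TRUE` (default) retain `length > min_len`, else
#'   `length >= min_len`.
#' @return List with `pavs` (data.frame: `accession, ref_chrom, ref_start,
#'   ref_end, pav_type, length, sequence, query_chrom, query_start,
#'   query_end`) and `coverage` (data.frame `chrom, start, end` of merged
#'   aligned reference intervals).
#' @export
extract_pavs <- function(paf, query_seqs, ref_seqs, accession = "query",
                         min_len = 50L, strict = TRUE) {
  query_seqs <- as_seq_vector(query_seqs)
  ref_seqs <- as_seq_vector(ref_seqs)
  paf <- paf[paf$usable %||% rep(TRUE, nrow(paf)), , drop = FALSE]
  paf <- resolve_overlapping_records(paf)
  keep_len <- function(len) if (strict) len > min_len else len >= min_len
  pavs <- list()
  cov <- list()
  for (i in seq_len(nrow(paf))) {
    cig <- paf$cigar[[i]]
    tch <- paf$tname[i]; qch <- paf$qname[i]
    minus <- paf$strand[i] == "-"
    tpos <- paf$tstart[i]
    qpos <- if (minus) paf$qend[i] else paf$qstart[i]
    cov[[length(cov) + 1L]] <- data.frame(chrom = tch, start = paf$tstart[i],
                                          end = paf$tend[i],
                                          stringsAsFactors = FALSE)
    for (k in seq_len(nrow(cig))) {
      op <- cig$op[k]; len <- cig$len[k]
      if (op %in% c("=", "X", "M")) {
        tpos <- tpos + len
        qpos <- if (minus) qpos - len else qpos + len
      } else if (op == "I") {
        if (keep_len(len)) {
          if (minus) {
            qs <- qpos - len; qe <- qpos
            seqv <- revcomp(substr(query_seqs[[qch]], qs + 1L, qe))
          } else {
            qs <- qpos; qe <- qpos + len
            seqv <- substr(query_seqs[[qch]], qs + 1L, qe)
          }
          pavs[[length(pavs) + 1L]] <- data.frame(
            accession = accession, ref_chrom = tch, ref_start = tpos,
            ref_end = tpos, pav_type = "ref_insertion", length = len,
            sequence = seqv, query_chrom = qch, query_start = qs,
            query_end = qe, stringsAsFactors = FALSE)
        }
        qpos <- if (minus) qpos - len else qpos + len
      } else if (op == "D") {
        if (keep_len(len)) {
          pavs[[length(pavs) + 1L]] <- data.frame(
            accession = accession, ref_chrom = tch, ref_start = tpos,
            ref_end = tpos + len, pav_type = "ref_deletion", length = len,
            sequence = substr(ref_seqs[[tch]], tpos + 1L, tpos + len),
            query_chrom = qch, query_start = NA_integer_,
            query_end = NA_integer_, stringsAsFactors = FALSE)
        }
        tpos <- tpos + len
      }
    }
  }
  pavs <- if (length(pavs)) do.call(rbind, pavs) else empty_pav_frame()
  cov <- if (length(cov)) do.call(rbind, cov) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  cov <- merge_coverage(cov)
  list(pavs = pavs, coverage = cov)
}

empty_pav_frame <- function() {
  data.frame(accession = character(0), ref_chrom = character(0),
             ref_start = integer(0), ref_end = integer(0),
             pav_type = character(0), length = integer(0),
             sequence = character(0), query_chrom = character(0),
             query_start = integer(0), query_end = integer(0),
             stringsAsFactors = FALSE)
}

as_seq_vector <- function(x) {
  if (methods::is(x, "DNAStringSet") || methods::is(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else as.list(x)
}

merge_coverage <- function(cov) {
  if (nrow(cov) == 0L) return(cov)
  out <- lapply(split(cov, cov$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

resolve_overlapping_records <- function(paf) {
  if (nrow(paf) < 2L) return(paf)
  drop <- rep(FALSE, nrow(paf))
  ord <- order(-(paf$alen))
  kept <- list()
  for (i in ord) {
    ir <- IRanges::IRanges(paf$tstart[i] + 1L, paf$tend[i])
    clash <- FALSE
    for (j in seq_along(kept)) {
      if (kept[[j]]$tname == paf$tname[i] &&
          IRanges::countOverlaps(ir, kept[[j]]$ir) > 0L) {
        clash <- TRUE
        break
      }
    }
    if (clash) {
      drop[i] <- TRUE
    } else {
      kept[[length(kept) + 1L]] <- list(tname = paf$tname[i], ir = ir)
    }
  }
  if (any(drop)) {
    message(sum(drop), " overlapping primary record(s) dropped; ",
            "longer aligned blocks kept")
  }
  paf[!drop, , drop = FALSE]
}

#' TE-covered fraction of one PAV
#'
#' Computes the proportion of a PAV's bases covered by annotated TE
#' intervals, union semantics (double-covered bases count once), together
#' with the list of overlapping TE units ordered by position. For a
#' `ref_deletion` the deleted reference interval is intersected with
#' reference annotations; for a `ref_insertion` the inserted segment is
#' located via its query coordinates and intersected with the carrying
#' accession's own annotations.
#'
#' @param pav One-row PAV data.frame (see [extract_pavs()]).
#' @param annotations TE annotations for the genome carrying the sequence
#'   ([read_te_gff3()] format). `NULL` yields `te_fraction = NA`.
#' @return List with `te_fraction`, and `te_units` (data.frame `superfamily,
#'   family, covered`), ordered by position.
#' @export
te_fraction <- function(pav, annotations) {
  if (is.null(annotations)) {
    return(list(te_fraction = NA_real_,
                te_units = data.frame(superfamily = character(0),
                                      family = character(0),
                                      covered = integer(0))))
  }
  if (pav$pav_type == "ref_deletion") {
    chrom <- pav$ref_chrom; s <- pav$ref_start; e <- pav$ref_end
  } else {
    chrom <- pav$query_chrom; s <- pav$query_start; e <- pav$query_end
  }
  ann <- annotations[annotations$chrom == chrom &
                       annotations$end > s & annotations$start < e, ,
                     drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  covered <- overlap_len(ann$start, ann$end, s, e)
  frac <- interval_union_width(pmax(ann$start, s), pmin(ann$end, e)) /
    (e - s)
  list(te_fraction = frac,
       te_units = data.frame(superfamily = ann$superfamily,
                             family = ann$family,
                             covered = as.integer(covered),
                             stringsAsFactors = FALSE))
}

#' Annotate PAVs with TE content and classify TE variations
#'
#' Vectorized driver over [te_fraction()]: adds `te_fraction`, the unit count
#' `n_units`, the locus-level `family`/`superfamily` label (the unit covering
#' the most bases, ties broken by earliest position) and the
#' `is_te_variation` flag (`te_fraction > min_te_frac`, strict). PAVs whose
#' carrying genome has no annotations get `te_fraction = NA` and an `NA`
#' flag.
#'
#' @param pavs PAV data.frame from [extract_pavs()].
#' @param query_te TE annotations of the query accession (for insertions).
#' @param ref_te TE annotations of the reference (for deletions).
#' @param min_te_frac Classification threshold (default 0.9, strict).
#' @return `pavs` with the added columns plus a `te_units` list-column.
#' @export
classify_te_variations <- function(pavs, query_te, ref_te,
                                   min_te_frac = 0.9) {
  n <- nrow(pavs)
  pavs$te_fraction <- rep(NA_real_, n)
  pavs$n_units <- rep(NA_integer_, n)
  pavs$family <- rep(NA_character_, n)
  pavs$superfamily <- rep(NA_character_, n)
  pavs$te_units <- vector("list", n)
  for (i in seq_len(n)) {
    ann <- if (pavs$pav_type[i] == "ref_deletion") ref_te else query_te
    tf <- te_fraction(pavs[i, ], ann)
    pavs$te_fraction[i] <- tf$te_fraction
    pavs$te_units[[i]] <- tf$te_units
    units <- tf$te_units[tf$te_units$covered >= 1L, , drop = FALSE]
    pavs$n_units[i] <- nrow(units)
    if (nrow(units)) {
      best <- order(-units$covered, seq_len(nrow(units)))[1]
      pavs$family[i] <- units$family[best]
      pavs$superfamily[i] <- units$superfamily[best]
    }
  }
  pavs$is_te_variation <- pavs$te_fraction > min_te_frac
  pavs
}
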