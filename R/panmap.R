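# Non-redundant pan-TE map construction: merging per-accession TE-variation
# callsets into loci, genotyping all accessions against the map, and
# polarizing loci against outgroups into derived TE variations (dTEs).

# union-find with path compression; clusters are single-linkage components
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

single_linkage <- function(n, pairs) {
  parent <- seq_len(n)
  if (length(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      a <- uf_find(parent, pairs[p, 1L])
      b <- uf_find(parent, pairs[p, 2L])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
}

#' Merge per-accession TE variations into non-redundant loci
#'
#' Single-linkage clustering per chromosome and PAV type: `ref_deletion`
#' calls cluster when their reciprocal overlap is at least
#' `reciprocal_overlap`; `ref_insertion` calls cluster when their insertion
#' points lie within `breakpoint_tol` bases and their min/max length ratio is
#' at least `length_ratio`. One locus is emitted per cluster with the longest
#' member as representative; transitive merges are intentional (single
#' linkage).
#'
#' @param callsets Data.frame of TE-variation PAVs across accessions
#'   (rbind of [classify_te_variations()] outputs, typically restricted to
#'   `is_te_variation`).
#' @param breakpoint_tol Insertion-point tolerance in bases (default 25).
#' @param reciprocal_overlap Minimum reciprocal overlap for deletions
#'   (default 0.8).
#' @param length_ratio Minimum min/max length ratio for insertions
#'   (default 0.8).
#' @return List with `loci` (one row per locus: `locus_id, ref_chrom,
#'   ref_start, ref_end, pav_type, length, family, superfamily, n_units`,
#'   plus `unit_families` list-column) and `members` (data.frame mapping
#'   `locus_id` to callset rows: `locus_id, accession, row`).
#' @export
merge_loci <- function(callsets, breakpoint_tol = 25L,
                       reciprocal_overlap = 0.8, length_ratio = 0.8) {
  n <- nrow(callsets)
  if (n == 0L) {
    return(list(loci = data.frame(), members = data.frame()))
  }
  callsets$.row <- seq_len(n)
  cluster <- integer(n)
  next_cl <- 0L
  for (key in unique(paste(callsets$ref_chrom, callsets$pav_type))) {
    sel <- which(paste(callsets$ref_chrom, callsets$pav_type) == key)
    d <- callsets[sel, , drop = FALSE]
    m <- nrow(d)
    pairs <- NULL
    if (m > 1L) {
      if (d$pav_type[1] == "ref_insertion") {
        ord <- order(d$ref_start)
        cand <- list()
        for (a in seq_len(m - 1L)) {
          i <- ord[a]
          for (b in (a + 1L):m) {
            j <- ord[b]
            if (d$ref_start[j] - d$ref_start[i] > breakpoint_tol) break
            ratio <- min(d$length[i], d$length[j]) / max(d$length[i], d$length[j])
            if (ratio >= length_ratio) {
              cand[[length(cand) + 1L]] <- c(i, j)
            }
          }
        }
        if (length(cand)) pairs <- do.call(rbind, cand)
      } else {
        ir <- IRanges::IRanges(d$ref_start + 1L, d$ref_end)
        hits <- IRanges::findOverlaps(ir, ir)
        hi <- S4Vectors::queryHits(hits)
        hj <- S4Vectors::subjectHits(hits)
        keep <- hi < hj
        hi <- hi[keep]; hj <- hj[keep]
        if (length(hi)) {
          ov <- overlap_len(d$ref_start[hi], d$ref_end[hi],
                            d$ref_start[hj], d$ref_end[hj])
          ok <- ov / d$length[hi] >= reciprocal_overlap &
            ov / d$length[hj] >= reciprocal_overlap
          if (any(ok)) pairs <- cbind(hi[ok], hj[ok])
        }
      }
    }
    comp <- single_linkage(m, pairs)
    cluster[sel] <- next_cl + match(comp, unique(comp))
    next_cl <- next_cl + length(unique(comp))
  }
  loci <- lapply(split(seq_len(n), cluster), function(rows) {
    d <- callsets[rows, , drop = FALSE]
    rep_i <- rows[order(-d$length, d$ref_start)[1]]
    r <- callsets[rep_i, , drop = FALSE]
    list(ref_chrom = r$ref_chrom, ref_start = r$ref_start,
         ref_end = r$ref_end, pav_type = r$pav_type, length = r$length,
         family = r$family, superfamily = r$superfamily,
         n_units = r$n_units,
         unit_families = if (!is.null(r$te_units[[1]]))
           r$te_units[[1]]$family else r$family,
         rows = rows)
  })
  ord <- order(vapply(loci, `[[`, "", "ref_chrom"),
               vapply(loci, `[[`, 0L, "ref_start"),
               vapply(loci, `[[`, 0L, "length"))
  loci <- loci[ord]
  ids <- sprintf("TEV_%05d", seq_along(loci))
  loci_df <- data.frame(
    locus_id = ids,
    ref_chrom = vapply(loci, `[[`, "", "ref_chrom"),
    ref_start = vapply(loci, `[[`, 0L, "ref_start"),
    ref_end = vapply(loci, `[[`, 0L, "ref_end"),
    pav_type = vapply(loci, `[[`, "", "pav_type"),
    length = vapply(loci, `[[`, 0L, "length"),
    family = vapply(loci, function(l) l$family %||% NA_character_, ""),
    superfamily = vapply(loci, function(l) l$superfamily %||% NA_character_, ""),
    n_units = vapply(loci, `[[`, 0L, "n_units"),
    stringsAsFactors = FALSE)
  loci_df$unit_families <- lapply(loci, `[[`, "unit_families")
  members <- do.call(rbind, lapply(seq_along(loci), function(k) {
    data.frame(locus_id = ids[k],
               accession = callsets$accession[loci[[k]]$rows],
               row = loci[[k]]$rows, stringsAsFactors = FALSE)
  }))
  rownames(loci_df) <- rownames(members) <- NULL
  list(loci = loci_df, members = members)
}

#' Genotype all accessions over the pan-TE map
#'
#' An accession is `1/1` at a locus if it contributed a member PAV, `0/0` if
#' its alignment coverage spans the locus breakpoint region
#' `[ref_start - tol, ref_end + tol]` without a member PAV, and `NA`
#' otherwise. Heterozygous `0/1` calls can only come from the optional
#' external het table (assembly-to-assembly alignment alone cannot observe
#' them); entries override non-`NA` states at matching loci.
#'
#' @param map Output of [merge_loci()].
#' @param coverages Named list (per accession) of coverage data.frames from
#'   [extract_pavs()].
#' @param accessions Data.frame `accession, subpop` (plus optional
#'   `is_outgroup`).
#' @param het_calls Optional data.frame `accession, chrom, ref_pos` of
#'   heterozygous calls.
#' @param tol Breakpoint tolerance in bases (default 25).
#' @return A `pante_genotypes` object: `states` (loci x accessions character
#'   matrix), `loci`, `accessions`.
#' @export
genotype_matrix <- function(map, coverages, accessions, het_calls = NULL,
                            tol = 25L) {
  loci <- map$loci
  n_l <- nrow(loci)
  accs <- accessions$accession
  states <- matrix(NA_character_, n_l, length(accs),
                   dimnames = list(loci$locus_id, accs))
  carrier <- table(factor(map$members$locus_id, levels = loci$locus_id),
                   factor(map$members$accession, levels = accs))
  missing_acc <- setdiff(unique(map$members$accession), accs)
  if (length(missing_acc)) {
    warning("callset accession(s) absent from the accession table: ",
            paste(missing_acc, collapse = ", "))
  }
  for (a in accs) {
    cov <- coverages[[a]]
    if (is.null(cov)) {
      warning("no coverage for accession ", a, "; all-NA column")
      next
    }
    has_pav <- carrier[, a] > 0L
    covered <- rep(FALSE, n_l)
    for (ch in unique(loci$ref_chrom)) {
      li <- which(loci$ref_chrom == ch)
      cv <- cov[cov$chrom == ch, , drop = FALSE]
      if (!nrow(cv)) next
      # locus is covered iff one merged interval spans the whole region
      for (k in li) {
        lo <- loci$ref_start[k] - tol
        hi <- loci$ref_end[k] + tol
        covered[k] <- any(cv$start <= lo & cv$end >= hi)
      }
    }
    states[has_pav, a] <- "1/1"
    states[!has_pav & covered, a] <- "0/0"
  }
  if (!is.null(het_calls) && nrow(het_calls)) {
    for (i in seq_len(nrow(het_calls))) {
      hit <- which(loci$ref_chrom == het_calls$chrom[i] &
                     abs(loci$ref_start - het_calls$ref_pos[i]) <= tol)
      a <- het_calls$accession[i]
      if (length(hit) && a %in% accs) {
        hit <- hit[which.min(abs(loci$ref_start[hit] - het_calls$ref_pos[i]))]
        if (!is.na(states[hit, a])) states[hit, a] <- "0/1"
      }
    }
  }
  if (is.null(accessions$is_outgroup)) {
    accessions$is_outgroup <- accessions$subpop == "outgroup"
  }
  structure(list(states = states, loci = loci, accessions = accessions),
            class = "pante_genotypes")
}

#' Polarize loci against outgroups
#'
#' The ancestral allele at a locus is the strict-majority allele among
#' non-`NA` outgroup genotypes (`0/0` votes for allele 0, `1/1` for allele
#' 1; a heterozygous outgroup votes for neither). A locus with no majority is
#' `unpolarized` and excluded from dTE analyses. Ingroup accessions whose
#' genotype differs from the ancestral homozygote (the opposite homozygote or
#' a heterozygote) are derived-state carriers. A locus is a dTE when it is
#' polarized and both derived-state and ancestral-state accessions exist
#' among the ingroup. Polarity follows from the ancestral allele and the PAV
#' type: the derived allele either gained the TE (INS) or lost it (DEL)
#' relative to the ancestral state.
#'
#' @param gm A `pante_genotypes` object.
#' @param outgroups Character vector of outgroup accession ids (default: the
#'   accessions flagged `is_outgroup`).
#' @return Data.frame: the loci table plus `ancestral_allele` (0/1/NA),
#'   `polarity` (INS/DEL/unpolarized), `dte`, `n_derived`, `n_ancestral`,
#'   `carrier_freq`.
#' @export
polarize_loci <- function(gm, outgroups = NULL) {
  acc <- gm$accessions
  if (is.null(outgroups)) {
    outgroups <- acc$accession[acc$is_outgroup %||% (acc$subpop == "outgroup")]
  }
  if (length(outgroups) < 1L) stop("at least one outgroup is required")
  ingroup <- setdiff(acc$accession, outgroups)
  st <- gm$states
  out <- gm$loci
  n_l <- nrow(out)
  anc <- rep(NA_integer_, n_l)
  pol <- rep("unpolarized", n_l)
  n_der <- integer(n_l)
  n_anc <- integer(n_l)
  freq <- rep(NA_real_, n_l)
  for (k in seq_len(n_l)) {
    og <- st[k, outgroups]
    v0 <- sum(og == "0/0", na.rm = TRUE)
    v1 <- sum(og == "1/1", na.rm = TRUE)
    if (v0 == v1) next  # all-NA, tied, or het-only outgroups: unpolarized
    a <- if (v0 > v1) 0L else 1L
    anc[k] <- a
    anc_hom <- if (a == 0L) "0/0" else "1/1"
    ig <- st[k, ingroup]
    n_der[k] <- sum(!is.na(ig) & ig != anc_hom)
    n_anc[k] <- sum(!is.na(ig) & ig == anc_hom)
    n_tot <- n_der[k] + n_anc[k]
    if (n_tot > 0L) freq[k] <- n_der[k] / n_tot
    # allele 1 of a ref_insertion PAV carries the TE; of a ref_deletion it
    # lacks it
    if (out$pav_type[k] == "ref_insertion") {
      pol[k] <- if (a == 0L) "INS" else "DEL"
    } else {
      pol[k] <- if (a == 0L) "DEL" else "INS"
    }
  }
  out$ancestral_allele <- anc
  out$polarity <- pol
  out$dte <- pol != "unpolarized" & n_der > 0L & n_anc > 0L
  out$n_derived <- n_der
  out$n_ancestral <- n_anc
  out$carrier_freq <- freq
  n_unpol <- sum(pol == "unpolarized")
  if (n_unpol > 0L) {
    message(n_unpol, " locus/loci unpolarized (no strict outgroup majority)")
  }
  out
}

#' Derived-carrier frequency of a polarized locus
#'
#' Frequency = derived-state accessions (heterozygotes count as carriers)
#' over non-`NA` ingroup accessions. `NA` when no ingroup genotype is
#' defined; such loci are excluded from frequency analyses.
#'
#' @param polarized One row of [polarize_loci()] output, or the full
#'   data.frame (vectorized: the `carrier_freq` column is returned).
#' @return Numeric carrier frequency/ies in \\[0, 1\\] or `NA`.
#' @export
carrier_frequency <- function(polarized) {
  polarized$carrier_freq
}

#' Classify every locus of a polarized map
#'
#' Partition of the map: each locus is exactly one of `dTE` (both states
#' segregate in the ingroup), `derived_fixed`, `ancestral_fixed`, or
#' `unpolarized`.
#'
#' @param polarized Output of [polarize_loci()].
#' @return Factor of the four classes, one per locus.
#' @export
locus_class <- function(polarized) {
  cls <- ifelse(polarized$polarity == "unpolarized", "unpolarized",
         ifelse(polarized$dte, "dTE",
         ifelse(polarized$n_derived > 0L, "derived_fixed", "ancestral_fixed")))
  factor(cls, levels = c("dTE", "derived_fixed", "ancestral_fixed",
                         "unpolarized"))
}
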