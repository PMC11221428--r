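# Synthetic rice-like population simulator.
#
# The generator plants TE insertion/deletion events on an ancestral backbone,
# draws per-accession genotypes from per-subpopulation derived-allele
# frequencies, uses one sampled ingroup accession as the alignment reference
# (so the map contains both reference-present and reference-absent loci), and
# emits every file the pipeline consumes together with a complete truth set.
# Outgroups are always fixed for the ancestral state.

#' Default TE family library
#'
#' A small library of TE families spanning the canonical superfamily
#' inventory (LTR retroelements Gypsy/Copia, non-LTR LINE/SINE, the DNA
#' transposon superfamilies DTC/DTA/DTT/DTM/DTH, Stowaway and Tourist MITEs,
#' and Helitrons) with length ranges typical for rice and sampling weights
#' reflecting the dominance of Gypsy, Copia and Helitron content.
#'
#' @return Data.frame with columns `family, superfamily, len_lo, len_hi,
#'   weight`.
#' @export
default_te_library <- function() {
  data.frame(
    family = c("RLG_1", "RLG_2", "RLC_1", "LINE_1", "SINE_1", "DTC_1",
               "DTA_1", "DTT_1", "DTM_1", "DTH_1", "STOW_1", "TOUR_1",
               "HEL_1"),
    superfamily = c("Gypsy", "Gypsy", "Copia", "LINE", "SINE", "DTC", "DTA",
                    "DTT", "DTM", "DTH", "MITE-Stowaway", "MITE-Tourist",
                    "Helitron"),
    len_lo = c(4000, 3500, 3000, 1000, 100, 500, 300, 200, 400, 300, 100,
               100, 500),
    len_hi = c(12000, 9000, 8000, 4000, 400, 2500, 2000, 1200, 2500, 1500,
               450, 450, 5000),
    weight = c(0.18, 0.10, 0.14, 0.05, 0.04, 0.06, 0.05, 0.05, 0.05, 0.04,
               0.06, 0.06, 0.12),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_population()].
#'
#' @param seed Integer RNG seed governing every random choice in the bundle.
#' @param ref_length Total backbone length in bases across chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Number of gene models placed on the reference.
#' @param te_library TE family library, see [default_te_library()]. All
#'   lengths must exceed 50 bp so planted events pass the PAV size filter.
#' @param n_ingroup Named integer vector: accessions per ingroup
#'   subpopulation (at least two subpopulations).
#' @param n_outgroup Number of outgroup accessions (>= 1), always fixed for
#'   the ancestral state.
#' @param n_te_events Number of planted TE presence/absence events.
#' @param fraction_selected Proportion of events given strongly
#'   subpopulation-differentiated frequencies.
#' @param selected_margin Minimum between-subpopulation frequency difference
#'   for selected events.
#' @param ins_fraction Proportion of events whose derived allele gained the
#'   TE (INS polarity).
#' @param multi_unit_rate Proportion of events composed of two or more TE
#'   units.
#' @param n_snps Number of small variants (SNPs plus a minority of short
#'   InDels) in the companion VCF.
#' @param het_rate Probability that a derived-allele carrier is heterozygous.
#' @param na_rate Per-cell probability that an accession's alignment coverage
#'   is masked over a locus, which the genotyper must report as `NA`.
#' @param n_egenes,eqtl_r2 Number of genes given a planted cis TE eQTL and
#'   the expression variance it explains.
#' @param n_causal_trait_loci,trait_h2 Causal loci and heritability of the
#'   simulated quantitative trait.
#' @return A validated `pante_sim_config` list.
#' @export
sim_config <- function(seed = 1L, ref_length = 1e6, n_chromosomes = 2L,
                       n_genes = 40L, te_library = default_te_library(),
                       n_ingroup = c(pop1 = 15L, pop2 = 15L),
                       n_outgroup = 2L, n_te_events = 300L,
                       fraction_selected = 0.05, selected_margin = 0.7,
                       ins_fraction = 0.7, multi_unit_rate = 0.14,
                       n_snps = 800L, het_rate = 0.03, na_rate = 0,
                       n_egenes = 8L, eqtl_r2 = 0.3,
                       n_causal_trait_loci = 1L, trait_h2 = 0.3) {
  cfg <- list(seed = as.integer(seed), ref_length = as.integer(ref_length),
              n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes), te_library = te_library,
              n_ingroup = n_ingroup, n_outgroup = as.integer(n_outgroup),
              n_te_events = as.integer(n_te_events),
              fraction_selected = fraction_selected,
              selected_margin = selected_margin,
              ins_fraction = ins_fraction,
              multi_unit_rate = multi_unit_rate,
              n_snps = as.integer(n_snps), het_rate = het_rate,
              na_rate = na_rate, n_egenes = as.integer(n_egenes),
              eqtl_r2 = eqtl_r2,
              n_causal_trait_loci = as.integer(n_causal_trait_loci),
              trait_h2 = trait_h2)
  counts <- c(cfg$ref_length, cfg$n_chromosomes, cfg$n_genes, cfg$n_outgroup,
              cfg$n_te_events, cfg$n_snps, cfg$n_egenes,
              cfg$n_causal_trait_loci, cfg$n_ingroup)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_chromosomes < 1L) stop("need at least one chromosome")
  props <- c(cfg$fraction_selected, cfg$ins_fraction, cfg$multi_unit_rate,
             cfg$het_rate, cfg$na_rate, cfg$trait_h2, cfg$selected_margin)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (length(cfg$n_ingroup) < 1L || is.null(names(cfg$n_ingroup))) {
    stop("n_ingroup must be a named vector of subpopulation sizes")
  }
  if (cfg$n_outgroup < 1L) stop("need at least one outgroup accession")
  if (any(cfg$te_library$len_lo <= 50)) {
    stop("te_library lengths must exceed 50 bp so planted events pass the ",
         "PAV size filter")
  }
  if (any(cfg$te_library$len_hi < cfg$te_library$len_lo)) {
    stop("te_library len_hi must be >= len_lo")
  }
  structure(cfg, class = "pante_sim_config")
}

# Draw the planted events: polarity, selection status, per-subpopulation
# derived-allele frequencies, and TE unit composition. Frequencies of
# non-selected events are shared across subpopulations; INS events draw from
# a low-frequency-skewed Beta and DEL events from a flatter one, so the
# INS/DEL count ratio falls with frequency as in natural TE spectra.
draw_event_models <- function(n_events, subpops, cfg) {
  lib <- cfg$te_library
  polarity <- ifelse(runif(n_events) < cfg$ins_fraction, "INS", "DEL")
  selected <- rep(FALSE, n_events)
  n_sel <- round(cfg$fraction_selected * n_events)
  if (n_sel > 0L) selected[sample.int(n_events, n_sel)] <- TRUE
  freqs <- matrix(0, n_events, length(subpops),
                  dimnames = list(NULL, subpops))
  for (e in seq_len(n_events)) {
    if (selected[e] && length(subpops) >= 2L) {
      lo <- runif(1, 0.02, 0.12)
      hi <- min(0.98, lo + cfg$selected_margin + runif(1, 0, 0.1))
      f <- rep(lo, length(subpops))
      f[sample.int(length(subpops), 1L)] <- hi
      freqs[e, ] <- f
    } else {
      f <- if (polarity[e] == "INS") rbeta(1, 0.35, 1.4) else rbeta(1, 1.2, 0.9)
      freqs[e, ] <- min(max(f, 0.02), 0.98)
    }
  }
  units <- lapply(seq_len(n_events), function(e) {
    k <- if (runif(1) < cfg$multi_unit_rate) sample(2:3, 1L, prob = c(0.8, 0.2)) else 1L
    rows <- sample.int(nrow(lib), k, replace = TRUE, prob = lib$weight)
    data.frame(family = lib$family[rows], superfamily = lib$superfamily[rows],
               length = vapply(rows, function(r)
                 as.integer(round(runif(1, lib$len_lo[r], lib$len_hi[r]))), 0L),
               stringsAsFactors = FALSE)
  })
  list(polarity = polarity, selected = selected, freqs = freqs, units = units,
       total_length = vapply(units, function(u) sum(u$length), 0L),
       family = vapply(units, function(u) {
         # locus-level label: unit with most bases, ties broken by position
         u$family[order(-u$length, seq_len(nrow(u)))[1]]
       }, ""),
       superfamily = vapply(units, function(u) {
         u$superfamily[order(-u$length, seq_len(nrow(u)))[1]]
       }, ""))
}

# Per-accession derived-allele dosages (0/1/2) given per-subpop frequencies.
draw_doses <- function(freqs, accessions, het_rate) {
  n_e <- nrow(freqs)
  dose <- matrix(0L, n_e, nrow(accessions),
                 dimnames = list(NULL, accessions$accession))
  for (j in which(!accessions$is_outgroup)) {
    p <- freqs[, accessions$subpop[j]]
    carrier <- runif(n_e) < p
    dose[, j] <- ifelse(carrier, ifelse(runif(n_e) < het_rate, 1L, 2L), 0L)
  }
  dose
}

make_accessions <- function(n_ingroup, n_outgroup) {
  acc <- do.call(rbind, lapply(names(n_ingroup), function(sp) {
    data.frame(accession = sprintf("%s_%02d", toupper(sp), seq_len(n_ingroup[[sp]])),
               subpop = sp, is_outgroup = FALSE, stringsAsFactors = FALSE)
  }))
  if (n_outgroup > 0L) {
    acc <- rbind(acc, data.frame(
      accession = sprintf("OUT_%02d", seq_len(n_outgroup)),
      subpop = "outgroup", is_outgroup = TRUE, stringsAsFactors = FALSE))
  }
  rownames(acc) <- NULL
  acc
}

#' Simulate a synthetic population bundle
#'
#' Generates an ancestral backbone, plants non-overlapping TE events (INS
#' polarity: TE absent in the ancestor, gained by derived carriers; DEL:
#' present in the ancestor, lost by derived carriers), draws genotypes per
#' subpopulation frequency, designates one sampled ingroup accession as the
#' alignment reference, and writes per-accession FASTA, truth PAF alignments
#' (`cg:Z` CIGARs), per-genome TE annotation GFF3, gene models, a SNP/InDel
#' VCF, a recombination-rate track, expression and phenotype tables, and the
#' complete truth set. `NA` genotypes are simulated by masking alignment
#' coverage around a locus, at rate `na_rate`.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created; must not already contain a bundle).
#' @return A `pante_bundle` list: file `paths`, the `config`, `accessions`,
#'   the truth `events` table, truth dosage/state matrices, `het_calls`,
#'   gene models, expression/phenotype truth and the reference accession id.
#' @export
simulate_population <- function(config, dir = tempfile("pante_sim_")) {
  stopifnot(inherits(config, "pante_sim_config"))
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("genomes", "aln", "te", "truth")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  subpops <- names(config$n_ingroup)
  acc <- make_accessions(config$n_ingroup, config$n_outgroup)
  n_acc <- nrow(acc)

  chrom_len <- config$ref_length %/% config$n_chromosomes
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  backbone <- setNames(lapply(chroms, function(ch) random_dna(chrom_len)), chroms)

  # --- events ------------------------------------------------------------
  n_e <- config$n_te_events
  ev_chrom <- if (n_e > 0L) sort(rep_len(chroms, n_e)) else character(0)
  anchors <- unlist(lapply(chroms, function(ch) {
    k <- sum(ev_chrom == ch)
    spaced_positions(chrom_len, k, gap = 100L, edge = 100L)
  }), use.names = FALSE)
  mod <- draw_event_models(n_e, subpops, config)
  ev_seq <- vapply(seq_len(n_e), function(e) random_dna(mod$total_length[e]), "")
  dose <- draw_doses(mod$freqs, acc, config$het_rate)

  # presence of the TE sequence in each accession's assembly (haplotype
  # carries the derived allele for any derived-state genotype)
  presence_of <- function(dose_vec, polarity) {
    ifelse(dose_vec > 0L, polarity == "INS", polarity == "DEL")
  }
  ref_idx <- if (any(!acc$is_outgroup)) sample(which(!acc$is_outgroup), 1L) else 1L
  ref_name <- acc$accession[ref_idx]

  # every planted event must be visible against the reference: if the
  # reference carries the ancestral allele, at least one ingroup accession
  # must carry the derived allele (redraw, keeping the frequency model)
  if (n_e > 0L) {
    for (e in seq_len(n_e)) {
      for (try in seq_len(100L)) {
        pres <- presence_of(dose[e, ], mod$polarity[e])
        if (any(pres != pres[ref_idx])) break
        ing <- which(!acc$is_outgroup)
        p <- mod$freqs[e, acc$subpop[ing]]
        carrier <- runif(length(ing)) < p
        dose[e, ing] <- ifelse(carrier,
                               ifelse(runif(length(ing)) < config$het_rate, 1L, 2L), 0L)
      }
      pres <- presence_of(dose[e, ], mod$polarity[e])
      if (all(pres == pres[ref_idx])) {
        j <- sample(setdiff(which(!acc$is_outgroup), ref_idx), 1L)
        dose[e, j] <- 2L
      }
    }
  }
  presence <- matrix(FALSE, max(n_e, 0L), n_acc, dimnames = list(NULL, acc$accession))
  for (e in seq_len(n_e)) presence[e, ] <- presence_of(dose[e, ], mod$polarity[e])

  mask <- matrix(runif(n_e * n_acc) < config$na_rate, max(n_e, 0L), n_acc,
                 dimnames = list(NULL, acc$accession))
  if (n_e > 0L) mask[, ref_idx] <- FALSE

  ev <- data.frame(event_id = sprintf("ev%04d", seq_len(n_e)),
                   chrom = ev_chrom, anchor = as.integer(anchors),
                   polarity = mod$polarity, selected = mod$selected,
                   total_length = mod$total_length,
                   n_units = vapply(mod$units, nrow, 0L),
                   family = mod$family, superfamily = mod$superfamily,
                   stringsAsFactors = FALSE)
  if (n_e == 0L) {
    ev <- data.frame(event_id = character(0), chrom = character(0),
                     anchor = integer(0), polarity = character(0),
                     selected = logical(0), total_length = integer(0),
                     n_units = integer(0), family = character(0),
                     superfamily = character(0), stringsAsFactors = FALSE)
  }

  # --- genome sequences, coordinates and TE annotations -------------------
  genome_coord <- function(j) {
    # genome coordinate of each event anchor in accession j, plus chrom lengths
    coord <- integer(n_e)
    clen <- setNames(integer(length(chroms)), chroms)
    for (ch in chroms) {
      idx <- which(ev$chrom == ch)
      idx <- idx[order(ev$anchor[idx])]
      plen <- ifelse(presence[idx, j], ev$total_length[idx], 0L)
      coord[idx] <- ev$anchor[idx] + c(0L, cumsum(plen))[seq_along(idx)]
      clen[ch] <- chrom_len + sum(plen)
    }
    list(coord = coord, chrom_len = clen)
  }

  build_genome <- function(j) {
    seqs <- setNames(character(length(chroms)), chroms)
    annot <- list()
    for (ch in chroms) {
      idx <- which(ev$chrom == ch)
      idx <- idx[order(ev$anchor[idx])]
      pieces <- character(0)
      prev <- 0L
      gpos <- 0L
      for (e in idx) {
        seg <- ev$anchor[e] - prev
        if (seg > 0L) pieces <- c(pieces, substr(backbone[[ch]], prev + 1L, ev$anchor[e]))
        gpos <- gpos + seg
        if (presence[e, j]) {
          pieces <- c(pieces, ev_seq[e])
          u <- mod$units[[e]]
          ustart <- gpos + c(0L, cumsum(u$length))[seq_len(nrow(u))]
          annot[[length(annot) + 1L]] <- data.frame(
            chrom = ch, start = ustart, end = ustart + u$length,
            superfamily = u$superfamily, family = u$family,
            stringsAsFactors = FALSE)
          gpos <- gpos + ev$total_length[e]
        }
        prev <- ev$anchor[e]
      }
      if (chrom_len - prev > 0L) {
        pieces <- c(pieces, substr(backbone[[ch]], prev + 1L, chrom_len))
      }
      seqs[ch] <- paste(pieces, collapse = "")
    }
    annot <- if (length(annot)) do.call(rbind, annot) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 superfamily = character(0), family = character(0),
                 stringsAsFactors = FALSE)
    list(seqs = seqs, annot = annot)
  }

  paths <- list(dir = dir, ref_fa = file.path(dir, "ref.fa"),
                genome_fa = setNames(file.path(dir, "genomes", paste0(acc$accession, ".fa")), acc$accession),
                paf = setNames(file.path(dir, "aln", paste0(acc$accession, ".paf")), acc$accession),
                te_gff3 = setNames(file.path(dir, "te", paste0(acc$accession, ".te.gff3")), acc$accession),
                ref_te_gff3 = file.path(dir, "te", "reference.te.gff3"),
                genes_gff3 = file.path(dir, "genes.gff3"),
                snp_vcf = file.path(dir, "snps.vcf"),
                recomb = file.path(dir, "recomb.tsv"),
                expression = file.path(dir, "expression.tsv"),
                phenotype = file.path(dir, "phenotype.tsv"),
                events = file.path(dir, "truth", "events.tsv"),
                genotypes = file.path(dir, "truth", "genotypes.tsv"),
                expected_states = file.path(dir, "truth", "expected_states.tsv"),
                het_calls = file.path(dir, "truth", "het_calls.tsv"),
                eqtl_truth = file.path(dir, "truth", "eqtl.tsv"),
                trait_truth = file.path(dir, "truth", "trait.tsv"))

  write_fa <- function(seqs, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, path, width = 60L)
  }

  ref_coordmap <- genome_coord(ref_idx)
  genomes <- vector("list", n_acc)
  for (j in seq_len(n_acc)) {
    g <- build_genome(j)
    genomes[[j]] <- g
    write_fa(g$seqs, paths$genome_fa[j])
    ann <- g$annot
    ann$genome <- rep(acc$accession[j], nrow(ann))
    ann$strand <- rep("+", nrow(ann))
    ann$intact <- rep(TRUE, nrow(ann))
    write_te_gff3(ann, paths$te_gff3[j])
  }
  ref_genome <- genomes[[ref_idx]]
  write_fa(ref_genome$seqs, paths$ref_fa)
  ref_ann <- ref_genome$annot
  ref_ann$genome <- rep("reference", nrow(ref_ann))
  ref_ann$strand <- rep("+", nrow(ref_ann))
  ref_ann$intact <- rep(TRUE, nrow(ref_ann))
  write_te_gff3(ref_ann, paths$ref_te_gff3)

  # reference-relative truth: locus breakpoints, PAV type, expected states
  ref_pres <- if (n_e > 0L) presence[, ref_idx] else logical(0)
  ev$ref_start <- ref_coordmap$coord
  ev$ref_end <- ifelse(ref_pres, ev$ref_start + ev$total_length, ev$ref_start)
  ev$pav_type <- ifelse(ref_pres, "ref_deletion", "ref_insertion")

  expected <- matrix(NA_character_, max(n_e, 0L), n_acc,
                     dimnames = list(ev$event_id, acc$accession))
  for (e in seq_len(n_e)) {
    st <- ifelse(dose[e, ] == 1L, "0/1",
                 ifelse(presence[e, ] != ref_pres[e], "1/1", "0/0"))
    st[mask[e, ]] <- NA_character_
    expected[e, ] <- st
  }
  truth_geno <- matrix(c("0/0", "0/1", "1/1")[dose + 1L], max(n_e, 0L), n_acc,
                       dimnames = list(ev$event_id, acc$accession))

  # --- truth alignments (PAF) --------------------------------------------
  mask_margin <- 40L
  for (j in seq_len(n_acc)) {
    cm <- genome_coord(j)
    recs <- list()
    for (ch in chroms) {
      idx <- which(ev$chrom == ch)
      idx <- idx[order(ev$anchor[idx])]
      # item stream: alternating aligned backbone segments and events
      segs <- diff(c(0L, ev$anchor[idx], chrom_len))
      pre_trim <- integer(length(idx))
      post_trim <- integer(length(idx))
      for (k in seq_along(idx)) {
        if (mask[idx[k], j]) {
          pre_trim[k] <- min(mask_margin, segs[k] - (if (k > 1L) post_trim[k - 1L] else 0L))
          post_trim[k] <- min(mask_margin, segs[k + 1L])
        }
      }
      tpos <- 0L; qpos <- 0L
      cur <- NULL  # list(tstart, qstart, ops=list of c(len, op))
      push_op <- function(cur, len, op) {
        if (len <= 0L) return(cur)
        n <- length(cur$ops)
        if (n > 0L && cur$ops[[n]][2] == op) {
          cur$ops[[n]][1] <- as.integer(cur$ops[[n]][1]) + len
        } else cur$ops[[length(cur$ops) + 1L]] <- c(len, op)
        cur
      }
      flush <- function(cur, tpos, qpos) {
        if (is.null(cur) || length(cur$ops) == 0L) return(NULL)
        lens <- vapply(cur$ops, function(o) as.integer(o[1]), 0L)
        ops <- vapply(cur$ops, function(o) o[2], "")
        list(qname = ch, qlen = unname(cm$chrom_len[ch]),
             qstart = cur$qstart, qend = qpos, strand = "+",
             tname = ch, tlen = unname(ref_coordmap$chrom_len[ch]),
             tstart = cur$tstart, tend = tpos,
             nmatch = sum(lens[ops == "="]), alen = sum(lens), mapq = 60L,
             cigar = data.frame(op = ops, len = lens, stringsAsFactors = FALSE))
      }
      out_recs <- list()
      for (k in seq_along(idx)) {
        e <- idx[k]
        seg <- segs[k] - (if (k > 1L) post_trim[k - 1L] else 0L) - pre_trim[k]
        if (is.null(cur)) cur <- list(tstart = tpos, qstart = qpos, ops = list())
        cur <- push_op(cur, seg, "=")
        tpos <- tpos + seg; qpos <- qpos + seg
        r_len <- if (ref_pres[e]) ev$total_length[e] else 0L
        q_len <- if (presence[e, j]) ev$total_length[e] else 0L
        if (mask[e, j]) {
          out_recs[[length(out_recs) + 1L]] <- flush(cur, tpos, qpos)
          cur <- NULL
          tpos <- tpos + pre_trim[k] + r_len + post_trim[k]
          qpos <- qpos + pre_trim[k] + q_len + post_trim[k]
        } else if (r_len > 0L && q_len > 0L) {
          cur <- push_op(cur, r_len, "=")
          tpos <- tpos + r_len; qpos <- qpos + q_len
        } else if (r_len > 0L) {
          cur <- push_op(cur, r_len, "D")
          tpos <- tpos + r_len
        } else if (q_len > 0L) {
          cur <- push_op(cur, q_len, "I")
          qpos <- qpos + q_len
        }
      }
      tail_seg <- segs[length(segs)] -
        (if (length(idx) > 0L) post_trim[length(idx)] else 0L)
      if (is.null(cur)) cur <- list(tstart = tpos, qstart = qpos, ops = list())
      cur <- push_op(cur, tail_seg, "=")
      tpos <- tpos + tail_seg; qpos <- qpos + tail_seg
      out_recs[[length(out_recs) + 1L]] <- flush(cur, tpos, qpos)
      recs <- c(recs, Filter(Negate(is.null), out_recs))
    }
    paf <- data.frame(
      qname = vapply(recs, `[[`, "", "qname"),
      qlen = vapply(recs, `[[`, 0L, "qlen"),
      qstart = vapply(recs, `[[`, 0L, "qstart"),
      qend = vapply(recs, `[[`, 0L, "qend"),
      strand = vapply(recs, `[[`, "", "strand"),
      tname = vapply(recs, `[[`, "", "tname"),
      tlen = vapply(recs, `[[`, 0L, "tlen"),
      tstart = vapply(recs, `[[`, 0L, "tstart"),
      tend = vapply(recs, `[[`, 0L, "tend"),
      nmatch = vapply(recs, `[[`, 0L, "nmatch"),
      alen = vapply(recs, `[[`, 0L, "alen"),
      mapq = vapply(recs, `[[`, 0L, "mapq"),
      stringsAsFactors = FALSE)
    paf$cigar <- lapply(recs, `[[`, "cigar")
    write_paf(paf, paths$paf[j])
  }

  # --- gene models on the reference --------------------------------------
  map_to_ref <- function(ch, b) {
    # backbone coordinate -> reference coordinate
    idx <- which(ev$chrom == ch & ref_pres & ev$anchor <= b)
    b + sum(ev$total_length[idx])
  }
  gene_models <- make_gene_models(config, chroms, chrom_len, map_to_ref)
  write_gene_models(gene_models, paths$genes_gff3)

  # --- SNPs / InDels -------------------------------------------------------
  snps <- make_small_variants(config, chroms, chrom_len, ev, acc, map_to_ref)
  write_snp_vcf(snps$variants, snps$dosage, paths$snp_vcf)

  # --- recombination track -------------------------------------------------
  win <- 100000L
  rec <- do.call(rbind, lapply(chroms, function(ch) {
    L <- unname(ref_coordmap$chrom_len[ch])
    starts <- seq(0L, max(L - 1L, 0L), by = win)
    data.frame(chrom = ch, start = starts, end = pmin(starts + win, L),
               rho = round(rlnorm(length(starts), log(4), 0.6), 4),
               stringsAsFactors = FALSE)
  }))
  write.table(rec, paths$recomb, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- het calls table ------------------------------------------------------
  het <- which(dose == 1L & !mask, arr.ind = TRUE)
  het_calls <- data.frame(
    accession = acc$accession[het[, 2L]],
    chrom = ev$chrom[het[, 1L]],
    ref_pos = ev$ref_start[het[, 1L]],
    event_id = ev$event_id[het[, 1L]], stringsAsFactors = FALSE)
  het_calls <- het_calls[order(het_calls$event_id, het_calls$accession), ]
  rownames(het_calls) <- NULL
  write.table(het_calls, paths$het_calls, sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- truth tables --------------------------------------------------------
  ev_out <- ev
  ev_out$unit_families <- vapply(mod$units, function(u) paste(u$family, collapse = ","), "")
  ev_out$unit_lengths <- vapply(mod$units, function(u) paste(u$length, collapse = ","), "")
  for (sp in subpops) ev_out[[paste0("freq_", sp)]] <- if (n_e) mod$freqs[, sp] else numeric(0)
  write.table(ev_out[, setdiff(names(ev_out), "anchor_seq")], paths$events,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(event_id = ev$event_id, as.data.frame(truth_geno)),
              paths$genotypes, sep = "\t", quote = FALSE, row.names = FALSE)
  exp_out <- expected
  exp_out[is.na(exp_out)] <- "NA"
  write.table(cbind(event_id = ev$event_id, as.data.frame(exp_out)),
              paths$expected_states, sep = "\t", quote = FALSE, row.names = FALSE)

  bundle <- structure(list(
    dir = dir, config = config, paths = paths, accessions = acc,
    ref_accession = ref_name, chroms = chroms, chrom_len = chrom_len,
    events = ev_out, units = mod$units, dose = dose, mask = mask,
    truth_genotypes = truth_geno, expected_states = expected,
    het_calls = het_calls, gene_models = gene_models, snps = snps,
    expression = NULL, eqtl_truth = NULL, phenotype = NULL,
    trait_truth = NULL), class = "pante_bundle")

  if (config$n_egenes > 0L || config$n_te_events > 0L) {
    bundle <- simulate_expression(bundle, n_egenes = config$n_egenes,
                                  eqtl_r2 = config$eqtl_r2,
                                  seed = child_seed(config$seed, "expression"))
  }
  if (config$n_causal_trait_loci > 0L) {
    bundle <- simulate_phenotype(bundle,
                                 causal_loci = config$n_causal_trait_loci,
                                 trait_h2 = config$trait_h2,
                                 seed = child_seed(config$seed, "phenotype"))
  }
  # config snapshot for reproducibility
  cfg_out <- unclass(config)
  cfg_out$te_library <- as.list(cfg_out$te_library)
  cfg_out$n_ingroup <- as.list(cfg_out$n_ingroup)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  bundle
}

make_gene_models <- function(config, chroms, chrom_len, map_to_ref) {
  n_g <- config$n_genes
  if (n_g == 0L) {
    return(list(genes = data.frame(gene_id = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0)),
                features = data.frame(gene_id = character(0), chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0), type = character(0))))
  }
  g_chrom <- sort(rep_len(chroms, n_g))
  genes <- list(); feats <- list()
  gi <- 0L
  for (ch in chroms) {
    k <- sum(g_chrom == ch)
    if (k == 0L) next
    starts <- spaced_positions(chrom_len, k, gap = 3000L, edge = 2500L)
    for (s in starts) {
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      strand <- sample(c("+", "-"), 1L)
      w <- c(utr5 = 150L, cds1 = as.integer(round(runif(1, 200, 500))),
             intron = as.integer(round(runif(1, 120, 400))),
             cds2 = as.integer(round(runif(1, 300, 700))), utr3 = 200L)
      # forward-layout parts; strand decides which UTR is 5'
      bnd <- s + c(0L, cumsum(w))
      part_types <- if (strand == "+") {
        c("five_prime_UTR", "CDS", NA, "CDS", "three_prime_UTR")
      } else {
        c("three_prime_UTR", "CDS", NA, "CDS", "five_prime_UTR")
      }
      rs <- vapply(bnd, function(b) map_to_ref(ch, b), 0)
      genes[[gi]] <- data.frame(gene_id = gid, chrom = ch,
                                start = as.integer(rs[1]), end = as.integer(rs[6]),
                                strand = strand, stringsAsFactors = FALSE)
      pf <- data.frame(gene_id = gid, chrom = ch,
                       start = as.integer(rs[-6]), end = as.integer(rs[-1]),
                       strand = strand, type = part_types,
                       stringsAsFactors = FALSE)
      ex <- data.frame(gene_id = gid, chrom = ch,
                       start = as.integer(c(rs[1], rs[4])),
                       end = as.integer(c(rs[3], rs[6])),
                       strand = strand, type = "exon", stringsAsFactors = FALSE)
      feats[[gi]] <- rbind(pf[!is.na(pf$type), ], ex)
    }
  }
  feat <- do.call(rbind, feats)
  intr <- do.call(rbind, lapply(feats, function(f) {
    ex <- f[f$type == "exon", ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(gene_id = ex$gene_id[1], chrom = ex$chrom[1],
               start = ex$end[-nrow(ex)], end = ex$start[-1],
               strand = ex$strand[1], type = "intron", stringsAsFactors = FALSE)
  }))
  feat <- rbind(feat, intr)
  rownames(feat) <- NULL
  list(genes = do.call(rbind, genes), features = feat)
}

make_small_variants <- function(config, chroms, chrom_len, ev, acc, map_to_ref) {
  n_s <- config$n_snps
  if (n_s == 0L) {
    return(list(variants = data.frame(variant_id = character(0), chrom = character(0),
                                      pos = integer(0), ref = character(0),
                                      alt = character(0), class = character(0)),
                dosage = matrix(NA_real_, 0L, nrow(acc),
                                dimnames = list(NULL, acc$accession))))
  }
  s_chrom <- sort(rep_len(chroms, n_s))
  pos_b <- unlist(lapply(chroms, function(ch) {
    k <- sum(s_chrom == ch)
    avoid <- ev$anchor[ev$chrom == ch]
    p <- sample(setdiff(seq(50L, chrom_len - 50L), avoid), k)
    sort(p)
  }), use.names = FALSE)
  pos_ref <- vapply(seq_len(n_s), function(i) map_to_ref(s_chrom[i], pos_b[i]), 0)
  is_indel <- runif(n_s) < 0.1
  bases <- c("A", "C", "G", "T")
  ref_al <- sample(bases, n_s, replace = TRUE)
  alt_al <- vapply(seq_len(n_s), function(i) {
    if (is_indel[i]) paste0(ref_al[i], random_dna(sample(1:4, 1L)))
    else sample(setdiff(bases, ref_al[i]), 1L)
  }, "")
  # Balding-Nichols differentiation between subpopulations
  Fst <- 0.15
  p_anc <- rbeta(n_s, 1.2, 1.2)
  dosage <- matrix(NA_real_, n_s, nrow(acc),
                   dimnames = list(NULL, acc$accession))
  subpops <- unique(acc$subpop[!acc$is_outgroup])
  p_sub <- sapply(subpops, function(sp)
    rbeta(n_s, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst))
  for (j in seq_len(nrow(acc))) {
    p <- if (acc$is_outgroup[j]) p_anc else p_sub[, acc$subpop[j]]
    dosage[j_idx <- seq_len(n_s), j] <- rbinom(n_s, 2L, p)
  }
  variants <- data.frame(
    variant_id = sprintf("sv%05d", seq_len(n_s)), chrom = s_chrom,
    pos = as.integer(pos_ref), ref = ref_al, alt = alt_al,
    class = ifelse(is_indel, "InDel", "SNP"), stringsAsFactors = FALSE)
  rownames(dosage) <- variants$variant_id
  list(variants = variants, dosage = dosage)
}

#' Simulate expression with planted cis TE eQTLs
#'
#' For each planted eGene, expression is `intercept + beta * dosage +
#' Gaussian noise`, with `beta` scaled so the genotype explains `eqtl_r2` of
#' the expression variance among ingroup accessions; remaining genes are pure
#' noise. A monomorphic candidate genotype vector is resampled.
#'
#' @param bundle A `pante_bundle`.
#' @param n_egenes Number of genes given a planted eQTL.
#' @param eqtl_r2 Target proportion of expression variance explained, in
#'   (0, 1).
#' @param seed RNG seed for this stage.
#' @return The bundle with `expression` (genes x ingroup accessions matrix)
#'   and `eqtl_truth` filled in, and the TSVs written.
#' @export
simulate_expression <- function(bundle, n_egenes, eqtl_r2, seed) {
  if (n_egenes > 0L && (eqtl_r2 <= 0 || eqtl_r2 >= 1)) {
    stop("eqtl_r2 must lie strictly between 0 and 1")
  }
  set.seed(seed)
  genes <- bundle$gene_models$genes
  ing <- bundle$accessions$accession[!bundle$accessions$is_outgroup]
  n <- length(ing)
  expr <- matrix(rnorm(nrow(genes) * n, mean = 100, sd = 1), nrow(genes), n,
                 dimnames = list(genes$gene_id, ing))
  truth <- data.frame(gene_id = character(0), event_id = character(0),
                      beta = numeric(0), r2 = numeric(0),
                      stringsAsFactors = FALSE)
  ev <- bundle$events
  if (n_egenes > 0L && nrow(ev) > 0L && nrow(genes) > 0L) {
    flank <- 50000L
    cis_events <- function(g) {
      which(ev$chrom == genes$chrom[g] &
              ev$ref_start <= genes$end[g] + flank &
              ev$ref_end >= genes$start[g] - flank)
    }
    cand <- which(vapply(seq_len(nrow(genes)), function(g) {
      any(vapply(cis_events(g), function(e)
        var(bundle$dose[e, ing]) > 0, TRUE))
    }, TRUE))
    pick <- sample(cand, min(n_egenes, length(cand)))
    for (g in pick) {
      es <- cis_events(g)
      es <- es[vapply(es, function(e) var(bundle$dose[e, ing]) > 0, TRUE)]
      e <- if (length(es) > 1L) sample(es, 1L) else es
      dvec <- bundle$dose[e, ing]
      beta <- sqrt(eqtl_r2 / (1 - eqtl_r2) / var(dvec))
      expr[g, ] <- 100 + beta * dvec + rnorm(n)
      truth <- rbind(truth, data.frame(gene_id = genes$gene_id[g],
                                       event_id = ev$event_id[e],
                                       beta = beta, r2 = eqtl_r2,
                                       stringsAsFactors = FALSE))
    }
  }
  bundle$expression <- expr
  bundle$eqtl_truth <- truth
  write.table(cbind(gene_id = rownames(expr), as.data.frame(round(expr, 6))),
              bundle$paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth, bundle$paths$eqtl_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  bundle
}

#' Simulate a quantitative trait with planted causal TE loci
#'
#' The trait is `intercept + sum(beta * dosage) + Gaussian noise` over the
#' ingroup, with the noise variance scaled so the causal loci jointly explain
#' `trait_h2` of the trait variance. `trait_h2 = 0` yields a phenotype
#' independent of all genotypes.
#'
#' @param bundle A `pante_bundle`.
#' @param causal_loci Number of causal loci to plant, or a character vector
#'   of event ids.
#' @param trait_h2 Proportion of trait variance explained, in \\[0, 1).
#' @param seed RNG seed for this stage.
#' @return The bundle with `phenotype` and `trait_truth` filled in.
#' @export
simulate_phenotype <- function(bundle, causal_loci, trait_h2, seed) {
  if (trait_h2 < 0 || trait_h2 >= 1) stop("trait_h2 must lie in [0, 1)")
  set.seed(seed)
  ing <- bundle$accessions$accession[!bundle$accessions$is_outgroup]
  n <- length(ing)
  ev <- bundle$events
  if (is.character(causal_loci)) {
    eidx <- match(causal_loci, ev$event_id)
    if (anyNA(eidx)) stop("unknown causal event id(s)")
  } else {
    poly <- which(apply(bundle$dose[, ing, drop = FALSE], 1L, var) > 0)
    eidx <- sample(poly, min(causal_loci, length(poly)))
  }
  G <- rep(0, n)
  betas <- numeric(length(eidx))
  if (length(eidx) > 0L && trait_h2 > 0) {
    for (k in seq_along(eidx)) {
      betas[k] <- 1
      G <- G + bundle$dose[eidx[k], ing]
    }
    vg <- var(G)
    noise_sd <- sqrt(vg * (1 - trait_h2) / trait_h2)
  } else {
    noise_sd <- 1
  }
  y <- 50 + G + rnorm(n, sd = noise_sd)
  pheno <- data.frame(accession = ing, value = round(y, 6),
                      stringsAsFactors = FALSE)
  truth <- data.frame(event_id = ev$event_id[eidx], beta = betas,
                      trait_h2 = trait_h2, stringsAsFactors = FALSE)
  bundle$phenotype <- pheno
  bundle$trait_truth <- truth
  write.table(pheno, bundle$paths$phenotype, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth, bundle$paths$trait_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  bundle
}

#' Simulate a genotype-level pan-TE data set (no sequences)
#'
#' A light-weight companion to [simulate_population()] for statistical
#' studies that need many loci or accessions without the cost of sequence
#' simulation. Loci are placed along a single virtual chromosome; states are
#' coded with allele 1 as the derived allele and outgroups fixed `0/0`.
#'
#' @param n_per_subpop Named vector of ingroup subpopulation sizes.
#' @param n_outgroup Number of outgroup accessions.
#' @param n_loci Number of loci.
#' @param fraction_selected,selected_margin,ins_fraction,multi_unit_rate,het_rate,na_rate
#'   As in [sim_config()].
#' @param chrom_length Virtual chromosome length for locus placement.
#' @param te_library TE family library.
#' @param seed RNG seed.
#' @return A `pante_genotypes` object with an extra `truth` data.frame
#'   (per-locus subpopulation frequencies, polarity and selection flags).
#' @export
simulate_genotypes <- function(n_per_subpop = c(pop1 = 50L, pop2 = 50L),
                               n_outgroup = 2L, n_loci = 500L,
                               fraction_selected = 0.04,
                               selected_margin = 0.7, ins_fraction = 0.7,
                               multi_unit_rate = 0.14, het_rate = 0.03,
                               na_rate = 0, chrom_length = 2e6,
                               te_library = default_te_library(),
                               seed = 1L) {
  set.seed(seed)
  cfg <- list(te_library = te_library, fraction_selected = fraction_selected,
              selected_margin = selected_margin, ins_fraction = ins_fraction,
              multi_unit_rate = multi_unit_rate)
  subpops <- names(n_per_subpop)
  acc <- make_accessions(n_per_subpop, n_outgroup)
  mod <- draw_event_models(n_loci, subpops, cfg)
  dose <- draw_doses(mod$freqs, acc, het_rate)
  pos <- spaced_positions(as.integer(chrom_length), n_loci, gap = 100L,
                          edge = 100L)
  states <- matrix(c("0/0", "0/1", "1/1")[dose + 1L], n_loci, nrow(acc),
                   dimnames = list(sprintf("L%05d", seq_len(n_loci)),
                                   acc$accession))
  if (na_rate > 0) {
    states[matrix(runif(length(states)) < na_rate, n_loci)] <- NA_character_
  }
  len <- vapply(mod$units, function(u) sum(u$length), 0L)
  loci <- data.frame(
    locus_id = rownames(states), ref_chrom = "chr1", ref_start = pos,
    ref_end = ifelse(mod$polarity == "DEL", pos + len, pos),
    pav_type = ifelse(mod$polarity == "INS", "ref_insertion", "ref_deletion"),
    length = len, family = mod$family, n_units = vapply(mod$units, nrow, 0L),
    stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = loci$locus_id, polarity = mod$polarity,
                      selected = mod$selected, stringsAsFactors = FALSE)
  for (sp in subpops) truth[[paste0("freq_", sp)]] <- mod$freqs[, sp]
  structure(list(states = states, loci = loci, accessions = acc,
                 truth = truth), class = "pante_genotypes")
}
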