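# End-to-end orchestration: simulate (or load) -> call PAVs -> classify TE
# variations -> merge -> genotype -> polarize -> population-genetic and
# association analyses, with a machine-readable run manifest.
#
# Outputs are first written into a `.partial` subdirectory and promoted to
# the output directory only when the run completes, so a failed run never
# leaves consumable half-written tables.

default_run_config <- function() {
  list(
    simulate = TRUE,
    sim = list(),
    thresholds = list(min_pav_len = 50L, min_te_frac = 0.9,
                      breakpoint_tol = 25L, reciprocal_overlap = 0.8,
                      length_ratio = 0.8, genotype_tol = 25L),
    analyses = list(window = 100000L, top_quantile = 0.05, n_perm = 500L,
                    genic_flank = 2000L, ld_flank = 50000L, cis_flank = 50000L,
                    n_pcs = 3L, spectrum_bin = 0.05))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the pan-TE pipeline end to end
#'
#' Executes all stages in order under a single configuration and seed;
#' failure in any stage halts with a stage-named error, and a rerun with the
#' identical config and seed reproduces identical outputs.
#'
#' @param config Path to a YAML run configuration, or an equivalent list.
#'   Keys: `simulate` (logical), `sim` (arguments to [sim_config()]),
#'   `inputs` (when `simulate = FALSE`: `ref_fa`, `accessions_tsv`, and
#'   per-accession `paf`/`fasta`/`te_gff3` directories plus `ref_te_gff3`),
#'   `thresholds` and `analyses` (see `default_run_config()`).
#' @param outdir Output directory.
#' @return A `RunManifest`-style list (also written as `manifest.json`):
#'   config hash, seed, per-stage output paths and counts, versions,
#'   timestamps.
#' @export
run_end_to_end <- function(config, outdir) {
  t0 <- Sys.time()
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  work <- file.path(outdir, ".partial")
  unlink(work, recursive = TRUE)
  dir.create(work)

  cfg_file <- file.path(work, "run_config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))

  # --- stage: inputs ------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    bundle <- run_stage("simulate", {
      sim_cfg <- do.call(sim_config, cfg$sim)
      simulate_population(sim_cfg, dir = file.path(work, "sim"))
    })
    accessions <- bundle$accessions
    ref_fa <- bundle$paths$ref_fa
    paf_paths <- bundle$paths$paf
    fa_paths <- bundle$paths$genome_fa
    te_paths <- bundle$paths$te_gff3
    ref_te_path <- bundle$paths$ref_te_gff3
    het_calls <- bundle$het_calls
    seed <- bundle$config$seed
  } else {
    loaded <- run_stage("load_inputs", {
      req <- c("ref_fa", "accessions_tsv", "ref_te_gff3")
      miss <- req[!vapply(req, function(k)
        !is.null(cfg$inputs[[k]]) && file.exists(cfg$inputs[[k]]), TRUE)]
      if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
      accessions <- read.table(cfg$inputs$accessions_tsv, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
      paf_paths <- setNames(file.path(cfg$inputs$paf_dir,
                                      paste0(accessions$accession, ".paf")),
                            accessions$accession)
      fa_paths <- setNames(file.path(cfg$inputs$fasta_dir,
                                     paste0(accessions$accession, ".fa")),
                           accessions$accession)
      te_paths <- setNames(file.path(cfg$inputs$te_dir,
                                     paste0(accessions$accession, ".te.gff3")),
                           accessions$accession)
      missing_paf <- paf_paths[!file.exists(paf_paths)]
      if (length(missing_paf)) {
        stop("missing PAF file(s): ", paste(missing_paf, collapse = ", "))
      }
      list(accessions = accessions, paf_paths = paf_paths,
           fa_paths = fa_paths, te_paths = te_paths)
    })
    accessions <- loaded$accessions
    paf_paths <- loaded$paf_paths
    fa_paths <- loaded$fa_paths
    te_paths <- loaded$te_paths
    ref_fa <- cfg$inputs$ref_fa
    ref_te_path <- cfg$inputs$ref_te_gff3
    het_calls <- NULL
    bundle <- NULL
    seed <- cfg$seed %||% 1L
  }

  thr <- cfg$thresholds
  an <- cfg$analyses
  ref_seqs <- Biostrings::readDNAStringSet(ref_fa)
  names(ref_seqs) <- sub("\\s.*$", "", names(ref_seqs))
  ref_te <- read_te_gff3(ref_te_path, genome = "reference")

  # --- stage: call --------------------------------------------------------
  called <- run_stage("call", {
    out <- list()
    for (a in accessions$accession) {
      paf <- read_paf(paf_paths[[a]])
      q <- Biostrings::readDNAStringSet(fa_paths[[a]])
      names(q) <- sub("\\s.*$", "", names(q))
      ex <- extract_pavs(paf, q, ref_seqs, accession = a,
                         min_len = thr$min_pav_len)
      q_te <- read_te_gff3(te_paths[[a]], genome = a)
      pavs <- classify_te_variations(ex$pavs, q_te, ref_te,
                                     min_te_frac = thr$min_te_frac)
      out[[a]] <- list(pavs = pavs, coverage = ex$coverage)
    }
    out
  })
  all_pavs <- do.call(rbind, lapply(called, `[[`, "pavs"))
  te_calls <- all_pavs[!is.na(all_pavs$is_te_variation) &
                         all_pavs$is_te_variation, , drop = FALSE]
  write.table(all_pavs[, setdiff(names(all_pavs), c("te_units", "sequence"))],
              file.path(work, "pavs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- stage: merge/genotype/polarize ------------------------------------
  map <- run_stage("merge", {
    merge_loci(te_calls, breakpoint_tol = thr$breakpoint_tol,
               reciprocal_overlap = thr$reciprocal_overlap,
               length_ratio = thr$length_ratio)
  })
  gm <- run_stage("genotype", {
    genotype_matrix(map, lapply(called, `[[`, "coverage"), accessions,
                    het_calls = het_calls, tol = thr$genotype_tol)
  })
  polarized <- run_stage("polarize", polarize_loci(gm))
  gm$loci$polarity <- polarized$polarity
  gm$loci$dte <- polarized$dte
  write_genotype_matrix(gm, file.path(work, "matrix.tsv"))
  export_dte_vcf(polarized, gm, file.path(work, "dte.vcf"))
  loci_out <- polarized
  loci_out$unit_families <- vapply(loci_out$unit_families,
                                   paste, "", collapse = ",")
  write.table(loci_out, file.path(work, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- stage: popgen ------------------------------------------------------
  subpops <- unique(accessions$subpop[!(accessions$is_outgroup %||%
                                          (accessions$subpop == "outgroup"))])
  counts <- list(
    n_pavs = nrow(all_pavs), n_te_variations = nrow(te_calls),
    n_loci = nrow(gm$loci), n_dte = sum(polarized$dte),
    n_dte_ins = sum(polarized$dte & polarized$polarity == "INS"),
    n_dte_del = sum(polarized$dte & polarized$polarity == "DEL"),
    n_unpolarized = sum(polarized$polarity == "unpolarized"))

  run_stage("popgen", {
    dte <- polarized[polarized$dte, , drop = FALSE]
    spectrum <- ins_del_ratio_by_frequency(dte, bin_width = an$spectrum_bin)
    write.table(spectrum, file.path(work, "spectrum.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(subpops) >= 2L) {
      p1 <- accessions$accession[accessions$subpop == subpops[1]]
      p2 <- accessions$accession[accessions$subpop == subpops[2]]
      fst <- locus_fst(gm, p1, p2)
      write.table(fst, file.path(work, "fst.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (sum(!is.na(fst$fst)) >= 20L) {
        out <- fst_outliers(fst, top_quantile = an$top_quantile)
        write.table(out$results, file.path(work, "fst_outliers.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        fam <- family_enrichment(out$selected, gm$loci)
        write.table(fam, file.path(work, "family_enrichment.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        counts$n_selected_dte <- sum(out$results$selected & polarized$dte)
      }
    }
    chrom_sizes <- setNames(Biostrings::width(ref_seqs), names(ref_seqs))
    wins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
      starts <- seq(0L, max(chrom_sizes[[ch]] - 1L, 0L), by = an$window)
      data.frame(chrom = ch, start = starts,
                 end = pmin(starts + an$window, chrom_sizes[[ch]]),
                 stringsAsFactors = FALSE)
    }))
    pi_w <- windowed_pi(dte, wins)
    write.table(pi_w, file.path(work, "pi_windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(bundle) && !is.null(bundle$snps) &&
        nrow(bundle$snps$variants) && length(subpops) >= 2L) {
      p1 <- accessions$accession[accessions$subpop == subpops[1]]
      p2 <- accessions$accession[accessions$subpop == subpops[2]]
      sw <- snp_selective_windows(bundle$snps$variants, bundle$snps$dosage,
                                  p1, p2, chrom_sizes, window = an$window,
                                  top_quantile = an$top_quantile)
      write.table(sw$windows, file.path(work, "snp_windows.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (nrow(sw$selective) && nrow(dte)) {
        enr <- permutation_enrichment(
          data.frame(chrom = dte$ref_chrom, pos = dte$ref_start),
          sw$windows, sw$windows$selective, n_perm = an$n_perm, seed = seed)
        jsonlite::write_json(enr[c("observed", "p", "n_perm", "seed")],
                             file.path(work, "enrichment.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    if (!is.null(bundle)) {
      ctx <- genic_context(dte, bundle$gene_models, flank = an$genic_flank)
      write.table(ctx$categories, file.path(work, "genic_context.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(ctx$gene_counts, file.path(work, "gene_dte_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(gm$states) >= 2L && ncol(gm$states) >= 4L) {
      pca <- dte_pca(gm, n_pcs = 4L)
      write.table(data.frame(accession = rownames(pca$scores),
                             round(pca$scores, 6)),
                  file.path(work, "pca.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      D <- genotype_distance(gm)
      nj_tree(D, file = file.path(work, "tree.nwk"))
    }
    invisible(NULL)
  })

  # --- stage: association -------------------------------------------------
  n_expr_acc <- if (!is.null(bundle) && !is.null(bundle$expression)) {
    length(intersect(colnames(gm$states), colnames(bundle$expression)))
  } else 0L
  if (n_expr_acc >= 20L) {
    run_stage("eqtl", {
      dte <- polarized[polarized$dte, , drop = FALSE]
      if (nrow(dte) >= 1L) {
        dd <- state_to_dosage(gm$states[dte$locus_id, , drop = FALSE])
        vp <- data.frame(variant_id = dte$locus_id, chrom = dte$ref_chrom,
                         pos = dte$ref_start, class = "dTE",
                         stringsAsFactors = FALSE)
        scan <- eqtl_scan(dd, vp, bundle$expression, bundle$gene_models,
                          cis_flank = an$cis_flank)
        write.table(scan$genes, file.path(work, "eqtl_genes.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        counts$n_egenes <- length(scan$egenes)
      }
    })
  }
  if (!is.null(bundle) && !is.null(bundle$phenotype)) {
    run_stage("gwas", {
      dte <- polarized[polarized$dte, , drop = FALSE]
      if (nrow(dte) >= 2L) {
        dd <- state_to_dosage(gm$states[dte$locus_id, , drop = FALSE])
        vp <- data.frame(variant_id = dte$locus_id, chrom = dte$ref_chrom,
                         pos = dte$ref_start, stringsAsFactors = FALSE)
        y <- setNames(bundle$phenotype$value, bundle$phenotype$accession)
        scan <- gwas_scan(dd, vp, y, n_pcs = an$n_pcs)
        write.table(scan$results, file.path(work, "gwas.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        counts$n_gwas_hits <- length(scan$significant)
      }
    })
  }

  manifest <- list(
    config_hash = cfg_hash, seed = seed,
    counts = counts,
    versions = list(panTE = as.character(utils::packageVersion("panTE")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list.files(work, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(work, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # promote: the run completed, move outputs out of quarantine
  for (f in list.files(work, recursive = FALSE, all.files = FALSE)) {
    file.rename(file.path(work, f), file.path(outdir, f))
  }
  unlink(work, recursive = TRUE)
  manifest
}
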