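# Shared fixtures. The sequence-level bundle is expensive, so it is built
# once per session and memoized; everything else is cheap and built inline.

.fixture_env <- new.env(parent = emptyenv())

# small sequence-level bundle: 2 subpops x 10 + 2 outgroups, 100 events
get_bundle7 <- function() {
  if (is.null(.fixture_env$bundle7)) {
    cfg <- sim_config(seed = 7, ref_length = 2e5, n_chromosomes = 2,
                      n_genes = 10, n_ingroup = c(pop1 = 10, pop2 = 10),
                      n_outgroup = 2, n_te_events = 100, n_snps = 200,
                      na_rate = 0)
    .fixture_env$bundle7 <- simulate_population(
      cfg, dir = file.path(tempdir(), "pante_bundle7"))
  }
  .fixture_env$bundle7
}

# run the call -> classify -> merge -> genotype chain over a bundle
call_bundle <- function(b) {
  ref <- Biostrings::readDNAStringSet(b$paths$ref_fa)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref_te <- read_te_gff3(b$paths$ref_te_gff3, genome = "reference")
  called <- list()
  for (a in b$accessions$accession) {
    paf <- read_paf(b$paths$paf[[a]])
    q <- Biostrings::readDNAStringSet(b$paths$genome_fa[[a]])
    names(q) <- sub("\\s.*$", "", names(q))
    ex <- extract_pavs(paf, q, ref, accession = a)
    q_te <- read_te_gff3(b$paths$te_gff3[[a]], genome = a)
    called[[a]] <- list(
      pavs = classify_te_variations(ex$pavs, q_te, ref_te),
      coverage = ex$coverage)
  }
  all_pavs <- do.call(rbind, lapply(called, `[[`, "pavs"))
  map <- merge_loci(all_pavs[!is.na(all_pavs$is_te_variation) &
                               all_pavs$is_te_variation, ])
  gm <- genotype_matrix(map, lapply(called, `[[`, "coverage"),
                        b$accessions, het_calls = b$het_calls)
  list(called = called, all_pavs = all_pavs, map = map, gm = gm,
       ref = ref, ref_te = ref_te)
}

get_chain7 <- function() {
  if (is.null(.fixture_env$chain7)) {
    .fixture_env$chain7 <- call_bundle(get_bundle7())
  }
  .fixture_env$chain7
}

# match truth events to called loci; returns row indices of loci per event
match_truth_loci <- function(events, loci) {
  key_t <- paste(events$chrom, events$ref_start, events$pav_type)
  key_l <- paste(loci$ref_chrom, loci$ref_start, loci$pav_type)
  match(key_t, key_l)
}

# a bundle-like object over genotype-level simulation, enough for
# simulate_expression()/simulate_phenotype() and the association scans
make_assoc_bundle <- function(n_per_subpop = c(pop1 = 100L, pop2 = 100L),
                              n_loci = 40L, n_genes = 10L,
                              chrom_length = 2e6, seed = 1L) {
  sim <- simulate_genotypes(n_per_subpop = n_per_subpop, n_outgroup = 2L,
                            n_loci = n_loci, chrom_length = chrom_length,
                            seed = seed)
  dose <- state_to_dosage(sim$states)
  events <- data.frame(event_id = sim$loci$locus_id,
                       chrom = sim$loci$ref_chrom,
                       ref_start = sim$loci$ref_start,
                       ref_end = pmax(sim$loci$ref_end, sim$loci$ref_start),
                       stringsAsFactors = FALSE)
  set.seed(seed + 1000L)
  gpos <- sort(sample.int(as.integer(chrom_length) - 5000L, n_genes))
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = "chr1", start = gpos, end = gpos + 3000L,
                      strand = "+", stringsAsFactors = FALSE)
  dir <- tempfile("assoc_bundle_")
  dir.create(dir)
  structure(list(
    dir = dir, accessions = sim$accessions, events = events, dose = dose,
    states = sim$states, loci = sim$loci, truth = sim$truth,
    gene_models = list(genes = genes,
                       features = genes[0, c("gene_id", "chrom", "start",
                                             "end", "strand")]),
    paths = list(expression = file.path(dir, "expression.tsv"),
                 eqtl_truth = file.path(dir, "eqtl.tsv"),
                 phenotype = file.path(dir, "phenotype.tsv"),
                 trait_truth = file.path(dir, "trait.tsv"))),
    class = "pante_bundle")
}

# dosage matrix of a genotype object restricted to ingroup accessions
ingroup_dosage <- function(sim) {
  ing <- sim$accessions$accession[!sim$accessions$is_outgroup]
  state_to_dosage(sim$states[, ing, drop = FALSE])
}
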