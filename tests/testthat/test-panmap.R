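# Locus merging, genotyping, polarization and carrier frequencies.

mk_calls <- function(pos, len, type = "ref_insertion",
                     acc = paste0("a", seq_along(pos))) {
  data.frame(accession = acc, ref_chrom = "chr1", ref_start = pos,
             ref_end = if (type == "ref_deletion") pos + len else pos,
             pav_type = type, length = len,
             family = "RLG_1", superfamily = "Gypsy", n_units = 1L,
             te_fraction = 1, is_te_variation = TRUE,
             stringsAsFactors = FALSE)
}

test_that("insertions within tolerance and length ratio merge into one locus", {
  calls <- mk_calls(c(1000L, 1005L), c(300L, 310L))
  map <- merge_loci(calls)
  expect_equal(nrow(map$loci), 1L)
  expect_equal(map$loci$length, 310L)  # representative = longest member
  # breakpoint apart: two loci
  calls2 <- mk_calls(c(1000L, 1030L), c(300L, 310L))
  expect_equal(nrow(merge_loci(calls2)$loci), 2L)
  # length ratio too small: two loci
  calls3 <- mk_calls(c(1000L, 1005L), c(300L, 390L))
  expect_equal(nrow(merge_loci(calls3)$loci), 2L)
})

test_that("deletions merge by reciprocal overlap", {
  calls <- mk_calls(c(100L, 120L), c(300L, 300L), type = "ref_deletion")
  # overlaps 280/300 both >= 0.8
  expect_equal(nrow(merge_loci(calls)$loci), 1L)
  calls2 <- mk_calls(c(100L, 180L), c(300L, 300L), type = "ref_deletion")
  # overlap 220/300 < 0.8
  expect_equal(nrow(merge_loci(calls2)$loci), 2L)
})

test_that("a single accession's callset passes through unchanged", {
  calls <- mk_calls(c(500L, 5000L, 9000L), c(100L, 200L, 300L),
                    acc = rep("a1", 3))
  map <- merge_loci(calls)
  expect_equal(nrow(map$loci), 3L)
  expect_equal(map$loci$ref_start, c(500L, 5000L, 9000L))
  expect_equal(map$loci$length, c(100L, 200L, 300L))
})

test_that("merging matches a brute-force single-linkage oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    pos <- sort(sample.int(2000L, n))
    len <- sample(60:400, n, replace = TRUE)
    type <- sample(c("ref_insertion", "ref_deletion"), 1)
    calls <- mk_calls(pos, len, type = type,
                      acc = paste0("a", sample(1:5, n, replace = TRUE)))
    map <- merge_loci(calls)
    linked <- if (type == "ref_insertion") {
      function(i, j) abs(pos[i] - pos[j]) <= 25 &&
        min(len[i], len[j]) / max(len[i], len[j]) >= 0.8
    } else {
      function(i, j) {
        ov <- max(0, min(pos[i] + len[i], pos[j] + len[j]) - max(pos[i], pos[j]))
        ov / len[i] >= 0.8 && ov / len[j] >= 0.8
      }
    }
    comp <- oracle_single_linkage(n, linked)
    expect_equal(nrow(map$loci), length(unique(comp)))
    # membership partition matches
    got <- map$members
    got_comp <- got$locus_id[order(got$row)]
    expect_equal(length(unique(paste(comp, got_comp))), length(unique(comp)))
  }
})

test_that("genotyping assigns 1/1 to members, 0/0 to covered, NA otherwise", {
  calls <- mk_calls(1000L, 300L, acc = "a1")
  map <- merge_loci(calls)
  cov <- list(
    a1 = data.frame(chrom = "chr1", start = 0L, end = 5000L),
    a2 = data.frame(chrom = "chr1", start = 0L, end = 5000L),
    a3 = data.frame(chrom = "chr1", start = 0L, end = 900L))
  acc <- data.frame(accession = c("a1", "a2", "a3"),
                    subpop = c("p1", "p1", "p2"), is_outgroup = FALSE)
  gm <- genotype_matrix(map, cov, acc)
  expect_equal(unname(gm$states[1, ]), c("1/1", "0/0", NA))
  # het override from the external table
  het <- data.frame(accession = "a2", chrom = "chr1", ref_pos = 1002L)
  gm2 <- genotype_matrix(map, cov, acc, het_calls = het)
  expect_equal(unname(gm2$states[1, "a2"]), "0/1")
  # an accession missing from coverage warns and yields an all-NA column
  expect_warning(gm3 <- genotype_matrix(map, cov[c("a1", "a2")], acc),
                 "no coverage")
  expect_true(all(is.na(gm3$states[, "a3"])))
})

test_that("coverage must span the breakpoint region with tolerance", {
  calls <- mk_calls(1000L, 300L, acc = "a1")
  map <- merge_loci(calls)
  acc <- data.frame(accession = c("a1", "a2"), subpop = "p1",
                    is_outgroup = FALSE)
  # coverage ends 10 bp after the insertion point: not 0/0
  cov <- list(a1 = data.frame(chrom = "chr1", start = 0L, end = 5000L),
              a2 = data.frame(chrom = "chr1", start = 0L, end = 1010L))
  gm <- genotype_matrix(map, cov, acc, tol = 25L)
  expect_true(is.na(gm$states[1, "a2"]))
  cov$a2$end <- 1025L
  gm <- genotype_matrix(map, cov, acc, tol = 25L)
  expect_equal(unname(gm$states[1, "a2"]), "0/0")
})

mk_gm <- function(states, pav_type = "ref_insertion",
                  outgroups = grep("^o", colnames(states), value = TRUE)) {
  loci <- data.frame(locus_id = rownames(states), ref_chrom = "chr1",
                     ref_start = seq_len(nrow(states)) * 1000L,
                     ref_end = seq_len(nrow(states)) * 1000L,
                     pav_type = pav_type, length = 100L, family = "RLG_1",
                     n_units = 1L, stringsAsFactors = FALSE)
  loci$unit_families <- as.list(loci$family)
  acc <- data.frame(accession = colnames(states),
                    subpop = ifelse(colnames(states) %in% outgroups,
                                    "outgroup", "p1"),
                    is_outgroup = colnames(states) %in% outgroups,
                    stringsAsFactors = FALSE)
  structure(list(states = states, loci = loci, accessions = acc),
            class = "pante_genotypes")
}

test_that("polarization follows the outgroup consensus rule", {
  st <- rbind(
    L1 = c(a1 = "1/1", a2 = "0/0", a3 = "0/0", o1 = "0/0", o2 = "0/0"),
    L2 = c(a1 = "0/0", a2 = "1/1", a3 = "0/0", o1 = "1/1", o2 = "1/1"),
    L3 = c(a1 = "1/1", a2 = "1/1", a3 = "1/1", o1 = "0/0", o2 = "0/0"),
    L4 = c(a1 = "1/1", a2 = "0/0", a3 = "0/0", o1 = "0/0", o2 = "1/1"))
  pol <- suppressMessages(polarize_loci(mk_gm(st)))
  # outgroups 0/0, ingroup mixed: dTE, derived gained the TE -> INS
  expect_equal(pol$polarity[1], "INS")
  expect_true(pol$dte[1])
  # outgroups 1/1 on a ref_insertion locus: ancestral carries the TE -> DEL
  expect_equal(pol$polarity[2], "DEL")
  expect_true(pol$dte[2])
  # derived-fixed: polarized but not a dTE (no ancestral-state ingroup)
  expect_equal(pol$polarity[3], "INS")
  expect_false(pol$dte[3])
  # tied outgroups: unpolarized
  expect_equal(pol$polarity[4], "unpolarized")
  expect_false(pol$dte[4])
})

test_that("polarity flips with PAV type: deletion alleles lack the TE", {
  st <- rbind(L1 = c(a1 = "1/1", a2 = "0/0", o1 = "0/0"),
              L2 = c(a1 = "1/1", a2 = "0/0", o1 = "1/1"))
  pol <- polarize_loci(mk_gm(st, pav_type = "ref_deletion"))
  # outgroup 0/0 (has the reference TE): derived allele deleted it
  expect_equal(pol$polarity[1], "DEL")
  # outgroup 1/1 (lacks it): derived allele gained it
  expect_equal(pol$polarity[2], "INS")
})

test_that("heterozygous ingroup accessions count as derived carriers", {
  st <- rbind(L1 = c(a1 = "0/1", a2 = "0/0", a3 = NA, a4 = "0/0",
                     o1 = "0/0"))
  pol <- polarize_loci(mk_gm(st))
  expect_true(pol$dte[1])
  expect_equal(pol$n_derived, 1L)
  expect_equal(carrier_frequency(pol), 1 / 3)
  st2 <- rbind(L1 = c(a1 = "1/1", a2 = "0/0", a3 = "0/0", a4 = "0/0",
                      o1 = "0/0"))
  expect_equal(carrier_frequency(polarize_loci(mk_gm(st2))), 0.25)
})

test_that("polarization is idempotent and accession-order invariant", {
  b <- get_bundle7()
  ch <- get_chain7()
  pol1 <- polarize_loci(ch$gm)
  pol2 <- polarize_loci(ch$gm)
  expect_identical(pol1, pol2)
  gm_shuf <- ch$gm
  perm <- sample(ncol(gm_shuf$states))
  gm_shuf$states <- gm_shuf$states[, perm]
  gm_shuf$accessions <- gm_shuf$accessions[perm, ]
  pol3 <- polarize_loci(gm_shuf)
  expect_equal(pol3$polarity, pol1$polarity)
  expect_equal(pol3$dte, pol1$dte)
  expect_equal(pol3$carrier_freq, pol1$carrier_freq)
})

test_that("every locus falls in exactly one polarization class", {
  ch <- get_chain7()
  pol <- polarize_loci(ch$gm)
  cls <- locus_class(pol)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), nrow(pol))
})

test_that("called polarity and frequencies match truth on the simulated bundle", {
  b <- get_bundle7()
  ch <- get_chain7()
  pol <- polarize_loci(ch$gm)
  ord <- match_truth_loci(b$events, pol)
  expect_false(anyNA(ord))
  expect_equal(pol$polarity[ord], b$events$polarity)
  # carrier frequency within 3 binomial SE of the subpop-weighted truth
  ing <- b$accessions$accession[!b$accessions$is_outgroup]
  p_true <- (b$events$freq_pop1 * 10 + b$events$freq_pop2 * 10) / 20
  se <- sqrt(p_true * (1 - p_true) / 20)
  ok <- abs(pol$carrier_freq[ord] - p_true) <= pmax(3 * se, 0.15)
  # single binomial tail draws are expected over 100 loci
  expect_gte(mean(ok), 0.95)
})

test_that("NA genotyping rate tracks the simulated masking rate", {
  cfg <- sim_config(seed = 11, ref_length = 1e5, n_chromosomes = 1,
                    n_genes = 4, n_ingroup = c(pop1 = 8, pop2 = 8),
                    n_outgroup = 2, n_te_events = 50, n_snps = 50,
                    na_rate = 0.1)
  b <- simulate_population(cfg, dir = tempfile())
  ch <- call_bundle(b)
  ord <- match_truth_loci(b$events, ch$gm$loci)
  got <- ch$gm$states[ord[!is.na(ord)], colnames(b$expected_states)]
  exp <- b$expected_states[!is.na(ord), ]
  # non-NA states match truth exactly
  both <- !is.na(got) & !is.na(exp)
  expect_true(all(got[both] == exp[both]))
  # NA pattern matches the planted masking
  expect_equal(unname(is.na(got)), unname(is.na(exp)))
  # overall NA rate within 3 binomial SE of the configured 0.1
  n_cells <- length(got)
  expect_lt(abs(mean(is.na(got)) - 0.1), 3 * sqrt(0.1 * 0.9 / n_cells) + 0.02)
})
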