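# Population-genetic statistics against hand formulas and brute-force
# oracles.

test_that("landscape summary uses the population SD/CV convention", {
  ann <- do.call(rbind, lapply(c("g1", "g2", "g3"), function(g) {
    n <- c(g1 = 5L, g2 = 10L, g3 = 15L)[[g]]
    data.frame(genome = g, chrom = "chr1",
               start = seq(0L, by = 1000L, length.out = n),
               end = seq(0L, by = 1000L, length.out = n) + 100L,
               strand = "+", superfamily = "Gypsy", family = "RLG_1",
               intact = TRUE, stringsAsFactors = FALSE)
  }))
  ls <- landscape_summary(ann)
  expect_equal(ls$families$mean_count, 10)
  expect_equal(ls$families$sd_count, sqrt(mean((c(5, 10, 15) - 10)^2)))
  expect_equal(ls$families$cv, ls$families$sd_count / 10)
  # identical counts: CV 0
  ann2 <- ann
  ann2$genome <- rep(c("g1", "g2", "g3"), each = 10)
  ls2 <- landscape_summary(ann2)
  expect_equal(ls2$families$cv, 0)
  expect_error(landscape_summary(ann[ann$genome == "g1", ]), ">= 2")
})

test_that("pearson correlation matches hand values and cor.test", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  got <- pearson_correlation(x, c(2, 1, 4, 3))
  expect_equal(got$r, 0.6)
  ct <- cor.test(x, c(2, 1, 4, 3))
  expect_equal(got$p, ct$p.value)
  expect_true(pearson_correlation(c(1, 1, 1), c(1, 2, 3))$degenerate)
  # NA pairs are dropped
  got2 <- pearson_correlation(c(x, NA), c(2, 1, 4, 3, 10))
  expect_equal(got2$n, 4L)
})

test_that("pearson p-values are calibrated under the null", {
  set.seed(77)
  n_sig <- 0L
  n_sim <- 500L
  for (i in seq_len(n_sim)) {
    x <- rnorm(20); y <- rnorm(20)
    if (pearson_correlation(x, y)$p < 0.05) n_sig <- n_sig + 1L
  }
  ci <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(n_sig, ci[1])
  expect_lte(n_sig, ci[2])
})

test_that("INS/DEL ratio bins the frequency spectrum correctly", {
  pol <- data.frame(polarity = c(rep("INS", 10), rep("DEL", 5), "INS", "DEL"),
                    carrier_freq = c(rep(0.01, 15), 0.99, 0.52))
  tab <- ins_del_ratio_by_frequency(pol)
  expect_equal(nrow(tab), 20L)
  expect_equal(tab$ratio[1], 2)
  # a frequency of exactly 1 lands in the last bin
  expect_equal(tab$n_ins[20], 1L)
  # bin with INS but no DEL: NA ratio, bin retained
  expect_true(is.na(tab$ratio[20]))
  expect_equal(tab$n_del[11], 1L)
})

test_that("the INS/DEL ratio falls with frequency under the generative model", {
  sim <- simulate_genotypes(n_per_subpop = c(pop1 = 60L, pop2 = 60L),
                            n_outgroup = 2L, n_loci = 2000L,
                            chrom_length = 5e6, fraction_selected = 0,
                            seed = 311L)
  pol <- suppressMessages(polarize_loci(sim))
  tab <- ins_del_ratio_by_frequency(pol[pol$dte, ])
  occ <- which(tab$n_ins + tab$n_del >= 20 & !is.na(tab$ratio))
  rho <- suppressWarnings(cor(occ, tab$ratio[occ], method = "spearman"))
  expect_lte(rho, 0)
})

test_that("hudson_fst matches hand evaluation and the oracle on random draws", {
  expect_equal(hudson_fst(1, 10, 0, 10), 1)
  expect_equal(hudson_fst(0.5, 11, 0.5, 11), -0.1)
  expect_error(hudson_fst(1.2, 10, 0.5, 10), "frequencies")
  expect_error(hudson_fst(0.5, 1, 0.5, 10), "sample sizes")
  set.seed(17)
  for (i in 1:1000) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(2:200, 1); n2 <- sample(2:200, 1)
    expect_equal(hudson_fst(p1, n1, p2, n2), oracle_hudson(p1, n1, p2, n2),
                 tolerance = 1e-12)
  }
})

test_that("fst outlier selection counts, ties and order invariance", {
  res <- data.frame(locus_id = sprintf("L%03d", 1:100),
                    fst = seq(0.005, 0.995, length.out = 100))
  out <- fst_outliers(res, top_quantile = 0.05)
  expect_equal(length(out$selected), 5L)
  # all-tied: everything selected at the threshold
  res_t <- data.frame(locus_id = sprintf("L%03d", 1:30), fst = 0.4)
  expect_equal(length(fst_outliers(res_t)$selected), 30L)
  # order invariance
  perm <- sample(nrow(res))
  out2 <- fst_outliers(res[perm, ], top_quantile = 0.05)
  expect_setequal(out2$selected, out$selected)
  expect_error(fst_outliers(res[1:10, ]), ">= 20")
})

test_that("rank percentile is the fraction of strictly greater FST values", {
  gm <- simulate_genotypes(n_per_subpop = c(pop1 = 30L, pop2 = 30L),
                           n_outgroup = 2L, n_loci = 50L, seed = 5L)
  p1 <- gm$accessions$accession[gm$accessions$subpop == "pop1"]
  p2 <- gm$accessions$accession[gm$accessions$subpop == "pop2"]
  fst <- locus_fst(gm, p1, p2)
  def <- !is.na(fst$fst)
  for (k in sample(which(def), 5)) {
    expect_equal(fst$rank_percentile[k],
                 mean(fst$fst[def] > fst$fst[k]))
  }
  # per-locus FST equals a direct evaluation from allele counts
  k <- which(def)[1]
  d1 <- state_to_dosage(gm$states[k, p1]); d2 <- state_to_dosage(gm$states[k, p2])
  o <- oracle_hudson(sum(d1, na.rm = TRUE) / (2 * sum(!is.na(d1))),
                     2 * sum(!is.na(d1)),
                     sum(d2, na.rm = TRUE) / (2 * sum(!is.na(d2))),
                     2 * sum(!is.na(d2)))
  expect_equal(fst$fst[k], o, tolerance = 1e-12)
})

test_that("windowed SNP FST aggregates by ratio of averages", {
  set.seed(23)
  n_snp <- 60L
  pos <- sort(sample.int(4e5, n_snp))
  chrom <- rep("chr1", n_snp)
  d <- matrix(rbinom(n_snp * 40, 2, 0.4), n_snp,
              dimnames = list(sprintf("s%02d", 1:n_snp),
                              c(paste0("a", 1:20), paste0("b", 1:20))))
  res <- snp_selective_windows(data.frame(chrom = chrom, pos = pos), d,
                               paste0("a", 1:20), paste0("b", 1:20),
                               c(chr1 = 4e5), window = 1e5)
  expect_equal(nrow(res$windows), 4L)
  # oracle: accumulate numerators and denominators per window by hand
  for (w in seq_len(nrow(res$windows))) {
    rows <- which(pos >= res$windows$start[w] & pos < res$windows$end[w])
    num <- den <- 0
    for (k in rows) {
      x1 <- d[k, 1:20]; x2 <- d[k, 21:40]
      p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
      num <- num + (p1 - p2)^2 - p1 * (1 - p1) / 39 - p2 * (1 - p2) / 39
      den <- den + p1 * (1 - p2) + p2 * (1 - p1)
    }
    expect_equal(res$windows$fst[w], num / den, tolerance = 1e-12)
  }
  # fixed differences: every window at 1
  d2 <- d; d2[, 1:20] <- 2; d2[, 21:40] <- 0
  res2 <- snp_selective_windows(data.frame(chrom = chrom, pos = pos), d2,
                                paste0("a", 1:20), paste0("b", 1:20),
                                c(chr1 = 4e5), window = 1e5)
  expect_true(all(abs(res2$windows$fst - 1) < 1e-12))
  # 40 windows, top 5% -> 2 selective
  pos40 <- seq(0L, by = 1e5, length.out = 40) + 50L
  d3 <- matrix(rbinom(40 * 40, 2, 0.5), 40,
               dimnames = list(NULL, colnames(d)))
  res3 <- snp_selective_windows(data.frame(chrom = "chr1", pos = pos40), d3,
                                paste0("a", 1:20), paste0("b", 1:20),
                                c(chr1 = 4e6), window = 1e5)
  expect_equal(sum(res3$windows$selective), 2L)
})

test_that("permutation enrichment: minimal p, determinism, calibration", {
  wins <- data.frame(chrom = "chr1", start = seq(0L, by = 1000L,
                                                 length.out = 200),
                     end = seq(1000L, by = 1000L, length.out = 200))
  selective <- c(rep(TRUE, 5), rep(FALSE, 195))
  # all dTEs inside selective windows: minimal attainable p
  dte <- data.frame(chrom = "chr1", pos = c(100, 1100, 2100, 3100, 4100))
  enr <- permutation_enrichment(dte, wins, selective, n_perm = 500,
                                seed = 4)
  expect_equal(enr$p, 1 / 501)
  # identical seed gives the identical null vector
  enr2 <- permutation_enrichment(dte, wins, selective, n_perm = 500,
                                 seed = 4)
  expect_identical(enr$null_means, enr2$null_means)
  expect_error(permutation_enrichment(dte, wins[1:3, ], rep(TRUE, 5),
                                      n_perm = 10, seed = 1),
               "more selective")
})

test_that("family enrichment matches the exact hypergeometric oracle", {
  # table (10,10; 10,70): odds in favour of the family
  loci <- data.frame(locus_id = sprintf("L%03d", 1:100),
                     family = c(rep("fam1", 20), rep("fam2", 80)),
                     stringsAsFactors = FALSE)
  selected <- c(sprintf("L%03d", 1:10), sprintf("L%03d", 21:30))
  fe <- family_enrichment(selected, loci)
  f1 <- fe[fe$family == "fam1", ]
  expect_equal(f1$n_selected, 10L)
  expect_equal(f1$fold, (10 / 20) / (20 / 100))
  expect_equal(f1$p, oracle_fisher_p(10, 10, 10, 70), tolerance = 1e-12)
  expect_equal(f1$p, fisher.test(matrix(c(10, 10, 10, 70), 2,
                                        byrow = TRUE))$p.value)
  # equal proportions: fold 1
  sel_prop <- c(sprintf("L%03d", 1:4), sprintf("L%03d", 21:36))
  fe2 <- family_enrichment(sel_prop, loci)
  expect_equal(fe2$fold, c(1, 1))
  # random tables vs the oracle
  set.seed(41)
  for (i in 1:200) {
    m <- sample(1:30, 1); n <- sample(1:50, 1); k <- sample(1:(m + n), 1)
    arange <- max(0, k - n):min(k, m)
    a <- if (length(arange) == 1L) arange else sample(arange, 1)
    loci_r <- data.frame(
      locus_id = sprintf("R%03d", seq_len(m + n)),
      family = c(rep("f", m), rep("g", n)), stringsAsFactors = FALSE)
    sel_r <- c(sprintf("R%03d", seq_len(a)),
               sprintf("R%03d", m + seq_len(k - a)))
    fe_r <- family_enrichment(sel_r, loci_r)
    expect_equal(fe_r$p[fe_r$family == "f"],
                 oracle_fisher_p(a, k - a, m - a, n - (k - a)),
                 tolerance = 1e-9)
  }
})

test_that("presence/absence pi equals the brute-force pairwise mean", {
  expect_equal(locus_pi(c(1, 0, 0, 0)), 0.5)
  expect_equal(locus_pi(c(1, 0, 0, 0)), oracle_pi_pairs(c(1, 0, 0, 0)))
  expect_equal(locus_pi(c(0, 0, 0)), 0)
  expect_true(is.na(locus_pi(c(1, NA, NA))))
  set.seed(53)
  for (i in 1:200) {
    v <- rbinom(sample(2:30, 1), 1, runif(1))
    expect_equal(locus_pi(v), oracle_pi_pairs(v), tolerance = 1e-12)
  }
})

test_that("windowed pi averages per-locus values within windows", {
  pol <- data.frame(locus_id = c("L1", "L2", "L3"), ref_chrom = "chr1",
                    ref_start = c(100L, 900L, 150000L),
                    carrier_freq = c(0.25, 0.5, 0.1),
                    n_derived = c(1L, 2L, 1L), n_ancestral = c(3L, 2L, 9L))
  wins <- data.frame(chrom = "chr1", start = c(0L, 100000L),
                     end = c(100000L, 200000L))
  got <- windowed_pi(pol, wins)
  pi1 <- 2 * 0.25 * 0.75 * 4 / 3
  pi2 <- 2 * 0.5 * 0.5 * 4 / 3
  pi3 <- 2 * 0.1 * 0.9 * 10 / 9
  expect_equal(got$pi, c(mean(c(pi1, pi2)), pi3))
  expect_equal(got$n_loci, c(2L, 1L))
})

test_that("max LD r2 matches the hand Pearson oracle and the flank boundary", {
  x <- c(a = 0, b = 0, c = 1, d = 2)
  y <- rbind(v1 = c(0, 1, 1, 2), v2 = c(0, 0, 1, 2),
             v3 = c(2, 2, 1, 0))
  colnames(y) <- names(x)
  vp <- data.frame(chrom = "chr1", pos = c(1000L, 50000L, 50001L))
  got <- max_ld_r2(x, y, vp, "chr1", 0L, flank = 50000L)
  # v3 at 50.001 kb is outside the flank
  expect_equal(length(got$r2), 2L)
  expect_equal(unname(got$r2["v1"]), 8 / 11)
  expect_equal(unname(got$r2["v2"]), 1)
  expect_equal(got$max_r2, 1)
  # identical dosages: r2 = 1; monomorphic partner: NA
  y2 <- rbind(v1 = c(1, 1, 1, 1)); colnames(y2) <- names(x)
  got2 <- max_ld_r2(x, y2, data.frame(chrom = "chr1", pos = 0L), "chr1", 0L)
  expect_true(is.na(got2$max_r2))
})

test_that("genic context assigns by containing feature and largest overlap", {
  gmod <- list(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       start = c(10000L, 40000L), end = c(13000L, 43000L),
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    features = data.frame(
      gene_id = c("g1", "g1", "g1", "g2"), chrom = "chr1",
      start = c(10000L, 11000L, 11200L, 40000L),
      end = c(11000L, 11200L, 13000L, 43000L),
      strand = c("+", "+", "+", "-"),
      type = c("CDS", "intron", "CDS", "CDS"), stringsAsFactors = FALSE))
  mk_loci <- function(s, e) {
    data.frame(locus_id = "L1", ref_chrom = "chr1", ref_start = s,
               ref_end = e, stringsAsFactors = FALSE)
  }
  ctx <- function(s, e = s) genic_context(mk_loci(s, e), gmod)$categories$category
  # insertion point 1.5 kb upstream of a + gene: promoter
  expect_equal(ctx(8500L), "promoter")
  # 3 kb upstream: intergenic
  expect_equal(ctx(7000L), "intergenic")
  # promoter of a - strand gene lies downstream in coordinates
  expect_equal(ctx(44000L), "promoter")
  expect_equal(ctx(38500L), "downstream")
  # span with 60 bp CDS and 140 bp intron: intron wins by overlap
  expect_equal(ctx(10940L, 11140L), "intron")
  # span with larger CDS overlap: CDS
  expect_equal(ctx(10800L, 11100L), "CDS")
  # tie broken CDS > intron
  expect_equal(ctx(10900L, 11100L), "CDS")
})

test_that("per-gene counts and the 0/1/>=2 distribution are consistent", {
  gmod <- list(
    genes = data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                       start = c(1e4, 5e4, 9e4), end = c(1.3e4, 5.3e4, 9.3e4),
                       strand = "+", stringsAsFactors = FALSE),
    features = data.frame(gene_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), type = character(0)))
  loci <- data.frame(locus_id = c("L1", "L2", "L3"), ref_chrom = "chr1",
                     ref_start = c(11000L, 11500L, 48500L),
                     ref_end = c(11000L, 11500L, 48500L),
                     stringsAsFactors = FALSE)
  ctx <- genic_context(loci, gmod)
  expect_equal(ctx$gene_counts$n_dte, c(2L, 1L, 0L))
  expect_equal(unname(ctx$count_distribution), c(1L, 1L, 1L))
  expect_equal(sum(ctx$count_distribution), 3L)
})

test_that("PCA separates simulated subpopulations", {
  sim <- simulate_genotypes(n_per_subpop = c(pop1 = 25L, pop2 = 25L),
                            n_outgroup = 2L, n_loci = 300L,
                            fraction_selected = 0.3, selected_margin = 0.8,
                            seed = 61L)
  ing <- sim$accessions[!sim$accessions$is_outgroup, ]
  gm_ing <- structure(list(states = sim$states[, ing$accession],
                           loci = sim$loci, accessions = ing),
                      class = "pante_genotypes")
  pca <- dte_pca(gm_ing, n_pcs = 2L)
  pc1 <- pca$scores[, 1]
  grp <- ing$subpop
  # silhouette of the PC1 split
  sil <- vapply(seq_along(pc1), function(i) {
    own <- setdiff(which(grp == grp[i]), i)
    a <- mean(abs(pc1[i] - pc1[own]))
    b <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.8)
})

test_that("neighbor joining recovers an additive 5-taxon tree exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6,E:7);")
  D <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(D)
  expect_equal(ape::Ntip(nj), 5L)
  Dhat <- ape::cophenetic.phylo(nj)
  expect_equal(Dhat[rownames(D), colnames(D)], D, tolerance = 1e-10)
  f <- tempfile(fileext = ".nwk")
  nj_tree(D, file = f)
  expect_true(ape::Ntip(ape::read.tree(f)) == 5L)
})

test_that("duplicate accessions sit at zero distance and as siblings", {
  st <- rbind(L1 = c(a1 = "1/1", a2 = "1/1", a3 = "0/0", a4 = "0/1"),
              L2 = c(a1 = "0/0", a2 = "0/0", a3 = "1/1", a4 = "1/1"),
              L3 = c(a1 = "0/1", a2 = "0/1", a3 = "0/0", a4 = "1/1"))
  gm <- structure(list(states = st, loci = NULL,
                       accessions = data.frame(accession = colnames(st),
                                               subpop = "p")),
                  class = "pante_genotypes")
  D <- genotype_distance(gm)
  expect_equal(D["a1", "a2"], 0)
  # zero-distance rows end up as sibling leaves at patristic distance 0
  nj <- nj_tree(D)
  expect_equal(ape::cophenetic.phylo(nj)["a1", "a2"], 0, tolerance = 1e-12)
})

test_that("JC69 dating matches closed forms and scales with 1/mu", {
  same <- ltr_insertion_time("ACGTACGT", "ACGTACGT")
  expect_equal(same$years, 0)
  # p = 0.03 hand evaluation
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 3), rep("A", 97)), collapse = "")
  got <- ltr_insertion_time(s1, s2, mu = 1.3e-8)
  d_hand <- -0.75 * log(1 - 4 * 0.03 / 3)
  expect_equal(got$d, d_hand, tolerance = 1e-9)
  expect_equal(got$years, d_hand / (2 * 1.3e-8), tolerance = 1e-6)
  half <- ltr_insertion_time(s1, s2, mu = 0.65e-8)
  expect_equal(half$years, 2 * got$years)
  # gaps are dropped columnwise
  gap <- ltr_insertion_time("AC-GT", "ACCGT")
  expect_equal(gap$p, 0)
  # saturation flagged
  sat <- ltr_insertion_time(paste(rep("A", 100), collapse = ""),
                            paste(rep("C", 100), collapse = ""))
  expect_true(sat$saturated)
  expect_error(ltr_insertion_time("ACGT", "ACG"), "equal length")
})
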