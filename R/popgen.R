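# Population-genetic analyses over the polarized pan-TE map: landscape
# summaries, frequency spectra, Hudson FST selection scans, permutation
# enrichment against SNP-based selective windows, TE family enrichment,
# presence/absence diversity, LD with nearby small variants, genic context,
# population structure, and LTR insertion-age dating.

#' Cross-accession TE landscape summary
#'
#' Per-family copy-number statistics across accessions: the coefficient of
#' variation (population SD / mean of per-accession counts) and the SD of
#' per-accession family counts, plus per-accession totals and per-superfamily
#' total lengths. The population (divide-by-n) SD convention is used.
#'
#' @param annotations Data.frame of TE annotations across >= 2 genomes
#'   ([read_te_gff3()] format with a `genome` column).
#' @param genome_sizes Optional named vector of genome sizes (bases).
#' @return List with `families` (family, superfamily, mean_count, sd_count,
#'   cv, total_length), `accessions` (genome, n_te, te_length, genome_size).
#' @export
landscape_summary <- function(annotations, genome_sizes = NULL) {
  genomes <- unique(annotations$genome)
  if (length(genomes) < 2L) stop("need annotations for >= 2 genomes")
  fam_keys <- unique(annotations[, c("family", "superfamily")])
  counts <- table(factor(annotations$family, levels = fam_keys$family),
                  factor(annotations$genome, levels = genomes))
  fam <- data.frame(
    family = fam_keys$family, superfamily = fam_keys$superfamily,
    mean_count = apply(counts, 1L, mean),
    sd_count = apply(counts, 1L, pop_sd),
    stringsAsFactors = FALSE)
  fam$cv <- ifelse(fam$mean_count > 0, fam$sd_count / fam$mean_count, NA_real_)
  lens <- tapply(annotations$end - annotations$start, annotations$family, sum)
  fam$total_length <- as.integer(lens[fam$family])
  fam <- fam[fam$mean_count > 0, , drop = FALSE]
  accs <- data.frame(
    genome = genomes,
    n_te = as.integer(table(factor(annotations$genome, levels = genomes))),
    te_length = as.numeric(tapply(annotations$end - annotations$start,
                                  factor(annotations$genome, levels = genomes),
                                  sum)),
    stringsAsFactors = FALSE)
  accs$te_length[is.na(accs$te_length)] <- 0
  if (!is.null(genome_sizes)) accs$genome_size <- unname(genome_sizes[accs$genome])
  rownames(fam) <- rownames(accs) <- NULL
  list(families = fam, accessions = accs)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation on complete pairs, with the two-sided p-value
#' from the t distribution on n - 2 degrees of freedom. A zero-variance
#' vector yields `r = NA` with a `degenerate` flag rather than an error.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List with `r`, `p`, `n`, `degenerate`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n, degenerate = FALSE)
}

#' INS/DEL count ratio across the carrier-frequency spectrum
#'
#' Bins dTE loci by derived-carrier frequency into `[0, bin_width)`, ...,
#' `[1 - bin_width, 1]` and reports the INS:DEL count ratio per bin (`NA`
#' where the bin has no DEL).
#'
#' @param polarized Output of [polarize_loci()], restricted to dTEs by the
#'   caller or not (loci without polarity or frequency are dropped).
#' @param bin_width Bin width on the frequency axis (default 0.05).
#' @return Data.frame `bin_lo, bin_hi, n_ins, n_del, ratio`.
#' @export
ins_del_ratio_by_frequency <- function(polarized, bin_width = 0.05) {
  d <- polarized[polarized$polarity %in% c("INS", "DEL") &
                   !is.na(polarized$carrier_freq), , drop = FALSE]
  lo <- seq(0, 1 - bin_width, by = bin_width)
  hi <- lo + bin_width
  bin <- pmin(floor(d$carrier_freq / bin_width) + 1L, length(lo))
  n_ins <- tabulate(bin[d$polarity == "INS"], nbins = length(lo))
  n_del <- tabulate(bin[d$polarity == "DEL"], nbins = length(lo))
  data.frame(bin_lo = lo, bin_hi = hi, n_ins = n_ins, n_del = n_del,
             ratio = ifelse(n_del > 0L, n_ins / n_del, NA_real_))
}

#' Hudson's FST estimator
#'
#' Sample-size-corrected Hudson estimator:
#' `[(p1 - p2)^2 - p1(1 - p1)/(n1 - 1) - p2(1 - p2)/(n2 - 1)] /
#'  [p1(1 - p2) + p2(1 - p1)]`. Negative values are reported, not clamped
#' (they do not affect ranking). `NA` when the denominator is zero.
#'
#' @param p1,p2 Derived-allele frequencies in each population (heterozygotes
#'   contribute one derived allele of two).
#' @param n1,n2 Allele sample sizes (>= 2).
#' @return FST value(s); vectorized.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (any(c(n1, n2) < 2, na.rm = TRUE)) stop("sample sizes must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

# per-locus derived-allele frequency and allele sample size within a set of
# accessions; het = 1 derived allele of 2
allele_freqs <- function(states, accs) {
  d <- state_to_dosage(states[, accs, drop = FALSE])
  n_ok <- rowSums(!is.na(d))
  list(p = rowSums(d, na.rm = TRUE) / (2 * n_ok), n = 2L * n_ok)
}

#' Per-locus FST between two subpopulations
#'
#' Computes [hudson_fst()] per locus from derived-allele counts within two
#' accession sets. Loci with fewer than 2 non-NA accessions in either set
#' get `NA`.
#'
#' @param gm A `pante_genotypes` object.
#' @param pop1,pop2 Accession id vectors.
#' @return Data.frame `locus_id, p1, p2, n1, n2, fst, rank_percentile`
#'   (fraction of defined-FST loci with strictly greater FST).
#' @export
locus_fst <- function(gm, pop1, pop2) {
  a1 <- allele_freqs(gm$states, pop1)
  a2 <- allele_freqs(gm$states, pop2)
  ok <- a1$n >= 4L & a2$n >= 4L  # >= 2 accessions, 2 alleles each
  fst <- rep(NA_real_, nrow(gm$states))
  fst[ok] <- hudson_fst(a1$p[ok], a1$n[ok], a2$p[ok], a2$n[ok])
  res <- data.frame(locus_id = gm$loci$locus_id, p1 = a1$p, p2 = a2$p,
                    n1 = a1$n, n2 = a2$n, fst = fst,
                    stringsAsFactors = FALSE)
  def <- !is.na(res$fst)
  res$rank_percentile <- NA_real_
  res$rank_percentile[def] <- vapply(res$fst[def], function(f)
    mean(res$fst[def] > f), 0)
  res
}

#' FST outliers (selected loci)
#'
#' The selection threshold is the empirical `1 - top_quantile` quantile of
#' the defined FST values; loci with `fst >= threshold` are selected (so a
#' fully tied distribution selects everything). Each locus also carries its
#' rank percentile, the fraction of loci with strictly greater FST.
#'
#' @param fst_results Output of [locus_fst()] (needs >= 20 defined values).
#' @param top_quantile Upper tail mass defining outliers (default 0.05).
#' @return List with `threshold`, `selected` (locus ids) and the annotated
#'   `results` table (`selected` flag added).
#' @export
fst_outliers <- function(fst_results, top_quantile = 0.05) {
  def <- fst_results[!is.na(fst_results$fst), , drop = FALSE]
  if (nrow(def) < 20L) stop("need >= 20 loci with defined FST")
  threshold <- unname(quantile(def$fst, 1 - top_quantile, type = 7))
  fst_results$selected <- !is.na(fst_results$fst) &
    fst_results$fst >= threshold
  list(threshold = threshold,
       selected = fst_results$locus_id[fst_results$selected],
       results = fst_results)
}

#' Windowed SNP FST and selective windows
#'
#' Tiles each chromosome into fixed windows, aggregates per-SNP Hudson FST by
#' the ratio-of-averages rule (sum of numerators over sum of denominators per
#' window), and returns the top-`top_quantile` windows as selective windows.
#' Windows without SNPs get `NA` and are excluded from ranking.
#'
#' @param variants Data.frame `chrom, pos` (0-based) per SNP.
#' @param dosage SNPs x accessions dosage matrix.
#' @param pop1,pop2 Accession id vectors.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Window size in bases (default 100 kb).
#' @param top_quantile Upper tail mass (default 0.05).
#' @return List with `windows` (chrom, start, end, n_snps, fst, selective)
#'   and `selective` (the selective subset).
#' @export
snp_selective_windows <- function(variants, dosage, pop1, pop2, chrom_sizes,
                                  window = 100000L, top_quantile = 0.05) {
  d1 <- dosage[, pop1, drop = FALSE]
  d2 <- dosage[, pop2, drop = FALSE]
  n1 <- 2 * rowSums(!is.na(d1)); p1 <- rowSums(d1, na.rm = TRUE) / n1
  n2 <- 2 * rowSums(!is.na(d2)); p2 <- rowSums(d2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- n1 >= 4 & n2 >= 4
  wins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0L, max(as.integer(chrom_sizes[ch]) - 1L, 0L), by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, as.integer(chrom_sizes[ch])),
               stringsAsFactors = FALSE)
  }))
  widx <- window_index(variants$chrom, variants$pos, wins)
  agg <- function(x, f) {
    out <- rep(NA_real_, nrow(wins))
    s <- tapply(x[ok & !is.na(widx)], widx[ok & !is.na(widx)], f)
    out[as.integer(names(s))] <- s
    out
  }
  wins$n_snps <- 0L
  tb <- table(widx[ok & !is.na(widx)])
  wins$n_snps[as.integer(names(tb))] <- as.integer(tb)
  num_s <- agg(num, sum); den_s <- agg(den, sum)
  wins$fst <- ifelse(wins$n_snps > 0L & !is.na(den_s) & den_s != 0,
                     num_s / den_s, NA_real_)
  def <- which(!is.na(wins$fst))
  thr <- quantile(wins$fst[def], 1 - top_quantile, type = 7)
  wins$selective <- !is.na(wins$fst) & wins$fst >= thr
  list(windows = wins, selective = wins[wins$selective, , drop = FALSE],
       threshold = unname(thr))
}

# index of the window containing each position (NA if none)
window_index <- function(chrom, pos, wins) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    pi <- which(chrom == ch)
    if (!length(pi)) next
    j <- findInterval(pos[pi], wins$start[wi])
    inside <- j >= 1L & pos[pi] < wins$end[wi][pmax(j, 1L)]
    idx[pi[inside]] <- wi[j[inside]]
  }
  idx
}

#' Permutation test for dTE enrichment in selective windows
#'
#' Observed statistic: mean dTE count over the selective windows. Null: each
#' permutation draws the same number of windows uniformly without replacement
#' from all windows and records the mean count. Empirical p-value with the
#' add-one correction `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so p
#' is never zero.
#'
#' @param dte_positions Data.frame `chrom, pos` of dTE loci.
#' @param windows All windows (`chrom, start, end`).
#' @param selective Logical vector over `windows`, or a data.frame subset of
#'   `windows`.
#' @param n_perm Number of permutations (default 500).
#' @param seed RNG seed.
#' @return List: `observed`, `null_means` (length `n_perm`), `p`, `n_perm`,
#'   `seed`.
#' @export
permutation_enrichment <- function(dte_positions, windows, selective,
                                   n_perm = 500L, seed = 1L) {
  if (is.data.frame(selective)) {
    key <- paste(windows$chrom, windows$start)
    selective <- key %in% paste(selective$chrom, selective$start)
  }
  n_sel <- sum(selective)
  if (n_sel > nrow(windows)) stop("more selective windows than windows")
  if (n_sel == 0L) stop("no selective windows")
  widx <- window_index(dte_positions$chrom, dte_positions$pos, windows)
  counts <- tabulate(widx[!is.na(widx)], nbins = nrow(windows))
  observed <- mean(counts[selective])
  set.seed(seed)
  null_means <- vapply(seq_len(n_perm), function(i)
    mean(counts[sample.int(nrow(windows), n_sel)]), 0)
  p <- (1 + sum(null_means >= observed)) / (n_perm + 1)
  list(observed = observed, null_means = null_means, p = p,
       n_perm = n_perm, seed = seed)
}

#' TE family enrichment among selected loci
#'
#' Per family, a 2x2 table (selected/background x family/other) is tested
#' with Fisher's exact test (two-sided); fold enrichment is the selected
#' fraction in the family over the background fraction.
#'
#' @param selected_ids Locus ids of the selected set.
#' @param loci Loci table with `locus_id` and `family` (one label per locus,
#'   majority-unit rule).
#' @return Data.frame `family, n_selected, n_background, fold, odds_ratio,
#'   p`.
#' @export
family_enrichment <- function(selected_ids, loci) {
  sel <- loci$locus_id %in% selected_ids
  fams <- unique(loci$family[!is.na(loci$family)])
  out <- do.call(rbind, lapply(fams, function(f) {
    in_f <- !is.na(loci$family) & loci$family == f
    a <- sum(sel & in_f); b <- sum(sel & !in_f)
    c_ <- sum(!sel & in_f); d <- sum(!sel & !in_f)
    if (a + c_ == 0L) return(NULL)
    ft <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                      alternative = "two.sided")
    sel_frac <- if (a + b > 0L) a / (a + b) else NA_real_
    bg_frac <- (a + c_) / (a + b + c_ + d)
    data.frame(family = f, n_selected = a, n_background = a + c_,
               fold = sel_frac / bg_frac,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Windowed presence/absence diversity (pi)
#'
#' Per locus, the average pairwise diversity of carrier states:
#' `pi = 2 * p * (1 - p) * m / (m - 1)` with `p` the derived-carrier
#' frequency over the `m` non-NA accessions — exactly the mean proportion of
#' differing states over all accession pairs. Loci with `m < 2` are skipped.
#' Per window, the mean over contained loci.
#'
#' @param polarized Output of [polarize_loci()] (uses `carrier_freq`,
#'   `n_derived`, `n_ancestral`).
#' @param windows Data.frame `chrom, start, end`.
#' @return `windows` with `n_loci` and `pi` columns (`NA` for empty
#'   windows).
#' @export
windowed_pi <- function(polarized, windows) {
  m <- polarized$n_derived + polarized$n_ancestral
  ok <- m >= 2L & !is.na(polarized$carrier_freq)
  p <- polarized$carrier_freq
  pi_loc <- ifelse(ok, 2 * p * (1 - p) * m / (m - 1), NA_real_)
  widx <- window_index(polarized$ref_chrom, polarized$ref_start, windows)
  windows$n_loci <- 0L
  use <- ok & !is.na(widx)
  tb <- table(widx[use])
  windows$n_loci[as.integer(names(tb))] <- as.integer(tb)
  windows$pi <- NA_real_
  mm <- tapply(pi_loc[use], widx[use], mean)
  windows$pi[as.integer(names(mm))] <- mm
  windows
}

#' Per-locus pi from a presence vector (helper)
#'
#' @param carrier Logical/0-1 vector of derived-carrier states (NA allowed).
#' @return Average pairwise difference with the m/(m-1) correction.
#' @export
locus_pi <- function(carrier) {
  carrier <- carrier[!is.na(carrier)]
  m <- length(carrier)
  if (m < 2L) return(NA_real_)
  p <- mean(carrier)
  2 * p * (1 - p) * m / (m - 1)
}

#' Maximum LD of a dTE with nearby variants
#'
#' LD is the squared Pearson correlation of genotype dosages over
#' pairwise-complete accessions. Variants farther than `flank` from the
#' locus breakpoint (strictly; a variant exactly at 50 kb is included, one
#' at 50.001 kb excluded) are not considered.
#'
#' @param dte_dosage Numeric dosage vector for the dTE (named by accession).
#' @param variant_dosage Variants x accessions dosage matrix.
#' @param variant_pos Data.frame `chrom, pos` per variant row.
#' @param dte_chrom,dte_pos Locus breakpoint.
#' @param flank Window on either side in bases (default 50 kb).
#' @return List `max_r2`, `best_variant` (row index), `r2` (per candidate
#'   variant, named by rownames).
#' @export
max_ld_r2 <- function(dte_dosage, variant_dosage, variant_pos, dte_chrom,
                      dte_pos, flank = 50000L) {
  near <- which(variant_pos$chrom == dte_chrom &
                  abs(variant_pos$pos - dte_pos) <= flank)
  if (!length(near)) {
    return(list(max_r2 = NA_real_, best_variant = NA_integer_,
                r2 = numeric(0)))
  }
  accs <- intersect(names(dte_dosage), colnames(variant_dosage))
  x <- dte_dosage[accs]
  r2 <- vapply(near, function(v) {
    y <- variant_dosage[v, accs]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])^2
  }, 0)
  names(r2) <- rownames(variant_dosage)[near]
  if (all(is.na(r2))) {
    return(list(max_r2 = NA_real_, best_variant = NA_integer_, r2 = r2))
  }
  list(max_r2 = max(r2, na.rm = TRUE),
       best_variant = near[which.max(r2)], r2 = r2)
}

#' Genic-context assignment of loci
#'
#' Each locus is assigned to the single feature class with the largest base
#' overlap among CDS, 5'UTR, 3'UTR, intron, promoter (2 kb upstream of the
#' gene body, strand-aware), downstream (2 kb downstream) and intergenic;
#' insertion points use the containing feature. Overlap ties are broken by
#' the priority CDS > 5'UTR > 3'UTR > intron > promoter > downstream. A
#' locus overlapping two genes is counted for both genes; its category comes
#' from the largest overlap. Per-gene counts include all loci overlapping
#' the gene body +/- `flank`.
#'
#' @param loci Loci data.frame (`locus_id, ref_chrom, ref_start, ref_end`).
#' @param gene_models Output of [read_gene_models()].
#' @param flank Promoter/downstream extent in bases (default 2 kb).
#' @return List: `categories` (locus_id, category), `gene_counts` (gene_id,
#'   n_dte), `count_distribution` (genes with 0, 1, >= 2 nearby loci).
#' @export
genic_context <- function(loci, gene_models, flank = 2000L) {
  genes <- gene_models$genes
  feats <- gene_models$features
  prom <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = ifelse(genes$strand == "+", genes$start - flank,
                                    genes$end),
                     end = ifelse(genes$strand == "+", genes$start,
                                  genes$end + flank),
                     type = "promoter", stringsAsFactors = FALSE)
  down <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = ifelse(genes$strand == "+", genes$end,
                                    genes$start - flank),
                     end = ifelse(genes$strand == "+", genes$end + flank,
                                  genes$start),
                     type = "downstream", stringsAsFactors = FALSE)
  all_feats <- rbind(feats[feats$type != "exon",
                           c("gene_id", "chrom", "start", "end", "type")],
                     prom, down)
  all_feats$type[all_feats$type == "five_prime_UTR"] <- "5'UTR"
  all_feats$type[all_feats$type == "three_prime_UTR"] <- "3'UTR"
  priority <- c("CDS" = 1, "5'UTR" = 2, "3'UTR" = 3, "intron" = 4,
                "promoter" = 5, "downstream" = 6)
  cats <- vapply(seq_len(nrow(loci)), function(k) {
    s <- loci$ref_start[k]; e <- loci$ref_end[k]
    point <- e <= s
    f <- all_feats[all_feats$chrom == loci$ref_chrom[k], , drop = FALSE]
    if (point) {
      hit <- f[f$start <= s & f$end > s, , drop = FALSE]
      if (!nrow(hit)) return("intergenic")
      hit$ov <- 1
    } else {
      hit <- f[f$end > s & f$start < e, , drop = FALSE]
      if (!nrow(hit)) return("intergenic")
      hit$ov <- overlap_len(hit$start, hit$end, s, e)
    }
    hit <- hit[order(-hit$ov, priority[hit$type]), , drop = FALSE]
    hit$type[1]
  }, "")
  categories <- data.frame(locus_id = loci$locus_id, category = cats,
                           stringsAsFactors = FALSE)
  # per-gene counts within gene body +/- flank
  n_dte <- vapply(seq_len(nrow(genes)), function(g) {
    s <- genes$start[g] - flank; e <- genes$end[g] + flank
    on <- loci$ref_chrom == genes$chrom[g]
    point <- loci$ref_end <= loci$ref_start
    sum(on & ifelse(point, loci$ref_start >= s & loci$ref_start < e,
                    loci$ref_end > s & loci$ref_start < e))
  }, 0L)
  gene_counts <- data.frame(gene_id = genes$gene_id, n_dte = n_dte,
                            stringsAsFactors = FALSE)
  dist <- c(`0` = sum(n_dte == 0L), `1` = sum(n_dte == 1L),
            `>=2` = sum(n_dte >= 2L))
  list(categories = categories, gene_counts = gene_counts,
       count_distribution = dist)
}

#' Population structure from the dTE matrix
#'
#' PCA of the centered genotype-dosage covariance, with per-locus mean
#' imputation of NA dosages. Accessions with all-NA genotypes are excluded
#' with a warning.
#'
#' @param gm A `pante_genotypes` object (or a dosage matrix loci x
#'   accessions).
#' @param n_pcs Number of PCs to return (default 10).
#' @return List: `scores` (accessions x PCs), `var_explained`.
#' @export
dte_pca <- function(gm, n_pcs = 10L) {
  d <- if (inherits(gm, "pante_genotypes")) state_to_dosage(gm$states) else gm
  all_na <- colSums(!is.na(d)) == 0L
  if (any(all_na)) {
    warning("excluding all-NA accession(s): ",
            paste(colnames(d)[all_na], collapse = ", "))
    d <- d[, !all_na, drop = FALSE]
  }
  for (k in seq_len(nrow(d))) {
    miss <- is.na(d[k, ])
    if (any(miss)) d[k, miss] <- mean(d[k, ], na.rm = TRUE)
  }
  d <- d[apply(d, 1L, sd) > 0, , drop = FALSE]
  pc <- prcomp(t(d), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Pairwise genotype distance matrix
#'
#' Distance = proportion of differing non-NA genotype states between two
#' accessions.
#'
#' @param gm A `pante_genotypes` object.
#' @return A symmetric `dist`-convertible matrix.
#' @export
genotype_distance <- function(gm) {
  st <- gm$states
  n <- ncol(st)
  D <- matrix(0, n, n, dimnames = list(colnames(st), colnames(st)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(st[, i]) & !is.na(st[, j])
      D[i, j] <- D[j, i] <- if (any(ok)) mean(st[ok, i] != st[ok, j]) else NA_real_
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining via [ape::nj()]; an additive distance matrix is
#' recovered exactly (topology and branch lengths).
#'
#' @param D Symmetric distance matrix.
#' @param file Optional path to write Newick.
#' @return An `ape::phylo` object (unrooted).
#' @export
nj_tree <- function(D, file = NULL) {
  tr <- ape::nj(as.dist(D))
  if (!is.null(file)) ape::write.tree(tr, file)
  tr
}

#' LTR insertion-time estimate from paired terminal repeats
#'
#' Jukes-Cantor correction of the divergence between the two long terminal
#' repeats of an element (or any pre-aligned paralogous pair):
#' `d = -(3/4) ln(1 - 4p/3)` with `p` the raw mismatch proportion over
#' ungapped columns, and `T = d / (2 mu)`. Saturated pairs (`p >= 0.75`) are
#' undefined and flagged.
#'
#' @param aligned_5p,aligned_3p Equal-length aligned sequences (characters;
#'   `-` marks gaps, dropped columnwise).
#' @param mu Substitution rate per site per year (default 1.3e-8).
#' @return List `p`, `d`, `years`, `saturated`.
#' @export
ltr_insertion_time <- function(aligned_5p, aligned_3p, mu = 1.3e-8) {
  a <- strsplit(toupper(aligned_5p), "")[[1]]
  b <- strsplit(toupper(aligned_3p), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no ungapped columns")
  p <- mean(a != b)
  if (p >= 0.75) {
    return(list(p = p, d = NA_real_, years = NA_real_, saturated = TRUE))
  }
  d <- -0.75 * log(1 - 4 * p / 3)
  list(p = p, d = d, years = d / (2 * mu), saturated = FALSE)
}
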