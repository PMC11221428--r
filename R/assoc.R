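# cis-eQTL scans and trait GWAS on dTE / SNP genotype dosages, plus the
# TE-vs-SNP eGene comparison.
#
# Model: ordinary least squares on dosage (0/1/2), with principal-component
# covariates for GWAS and no covariates for the cis-eQTL scan. Multiplicity:
# per-gene Bonferroni over the gene's tested variants, then Benjamini-
# Hochberg across genes on the per-gene minimal adjusted p (eQTL);
# Bonferroni 0.05/M genome-wide (GWAS).

# closed-form simple regression y ~ x on complete pairs
ols_simple <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || sd(x) == 0) {
    return(list(beta = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  }
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  tss <- sum(yc^2)
  if (tss == 0) {  # constant response: nothing to explain
    return(list(beta = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  }
  beta <- sum(xc * yc) / sxx
  fitted <- beta * xc
  rss <- sum((yc - fitted)^2)
  r2 <- 1 - rss / tss
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * pt(-abs(beta / se), df = n - 2)
  list(beta = beta, r2 = r2, p = p, n = n)
}

# y ~ x + covariates, returning the slope test for x
ols_covar <- function(x, y, covar) {
  ok <- stats::complete.cases(x, y, covar)
  x <- x[ok]; y <- y[ok]
  C <- cbind(1, covar[ok, , drop = FALSE])
  n <- length(x)
  k <- ncol(C)
  if (n < k + 2L || sd(x) == 0) {
    return(list(beta = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  }
  qc <- qr(C)
  xr <- qr.resid(qc, x)
  yr <- qr.resid(qc, y)
  sxx <- sum(xr^2)
  if (sxx < 1e-12) {
    return(list(beta = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  }
  beta <- sum(xr * yr) / sxx
  rss <- sum((yr - beta * xr)^2)
  df <- n - k - 1L
  se <- sqrt(rss / df / sxx)
  tss <- sum(yr^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  p <- if (se == 0) 0 else 2 * pt(-abs(beta / se), df = df)
  list(beta = beta, r2 = r2, p = p, n = n)
}

#' cis-eQTL scan
#'
#' Tests every variant within `cis_flank` of a gene body against that gene's
#' expression by OLS on dosage. Per gene, the minimal p is Bonferroni-
#' adjusted for the number of variants tested for that gene; eGenes are
#' called by Benjamini-Hochberg at `fdr` across the per-gene adjusted
#' minima. Monomorphic variants are skipped; genes with no cis variant are
#' recorded untested.
#'
#' @param dosage Variants x accessions dosage matrix.
#' @param variant_pos Data.frame `variant_id, chrom, pos` (0-based; one row
#'   per dosage row) with optional `class` column.
#' @param expression Genes x accessions matrix.
#' @param gene_models Output of [read_gene_models()] (or a `genes`-like
#'   data.frame with `gene_id, chrom, start, end`).
#' @param cis_flank Window on either side of the gene body (default 50 kb).
#' @param fdr Across-gene FDR level for eGene calling (default 0.05).
#' @return List: `pairs` (per gene-variant test), `genes` (per gene: best
#'   variant by smallest p, ties broken by larger r2 then smaller
#'   coordinate; `p_adj_gene`, `p_bh`, `egene`), `egenes` (ids).
#' @export
eqtl_scan <- function(dosage, variant_pos, expression, gene_models,
                      cis_flank = 50000L, fdr = 0.05) {
  genes <- if (is.data.frame(gene_models)) gene_models else gene_models$genes
  accs <- intersect(colnames(dosage), colnames(expression))
  if (length(accs) < 20L) {
    stop("need >= 20 accessions with both genotype and expression")
  }
  d <- dosage[, accs, drop = FALSE]
  pairs <- list()
  gene_rows <- list()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    if (!gid %in% rownames(expression)) next
    y <- expression[gid, accs]
    cand <- which(variant_pos$chrom == genes$chrom[g] &
                    variant_pos$pos >= genes$start[g] - cis_flank &
                    variant_pos$pos <= genes$end[g] + cis_flank)
    res <- lapply(cand, function(v) {
      x <- d[v, ]
      if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) return(NULL)
      fit <- ols_simple(x, y)
      if (is.na(fit$p)) return(NULL)
      data.frame(gene_id = gid, variant_id = variant_pos$variant_id[v],
                 class = variant_pos$class[v] %||% NA_character_,
                 chrom = variant_pos$chrom[v], pos = variant_pos$pos[v],
                 beta = fit$beta, r2 = fit$r2, p = fit$p, n = fit$n,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res) || nrow(res) == 0L) {
      gene_rows[[gid]] <- data.frame(gene_id = gid, n_tested = 0L,
                                     variant_id = NA_character_,
                                     beta = NA_real_, r2 = NA_real_,
                                     p = NA_real_, p_adj_gene = NA_real_,
                                     stringsAsFactors = FALSE)
      next
    }
    pairs[[gid]] <- res
    best <- res[order(res$p, -res$r2, res$pos), ][1, ]
    gene_rows[[gid]] <- data.frame(
      gene_id = gid, n_tested = nrow(res), variant_id = best$variant_id,
      beta = best$beta, r2 = best$r2, p = best$p,
      p_adj_gene = min(best$p * nrow(res), 1), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  genes_out <- do.call(rbind, gene_rows)
  rownames(genes_out) <- NULL
  tested <- !is.na(genes_out$p_adj_gene)
  genes_out$p_bh <- NA_real_
  genes_out$p_bh[tested] <- p.adjust(genes_out$p_adj_gene[tested],
                                     method = "BH")
  genes_out$egene <- !is.na(genes_out$p_bh) & genes_out$p_bh <= fdr
  list(pairs = pairs, genes = genes_out,
       egenes = genes_out$gene_id[genes_out$egene])
}

#' Compare TE-based and SNP-based eGene sets
#'
#' Partitions eGenes into shared, dTE-only and SNP-only sets over the common
#' gene universe (a non-identical universe is intersected with a message),
#' and flags, per shared gene, whether the leading dTE explains more
#' expression variance than the leading SNP.
#'
#' @param te_scan,snp_scan Outputs of [eqtl_scan()].
#' @return List: `both`, `te_only`, `snp_only` (gene id vectors), `shared`
#'   (data.frame `gene_id, te_r2, snp_r2, te_explains_more`).
#' @export
compare_te_snp_egenes <- function(te_scan, snp_scan) {
  gt <- te_scan$genes; gs <- snp_scan$genes
  common <- intersect(gt$gene_id, gs$gene_id)
  if (length(common) < length(union(gt$gene_id, gs$gene_id))) {
    message("gene universes differ; using the intersection (",
            length(common), " genes)")
  }
  te_e <- intersect(te_scan$egenes, common)
  snp_e <- intersect(snp_scan$egenes, common)
  both <- intersect(te_e, snp_e)
  shared <- data.frame(
    gene_id = both,
    te_r2 = gt$r2[match(both, gt$gene_id)],
    snp_r2 = gs$r2[match(both, gs$gene_id)],
    stringsAsFactors = FALSE)
  shared$te_explains_more <- shared$te_r2 > shared$snp_r2
  list(both = both, te_only = setdiff(te_e, snp_e),
       snp_only = setdiff(snp_e, te_e), shared = shared)
}

#' Trait GWAS
#'
#' Per-variant OLS of the phenotype on dosage with the leading principal
#' components of the same variant class as covariates; genome-wide
#' significance by Bonferroni `alpha / M` over the `M` tested variants.
#' Missing phenotypes and genotypes are dropped pairwise.
#'
#' @param dosage Variants x accessions dosage matrix.
#' @param variant_pos Data.frame `variant_id, chrom, pos` per dosage row.
#' @param phenotype Named numeric vector (accession -> value).
#' @param n_pcs Number of PC covariates (default 3).
#' @param alpha Family-wise level (default 0.05).
#' @return List: `results` (Manhattan-ready, ordered by chrom/pos:
#'   `variant_id, chrom, pos, beta, r2, p, n, significant`), `threshold`,
#'   `significant` (ids), `n_tested`.
#' @export
gwas_scan <- function(dosage, variant_pos, phenotype, n_pcs = 3L,
                      alpha = 0.05) {
  accs <- intersect(colnames(dosage), names(phenotype))
  y <- phenotype[accs]
  accs <- accs[!is.na(y)]
  y <- phenotype[accs]
  if (length(accs) <= n_pcs + 2L) {
    stop("need more than n_pcs + 2 accessions with phenotype")
  }
  d <- dosage[, accs, drop = FALSE]
  covar <- NULL
  if (n_pcs > 0L) {
    di <- d
    for (k in seq_len(nrow(di))) {
      miss <- is.na(di[k, ])
      if (any(miss)) di[k, miss] <- mean(di[k, ], na.rm = TRUE)
    }
    di <- di[apply(di, 1L, sd) > 0, , drop = FALSE]
    pc <- prcomp(t(di), center = TRUE)
    covar <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(d)), function(v) {
    x <- d[v, ]
    if (all(is.na(x)) || sd(x, na.rm = TRUE) == 0) return(NULL)
    fit <- if (is.null(covar)) ols_simple(x, y) else ols_covar(x, y, covar)
    if (is.na(fit$p)) return(NULL)
    data.frame(variant_id = variant_pos$variant_id[v],
               chrom = variant_pos$chrom[v], pos = variant_pos$pos[v],
               beta = fit$beta, r2 = fit$r2, p = fit$p, n = fit$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable variants")
  M <- nrow(res)
  thr <- alpha / M
  res$significant <- res$p < thr
  res <- res[order(res$chrom, res$pos), ]
  rownames(res) <- NULL
  list(results = res, threshold = thr,
       significant = res$variant_id[res$significant], n_tested = M)
}
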