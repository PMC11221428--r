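# Independent brute-force oracles. These deliberately avoid the package's
# code paths: loops over pairs, direct formula evaluation, exhaustive
# clustering.

# Hudson FST evaluated term by term
oracle_hudson <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - (p1 * (1 - p1)) / (n1 - 1) - (p2 * (1 - p2)) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) return(NA_real_)
  num / den
}

# mean pairwise difference over all accession pairs
oracle_pi_pairs <- function(carrier) {
  carrier <- carrier[!is.na(carrier)]
  m <- length(carrier)
  if (m < 2) return(NA_real_)
  diffs <- 0
  npairs <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      diffs <- diffs + as.integer(carrier[i] != carrier[j])
      npairs <- npairs + 1
    }
  }
  diffs / npairs
}

# two-sided Fisher p from the hypergeometric pmf: sum of all tables (over
# the free cell) at most as probable as the observed one
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_      # family total
  n <- b + d       # other total
  k <- a + b       # selected total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# simple regression via lm()
oracle_ols <- function(x, y) {
  fit <- summary(lm(y ~ x))
  list(beta = unname(coef(fit)[2, 1]), p = unname(coef(fit)[2, 4]),
       r2 = fit$r.squared)
}

# exhaustive single-linkage clustering from an adjacency predicate
oracle_single_linkage <- function(n, linked) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && linked(i, j) && comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# union width of 0-based half-open intervals via a base-pair bitmap
oracle_union_width <- function(starts, ends, span) {
  hit <- logical(span)
  for (k in seq_along(starts)) {
    if (ends[k] > starts[k]) hit[(starts[k] + 1):ends[k]] <- TRUE
  }
  sum(hit)
}

# reconstruct the aligned portions of a query from reference + CIGAR and
# check consistency with the emitted query sequence
check_cigar_consistency <- function(paf, query_seqs, ref_seqs) {
  for (i in seq_len(nrow(paf))) {
    cig <- paf$cigar[[i]]
    tpos <- paf$tstart[i]
    qpos <- paf$qstart[i]
    q <- query_seqs[[paf$qname[i]]]
    r <- ref_seqs[[paf$tname[i]]]
    for (k in seq_len(nrow(cig))) {
      op <- cig$op[k]; len <- cig$len[k]
      if (op == "=") {
        if (substr(r, tpos + 1, tpos + len) != substr(q, qpos + 1, qpos + len)) {
          return(FALSE)
        }
        tpos <- tpos + len; qpos <- qpos + len
      } else if (op %in% c("X", "M")) {
        tpos <- tpos + len; qpos <- qpos + len
      } else if (op == "I") {
        qpos <- qpos + len
      } else if (op == "D") {
        tpos <- tpos + len
      }
    }
    if (tpos != paf$tend[i] || qpos != paf$qend[i]) return(FALSE)
  }
  TRUE
}
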