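# PAF (Pairwise mApping Format) reading and writing with cg:Z CIGAR tags.
#
# PAF records carry 0-based half-open query/target coordinates. For minus-
# strand records the query interval refers to the original (plus) strand of
# the query while the CIGAR walks the target forward and the query as its
# reverse complement; `read_paf()` keeps the record as stored and downstream
# CIGAR walkers handle orientation (see `extract_pavs()`).

CIGAR_OPS <- c("=", "X", "I", "D", "M")

parse_cigar <- function(cg) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cg, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("unparsable CIGAR string: ", substr(cg, 1, 50))
  toks <- regmatches(cg, gregexpr("(\\d+)([MIDNSHP=X])", cg, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(cg)) {
    stop("unparsable CIGAR string: ", substr(cg, 1, 50))
  }
  op <- substr(toks, nchar(toks), nchar(toks))
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  bad <- !op %in% CIGAR_OPS
  if (any(bad)) stop("unsupported CIGAR op(s): ", paste(unique(op[bad]), collapse = ", "))
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

cigar_spans <- function(cig) {
  list(
    target = sum(cig$len[cig$op %in% c("=", "X", "M", "D")]),
    query  = sum(cig$len[cig$op %in% c("=", "X", "M", "I")])
  )
}

#' Read a PAF alignment file
#'
#' Parses PAF records, extracting the `cg:Z` CIGAR tag where present and
#' validating that the CIGAR-implied target and query spans equal the record's
#' stated coordinates. Records lacking a `cg:Z` tag are retained but flagged
#' unusable for PAV calling (`usable = FALSE`) with a warning; malformed lines
#' are a hard error naming the offending line.
#'
#' @param path Path to a PAF file.
#' @return A data.frame with one row per record: `qname, qlen, qstart, qend,
#'   strand, tname, tlen, tstart, tend, nmatch, alen, mapq, usable`, plus a
#'   `cigar` list-column of `(op, len)` data.frames (`NULL` when absent).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) {
      stop("malformed PAF line ", i, " in ", path, ": fewer than 12 fields")
    }
    num <- suppressWarnings(as.numeric(f[c(2, 3, 4, 7, 8, 9, 10, 11, 12)]))
    if (anyNA(num) || !f[5] %in% c("+", "-")) {
      stop("malformed PAF line ", i, " in ", path)
    }
    tags <- f[-(1:12)]
    cg <- tags[startsWith(tags, "cg:Z:")]
    cigar <- NULL
    if (length(cg) >= 1L) cigar <- parse_cigar(sub("^cg:Z:", "", cg[1]))
    recs[[i]] <- list(
      qname = f[1], qlen = as.integer(f[2]),
      qstart = as.integer(f[3]), qend = as.integer(f[4]),
      strand = f[5],
      tname = f[6], tlen = as.integer(f[7]),
      tstart = as.integer(f[8]), tend = as.integer(f[9]),
      nmatch = as.integer(f[10]), alen = as.integer(f[11]),
      mapq = as.integer(f[12]), cigar = cigar)
  }
  out <- data.frame(
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
  out$cigar <- lapply(recs, `[[`, "cigar")
  out$usable <- !vapply(out$cigar, is.null, TRUE)
  if (any(!out$usable)) {
    warning(sum(!out$usable), " PAF record(s) lack a cg:Z tag and are ",
            "flagged unusable for PAV calling")
  }
  for (i in which(out$usable)) {
    sp <- cigar_spans(out$cigar[[i]])
    if (sp$target != out$tend[i] - out$tstart[i]) {
      stop("PAF record ", i, ": CIGAR target span ", sp$target,
           " != stated span ", out$tend[i] - out$tstart[i])
    }
    if (sp$query != out$qend[i] - out$qstart[i]) {
      stop("PAF record ", i, ": CIGAR query span ", sp$query,
           " != stated span ", out$qend[i] - out$qstart[i])
    }
  }
  out
}

#' Write PAF records
#'
#' Inverse of [read_paf()]; records with a `cigar` entry get a `cg:Z` tag.
#'
#' @param paf Data.frame as returned by [read_paf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_paf <- function(paf, path) {
  lines <- vapply(seq_len(nrow(paf)), function(i) {
    base <- paste(paf$qname[i], paf$qlen[i], paf$qstart[i], paf$qend[i],
                  paf$strand[i], paf$tname[i], paf$tlen[i], paf$tstart[i],
                  paf$tend[i], paf$nmatch[i], paf$alen[i], paf$mapq[i],
                  sep = "\t")
    cig <- paf$cigar[[i]]
    if (!is.null(cig)) {
      base <- paste0(base, "\ttp:A:P\tcg:Z:",
                     paste0(cig$len, cig$op, collapse = ""))
    }
    base
  }, "")
  writeLines(lines, path)
  invisible(path)
}
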