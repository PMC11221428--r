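# Readers/writers for the remaining formats: TE annotation GFF3 (EDTA-style
# Classification attributes), gene models, SNP/InDel VCF, the on-disk
# genotype-matrix TSV dialect, and the dTE VCF export.

TE_SUPERFAMILIES <- c("Gypsy", "Copia", "LINE", "SINE", "DTC", "DTA", "DTT",
                      "DTM", "DTH", "MITE-Stowaway", "MITE-Tourist", "Helitron")

# Normalization of common classification aliases (RepeatMasker / EDTA
# dialects) to the canonical superfamily inventory.
TE_CLASS_ALIASES <- c(
  "LTR/Gypsy" = "Gypsy", "LTR/Copia" = "Copia", "LTR/unknown" = "unknown",
  "LINE/L1" = "LINE", "LINE/unknown" = "LINE", "SINE/tRNA" = "SINE",
  "SINE/unknown" = "SINE", "DNA/DTC" = "DTC", "DNA/DTA" = "DTA",
  "DNA/DTT" = "DTT", "DNA/DTM" = "DTM", "DNA/DTH" = "DTH",
  "DNA/Helitron" = "Helitron", "RC/Helitron" = "Helitron",
  "MITE/Stow" = "MITE-Stowaway", "MITE/Stowaway" = "MITE-Stowaway",
  "MITE/Tourist" = "MITE-Tourist")

normalize_superfamily <- function(x) {
  out <- x
  hit <- x %in% names(TE_CLASS_ALIASES)
  out[hit] <- TE_CLASS_ALIASES[x[hit]]
  unknown <- !out %in% c(TE_SUPERFAMILIES, "unknown")
  if (any(unknown)) {
    warning("unknown TE superfamily label(s) mapped to 'unknown': ",
            paste(unique(out[unknown]), collapse = ", "))
    out[unknown] <- "unknown"
  }
  out
}

#' Read TE annotations from GFF3
#'
#' Reads an EDTA-style TE annotation GFF3 where the TE lineage is carried in a
#' `Classification=superfamily/family` attribute. Coordinates are converted to
#' 0-based half-open. Unrecognized superfamily labels are normalized through a
#' small alias table and otherwise mapped to `"unknown"` with a warning.
#'
#' @param path GFF3 file path.
#' @param genome Genome identifier stored on each record (default: file stem).
#' @return Data.frame with columns `genome, chrom, start, end, strand,
#'   superfamily, family, intact`.
#' @export
read_te_gff3 <- function(path, genome = sub("\\.gff3?$", "", basename(path))) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) {
    return(data.frame(genome = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), superfamily = character(0),
                      family = character(0), intact = logical(0),
                      stringsAsFactors = FALSE))
  }
  cls <- if ("Classification" %in% names(df)) as.character(df$Classification)
         else rep("unknown/unknown", nrow(df))
  parts <- strsplit(cls, "/", fixed = TRUE)
  fam <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else "unknown", "")
  # a whole classification may be a known alias (e.g. LTR/Gypsy); otherwise
  # the leading component names the superfamily
  aliased <- cls %in% names(TE_CLASS_ALIASES)
  superfam <- vapply(parts, `[`, "", 1L)
  superfam[aliased] <- TE_CLASS_ALIASES[cls[aliased]]
  superfam <- normalize_superfamily(superfam)
  data.frame(
    genome = genome,
    chrom = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    strand = ifelse(as.character(df$strand) == "-", "-", "+"),
    superfamily = superfam,
    family = fam,
    intact = if ("Method" %in% names(df)) df$Method == "structural" else TRUE,
    stringsAsFactors = FALSE)
}

#' Write TE annotations to GFF3
#'
#' @param te Data.frame as returned by [read_te_gff3()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_te_gff3 <- function(te, path) {
  lines <- c("##gff-version 3")
  if (nrow(te)) {
    attrs <- sprintf("ID=TE_%06d;Name=%s;Classification=%s/%s;Method=%s",
                     seq_len(nrow(te)), te$family, te$superfamily, te$family,
                     ifelse(te$intact, "structural", "homology"))
    lines <- c(lines, paste(te$chrom, "panTE", "transposable_element",
                            te$start + 1L, te$end, ".", te$strand, ".",
                            attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads gene/mRNA/exon/CDS/UTR features, converts to 0-based half-open
#' coordinates, and derives intron intervals as the gaps between a
#' transcript's exons. Overlapping exons within one transcript are a hard
#' error.
#'
#' @param path GFF3 file path.
#' @return List with elements `genes` (one row per gene: `gene_id, chrom,
#'   start, end, strand`) and `features` (one row per feature part: `gene_id,
#'   chrom, start, end, strand, type` with type in CDS, five_prime_UTR,
#'   three_prime_UTR, intron, exon).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  gene_id <- if ("Parent" %in% names(df)) {
    par <- vapply(df$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
    ifelse(df$type == "gene", as.character(df$ID), sub("\\.mRNA\\d*$", "", par))
  } else as.character(df$ID)
  df$gene_id <- gene_id
  genes <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = as.character(genes$ID),
                      chrom = as.character(genes$seqnames),
                      start = genes$start - 1L, end = genes$end,
                      strand = as.character(genes$strand),
                      stringsAsFactors = FALSE)
  parts <- df[df$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR", "exon"), ]
  feats <- data.frame(gene_id = parts$gene_id,
                      chrom = as.character(parts$seqnames),
                      start = parts$start - 1L, end = parts$end,
                      strand = as.character(parts$strand),
                      type = parts$type, stringsAsFactors = FALSE)
  introns <- do.call(rbind, lapply(split(feats[feats$type == "exon", ], feats$gene_id[feats$type == "exon"]),
    function(ex) {
      ex <- ex[order(ex$start), ]
      if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
        stop("overlapping exons within transcript of gene ", ex$gene_id[1])
      }
      if (nrow(ex) < 2L) return(NULL)
      data.frame(gene_id = ex$gene_id[1], chrom = ex$chrom[1],
                 start = ex$end[-nrow(ex)], end = ex$start[-1],
                 strand = ex$strand[1], type = "intron",
                 stringsAsFactors = FALSE)
    }))
  feats <- rbind(feats, introns)
  rownames(feats) <- NULL
  list(genes = genes, features = feats)
}

#' Write gene models to GFF3
#'
#' @param models List as returned by [read_gene_models()] (the `intron` rows
#'   are not written; they are derivable).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  f <- models$features[models$features$type != "intron", ]
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines,
      paste(g$chrom[i], "panTE", "gene", g$start[i] + 1L, g$end[i], ".",
            g$strand[i], ".", sprintf("ID=%s", gid), sep = "\t"),
      paste(g$chrom[i], "panTE", "mRNA", g$start[i] + 1L, g$end[i], ".",
            g$strand[i], ".", sprintf("ID=%s.mRNA1;Parent=%s", gid, gid),
            sep = "\t"))
    fi <- f[f$gene_id == gid, ]
    fi <- fi[order(fi$start), ]
    lines <- c(lines, paste(fi$chrom, "panTE", fi$type, fi$start + 1L, fi$end,
                            ".", fi$strand, ifelse(fi$type == "CDS", "0", "."),
                            sprintf("ID=%s.%s%d;Parent=%s.mRNA1", gid,
                                    fi$type, seq_len(nrow(fi)), gid),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SNP/InDel genotypes from VCF
#'
#' Reads a VCF 4.2 file with `GT` genotypes and returns positions (0-based)
#' plus a dosage matrix. Heterozygous `0/1` becomes dosage 1; missing `./.`
#' becomes `NA`.
#'
#' @param path VCF file path.
#' @return List with `variants` (data.frame `variant_id, chrom, pos, ref, alt,
#'   class`) and `dosage` (variants x samples numeric matrix).
#' @export
read_snp_vcf <- function(path) {
  v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dose[gt %in% c("1/1", "1|1")] <- 2
  cls <- ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L, "SNP", "InDel")
  id <- fix$ID
  if (is.null(id) || all(is.na(id))) id <- sprintf("var%06d", seq_len(nrow(fix)))
  rownames(dose) <- id
  list(variants = data.frame(variant_id = id, chrom = fix$CHROM,
                             pos = as.integer(fix$POS) - 1L,
                             ref = fix$REF, alt = fix$ALT, class = cls,
                             stringsAsFactors = FALSE),
       dosage = dose)
}

#' Write a simple biallelic VCF from a dosage matrix
#'
#' @param variants Data.frame with `variant_id, chrom, pos` (0-based), `ref`,
#'   `alt`.
#' @param dosage Variants x samples matrix over `{0, 1, 2, NA}`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_vcf <- function(variants, dosage, path) {
  gt <- matrix("./.", nrow(dosage), ncol(dosage))
  gt[which(dosage == 0)] <- "0/0"
  gt[which(dosage == 1)] <- "0/1"
  gt[which(dosage == 2)] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(dosage)), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos + 1L, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the pan-TE genotype matrix
#'
#' TSV dialect: locus metadata columns (`locus_id, chrom, start, end,
#' pav_type, length, family, n_units, polarity, dte`) followed by one column
#' per accession holding `0/0`, `0/1`, `1/1` or the literal `NA` for an
#' uncertain genotype. Round trips losslessly through
#' [read_genotype_matrix()].
#'
#' @param gm A `pante_genotypes` object (see [genotype_matrix()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_matrix <- function(gm, path) {
  loci <- gm$loci
  meta <- data.frame(locus_id = loci$locus_id, chrom = loci$ref_chrom,
                     start = loci$ref_start, end = loci$ref_end,
                     pav_type = loci$pav_type, length = loci$length,
                     family = loci$family, n_units = loci$n_units,
                     polarity = loci$polarity %||% rep(NA_character_, nrow(loci)),
                     dte = loci$dte %||% rep(NA, nrow(loci)),
                     stringsAsFactors = FALSE)
  states <- gm$states
  states[is.na(states)] <- "NA"
  out <- cbind(meta, as.data.frame(states, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#subpop\t", paste(
    paste(gm$accessions$accession, gm$accessions$subpop, sep = "="),
    collapse = ";")), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the pan-TE genotype matrix
#'
#' @param path Path written by [write_genotype_matrix()].
#' @return A `pante_genotypes` object.
#' @export
read_genotype_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  acc <- NULL
  if (startsWith(first, "#subpop\t")) {
    pairs <- strsplit(sub("^#subpop\t", "", first), ";", fixed = TRUE)[[1]]
    if (length(pairs) && nzchar(pairs[1])) {
      kv <- strsplit(pairs, "=", fixed = TRUE)
      acc <- data.frame(accession = vapply(kv, `[`, "", 1L),
                        subpop = vapply(kv, `[`, "", 2L),
                        stringsAsFactors = FALSE)
    } else {
      acc <- data.frame(accession = character(0), subpop = character(0))
    }
  }
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0))
  meta_cols <- c("locus_id", "chrom", "start", "end", "pav_type", "length",
                 "family", "n_units", "polarity", "dte")
  state_cols <- setdiff(names(tab), meta_cols)
  states <- as.matrix(tab[, state_cols, drop = FALSE])
  bad <- !(states %in% c(GT_STATES, "NA"))
  if (any(bad)) {
    stop("unknown genotype state token(s): ",
         paste(unique(states[bad]), collapse = ", "))
  }
  states[states == "NA"] <- NA_character_
  rownames(states) <- tab$locus_id
  loci <- data.frame(locus_id = tab$locus_id, ref_chrom = tab$chrom,
                     ref_start = as.integer(tab$start),
                     ref_end = as.integer(tab$end), pav_type = tab$pav_type,
                     length = as.integer(tab$length), family = tab$family,
                     n_units = as.integer(tab$n_units),
                     polarity = ifelse(tab$polarity == "NA", NA_character_, tab$polarity),
                     dte = as.logical(tab$dte), stringsAsFactors = FALSE)
  if (is.null(acc)) {
    acc <- data.frame(accession = state_cols,
                      subpop = rep(NA_character_, length(state_cols)),
                      stringsAsFactors = FALSE)
  }
  structure(list(states = states, loci = loci, accessions = acc),
            class = "pante_genotypes")
}

#' Export polarized loci as a symbolic-ALT VCF
#'
#' Writes one VCF 4.2 record per locus with symbolic ALT (`<INS>`/`<DEL>`,
#' following the locus polarity; unpolarized loci get `POLARITY=NA` and a
#' symbolic ALT from the PAV type), INFO keys `SVLEN`, `TEFAM` (comma-joined
#' across TE units), `POLARITY` and the `DTE` flag, and `GT` genotypes.
#'
#' @param polarized Data.frame of polarized loci (see [polarize_loci()]).
#' @param gm `pante_genotypes` object aligned with `polarized`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_dte_vcf <- function(polarized, gm, path) {
  states <- gm$states[polarized$locus_id, , drop = FALSE]
  gt <- states
  gt[is.na(gt)] <- "./."
  pol <- ifelse(is.na(polarized$polarity) | polarized$polarity == "unpolarized",
                "NA", polarized$polarity)
  alt <- ifelse(pol %in% c("INS", "DEL"), sprintf("<%s>", pol),
                ifelse(polarized$pav_type == "ref_insertion", "<INS>", "<DEL>"))
  fam <- vapply(polarized$unit_families, function(u)
    paste(u, collapse = ","), "")
  info <- sprintf("SVLEN=%d;TEFAM=%s;POLARITY=%s%s", polarized$length, fam,
                  pol, ifelse(polarized$dte, ";DTE", ""))
  header <- c("##fileformat=VCFv4.2",
    "##ALT=<ID=INS,Description=\"TE insertion relative to the ancestral state\">",
    "##ALT=<ID=DEL,Description=\"TE deletion relative to the ancestral state\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Variant length\">",
    "##INFO=<ID=TEFAM,Number=.,Type=String,Description=\"TE families of the member units\">",
    "##INFO=<ID=POLARITY,Number=1,Type=String,Description=\"INS/DEL relative to the outgroup ancestral state\">",
    "##INFO=<ID=DTE,Number=0,Type=Flag,Description=\"Derived TE variation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(states)), collapse = "\t"))
  body <- paste(polarized$ref_chrom, polarized$ref_start + 1L,
                polarized$locus_id, "N", alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
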