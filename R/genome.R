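# Reference genome with gene annotation, and exhaustive per-site
# substitution-effect lookup used by the parallelism randomisation and the
# spectrum-corrected dN/dS.
#
# Coordinates are 0-based half-open internally; user-facing files (gene
# TSV / GFF3) are 1-based inclusive.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 12 reference-strand substitution types
#'
#' @return character vector of \code{"ref>alt"} labels (e.g. \code{"A>C"}).
#' @export
substitution_types <- function() {
  out <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
  out[substr(out, 1, 1) != substr(out, 3, 3)]
}

#' Genome model: sequence plus gene coordinates
#'
#' @param sequence reference nucleotide sequence (single character string
#'   or \code{Biostrings::DNAString}), bases ACGT.
#' @param genes data.frame with columns \code{gene}, \code{start},
#'   \code{end} (0-based half-open) and \code{strand} (\code{"+"} or
#'   \code{"-"}); gene lengths must be multiples of 3.
#' @return a \code{genome_model}: the sequence (character), gene table,
#'   per-gene lengths \code{L_i} and total coding length \code{L_tot}
#'   (overlapping bases counted once), plus cached per-site effect lookups.
#' @export
genome_model <- function(sequence, genes) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  stopifnot(is.data.frame(genes),
            all(c("gene", "start", "end", "strand") %in% names(genes)))
  genes <- genes[, c("gene", "start", "end", "strand")]
  genes$gene <- as.character(genes$gene)
  stopifnot(all(genes$start >= 0), all(genes$end <= L),
            all(genes$end > genes$start),
            all((genes$end - genes$start) %% 3 == 0),
            all(genes$strand %in% c("+", "-")),
            !anyDuplicated(genes$gene))
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% BASES)) stop("sequence must contain only A, C, G, T")
  # coding footprint with overlaps counted once
  coding <- logical(L)
  for (k in seq_len(nrow(genes)))
    coding[(genes$start[k] + 1):genes$end[k]] <- TRUE
  gm <- structure(list(sequence = sequence, bases = bases, genes = genes,
                       L_i = stats::setNames(genes$end - genes$start, genes$gene),
                       L_tot = sum(coding), length = L,
                       base_positions = lapply(stats::setNames(BASES, BASES),
                                               function(b) which(bases == b) - 1L)),
                  class = "genome_model")
  gm$effects <- build_effect_lookup(gm)
  gm
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Genome model: %d bp, %d genes, coding length %d bp\n",
              x$length, nrow(x$genes), x$L_tot))
  invisible(x)
}

revcomp_chr <- function(x) {
  paste(rev(COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# Exhaustive effect lookup: for every coding site (0-based genome
# position) and every alt base (reference-strand), whether the
# substitution is synonymous or nonsynonymous. Sites covered by several
# genes get one row per gene. Returned as a long data.frame plus a
# position -> effect matrix resolving overlaps (nonsynonymous in any
# covering gene wins).
build_effect_lookup <- function(gm) {
  rows <- vector("list", nrow(gm$genes))
  for (k in seq_len(nrow(gm$genes))) {
    g <- gm$genes[k, ]
    glen <- g$end - g$start
    gseq <- substr(gm$sequence, g$start + 1, g$end)
    if (g$strand == "-") gseq <- revcomp_chr(gseq)
    gb <- strsplit(gseq, "", fixed = TRUE)[[1]]
    site <- seq_len(glen) - 1L                      # gene-frame coordinate
    cidx <- site %/% 3L
    cpos <- site %% 3L
    codon_start <- cidx * 3L + 1L
    codons <- substring(gseq, codon_start, codon_start + 2L)
    aa0 <- translate_codons(codons)
    ref_gene <- gb
    # three alternative bases per site, in gene-strand space
    alt_gene <- t(vapply(ref_gene, function(b) setdiff(BASES, b),
                         character(3)))
    eff <- matrix(NA_character_, nrow = glen, ncol = 3)
    for (a in 1:3) {
      mut <- codons
      substr(mut, cpos + 1L, cpos + 1L) <- alt_gene[, a]
      aa1 <- translate_codons(mut)
      eff[, a] <- ifelse(aa1 == aa0, "synonymous", "nonsynonymous")
    }
    # map back to reference-strand genome coordinates and alleles
    if (g$strand == "+") {
      gpos <- g$start + site
      alt_ref <- alt_gene
    } else {
      gpos <- g$end - 1L - site
      alt_ref <- matrix(COMPLEMENT[alt_gene], nrow = glen)
    }
    rows[[k]] <- data.frame(gene = g$gene,
                            position = rep(gpos, 3L),
                            alt = as.vector(alt_ref),
                            effect = as.vector(eff),
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  # overlap-resolved position x alt matrix: 0 = noncoding, 1 = syn, 2 = nonsyn
  m <- matrix(0L, nrow = gm$length, ncol = 4,
              dimnames = list(NULL, BASES))
  code <- ifelse(long$effect == "nonsynonymous", 2L, 1L)
  idx <- cbind(long$position + 1L, match(long$alt, BASES))
  # nonsynonymous in any covering gene dominates
  m[idx] <- pmax(m[idx], code)
  list(long = long, matrix = m)
}

#' Genes covering a set of genome positions
#'
#' @param gm a \code{\link{genome_model}}.
#' @param positions 0-based genome positions.
#' @return list (per position) of covering gene ids (possibly empty, or
#'   several for overlapping genes).
#' @export
genes_at <- function(gm, positions) {
  lapply(positions, function(p) {
    hit <- gm$genes$start <= p & p < gm$genes$end
    gm$genes$gene[hit]
  })
}

#' Classify the coding effect of a single-nucleotide substitution
#'
#' Intergenic if the position lies outside all annotated genes; otherwise
#' the affected codon is translated (standard genetic code, strand-aware)
#' before and after the substitution: synonymous iff the amino acid is
#' unchanged. A site covered by overlapping genes is called nonsynonymous
#' if the change is nonsynonymous in any covering gene.
#'
#' @param gm a \code{\link{genome_model}}.
#' @param position 0-based genome position(s).
#' @param alt alternative base(s) on the reference strand.
#' @return character vector: \code{"synonymous"}, \code{"nonsynonymous"}
#'   or \code{"intergenic"}.
#' @export
classify_snp_effect <- function(gm, position, alt) {
  stopifnot(inherits(gm, "genome_model"))
  if (any(position < 0 | position >= gm$length))
    stop("position out of range")
  alt <- toupper(alt)
  if (!all(alt %in% BASES)) stop("alt must be one of A, C, G, T")
  ref <- gm$bases[position + 1L]
  if (any(ref == alt)) stop("alt must differ from the reference base")
  code <- gm$effects$matrix[cbind(position + 1L, match(alt, BASES))]
  c("intergenic", "synonymous", "nonsynonymous")[code + 1L]
}

# ---- file round-tripping ---------------------------------------------------

#' Write a genome model to FASTA plus a gene table
#'
#' The gene table is a 4-column TSV (gene, start, end, strand) with 1-based
#' inclusive coordinates, the convention of GFF-style annotation.
#'
#' @param gm a \code{\link{genome_model}}.
#' @param fasta_path,genes_path output files.
#' @param name sequence name for the FASTA header.
#' @export
write_genome <- function(gm, fasta_path, genes_path, name = "synthetic_chr") {
  seq <- Biostrings::DNAStringSet(gm$sequence)
  names(seq) <- name
  Biostrings::writeXStringSet(seq, fasta_path)
  g <- gm$genes
  out <- data.frame(gene = g$gene, start = g$start + 1L, end = g$end,
                    strand = g$strand)
  utils::write.table(out, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, genes = genes_path))
}

#' Read a genome model from FASTA plus a gene table
#'
#' @param fasta_path reference FASTA (first sequence used).
#' @param genes_path 4-column TSV (gene, start, end, strand), 1-based
#'   inclusive coordinates.
#' @return a \code{\link{genome_model}}.
#' @export
read_genome <- function(fasta_path, genes_path) {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  g <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(g)))
  genes <- data.frame(gene = g$gene, start = g$start - 1L, end = g$end,
                      strand = g$strand)
  genome_model(as.character(seq[[1]]), genes)
}

# ---- SNP tables ------------------------------------------------------------

#' Annotate a SNP table with gene and effect
#'
#' Recomputes (or fills in) the \code{gene} and \code{effect} columns of a
#' per-clone SNP table from the genome model. SNPs in overlapping genes
#' are assigned to every covering gene for gene-level counting; the
#' reported \code{gene} column keeps the first.
#'
#' @param table data.frame with columns \code{clone}, \code{position}
#'   (0-based), \code{ref}, \code{alt}.
#' @param gm a \code{\link{genome_model}}.
#' @return the table with \code{gene} (NA for intergenic) and
#'   \code{effect} columns.
#' @export
annotate_snps <- function(table, gm) {
  stopifnot(all(c("clone", "position", "ref", "alt") %in% names(table)))
  if (nrow(table) == 0L) {
    table$gene <- character(0); table$effect <- character(0)
    return(table)
  }
  ref_gm <- gm$bases[table$position + 1L]
  if (!all(ref_gm == toupper(table$ref)))
    stop("ref allele mismatch with the genome sequence")
  table$effect <- classify_snp_effect(gm, table$position, table$alt)
  gl <- genes_at(gm, table$position)
  table$gene <- vapply(gl, function(g) if (length(g)) g[1] else NA_character_,
                       character(1))
  table
}

#' Substitution spectrum of a SNP table
#'
#' @param table data.frame with \code{ref} and \code{alt} columns.
#' @param types which substitution types to tabulate (default the 12
#'   reference-strand types).
#' @return named integer vector of counts over the types.
#' @export
spectrum_counts <- function(table, types = substitution_types()) {
  key <- paste0(toupper(table$ref), ">", toupper(table$alt))
  if (!all(key %in% types)) stop("ref/alt pair outside the expected types")
  tab <- table(factor(key, levels = types))
  stats::setNames(as.integer(tab), types)
}

#' Collapse a 12-type spectrum to 6 strand-symmetric types
#'
#' @param spectrum named counts over the 12 reference-strand types.
#' @return named counts over the 6 pyrimidine-anchored types
#'   (\code{"C>A"}, \code{"C>G"}, \code{"C>T"}, \code{"T>A"},
#'   \code{"T>C"}, \code{"T>G"}).
#' @export
collapse_spectrum <- function(spectrum) {
  canon <- function(type) {
    ref <- substr(type, 1, 1); alt <- substr(type, 3, 3)
    if (ref %in% c("A", "G"))
      paste0(COMPLEMENT[ref], ">", COMPLEMENT[alt])
    else type
  }
  keys <- vapply(names(spectrum), canon, character(1))
  out <- tapply(spectrum, keys, sum)
  stats::setNames(as.integer(out), names(out))
}
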