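# Shared fixtures, built in code. All genomes are tiny synthetic coding
# sequences; nothing is read from disk unless a test writes it first.

# A deterministic 2-gene toy genome with one gene on each strand.
# Layout (0-based):  5 bp spacer | gene_plus (12 bp) | 4 bp spacer |
#                    gene_minus (12 bp) | 5 bp spacer
# gene_plus  CDS:  ATG GGT CGA TAA
# gene_minus CDS:  ATG CAT AAA TGA  (stored reverse-complemented)
toy_genome <- function() {
  plus <- "ATGGGTCGATAA"
  minus_cds <- "ATGCATAAATGA"
  minus <- paste(rev(strsplit(chartr("ACGT", "TGCA", minus_cds), "")[[1]]),
                 collapse = "")
  seq <- paste0("ACACA", plus, "TTTT", minus, "GCGCG")
  genes <- data.frame(gene = c("plus1", "minus1"),
                      start = c(5L, 21L), end = c(17L, 33L),
                      strand = c("+", "-"))
  genome_model(seq, genes)
}

# brute-force effect oracle: mutate the raw sequence string, re-extract the
# gene, translate both strands with Biostrings, compare proteins
brute_force_effect <- function(gm, position, alt) {
  covering <- genes_at(gm, position)[[1]]
  if (length(covering) == 0L) return("intergenic")
  effects <- vapply(covering, function(gname) {
    g <- gm$genes[gm$genes$gene == gname, ]
    mutseq <- gm$sequence
    substr(mutseq, position + 1L, position + 1L) <- alt
    extract <- function(s) {
      cds <- substr(s, g$start + 1L, g$end)
      if (g$strand == "-")
        cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      # no.init.codon: plain codon translation, as variant annotation does
      # (an ATG -> CTG start change is an M -> L amino-acid change, even
      # though CTG can initiate)
      as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                         if.fuzzy.codon = "solve",
                                         no.init.codon = TRUE))
    }
    if (extract(gm$sequence) == extract(mutseq)) "synonymous" else "nonsynonymous"
  }, character(1))
  if (any(effects == "nonsynonymous")) "nonsynonymous" else "synonymous"
}

# exhaustive log-likelihood grid oracle for the MSS estimator
mss_grid_oracle <- function(r, grid = seq(0.05, 20, by = 0.05)) {
  ll <- vapply(grid, function(m) {
    p <- ld_pmf(m, max(100, 2 * max(r) + 10))
    sum(log(pmax(p[r + 1], 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}
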