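# Synthetic-data generators: every input the pipeline consumes can be
# produced at desk scale with known ground truth (genomes with coding
# genes, SNP tables with a specified substitution spectrum and planted
# parallel targets, Luria-Delbruck culture counts, and two-clone CFU
# series with a known selection coefficient). Each generator is a pure
# function of its parameters and the RNG state; emitted files ship with a
# JSON ground-truth sidecar.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n, base_prob) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    b <- matrix(sample(BASES, 3 * length(need), replace = TRUE,
                       prob = base_prob), ncol = 3)
    cand <- paste0(b[, 1], b[, 2], b[, 3])
    ok <- !(cand %in% STOP_CODONS)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a random coding genome
#'
#' Builds a synthetic genome of \code{n_genes} protein-coding genes
#' (start codon, random internal sense codons, stop codon) separated by
#' random intergenic spacers, with genes alternating between the two
#' strands. Base composition is controlled by \code{gc_content}. The
#' genome is random sequence, not derived from any organism; it exists so
#' the pipeline runs without downloads.
#'
#' @param n_genes number of genes.
#' @param gene_length gene length in bases (multiple of 3, >= 9).
#' @param intergenic_length spacer length between (and flanking) genes.
#' @param gc_content GC fraction in (0, 1).
#' @return a \code{\link{genome_model}}.
#' @export
make_genome <- function(n_genes = 100, gene_length = 300,
                        intergenic_length = 100, gc_content = 0.5) {
  stopifnot(n_genes >= 1, gene_length %% 3 == 0, gene_length >= 9,
            intergenic_length >= 0, gc_content > 0, gc_content < 1)
  base_prob <- c((1 - gc_content) / 2, gc_content / 2,
                 gc_content / 2, (1 - gc_content) / 2)
  spacer <- function(n) paste(sample(BASES, n, replace = TRUE,
                                     prob = base_prob), collapse = "")
  n_codons <- gene_length / 3 - 2
  pieces <- character(2 * n_genes + 1)
  pieces[1] <- spacer(intergenic_length)
  genes <- data.frame(gene = sprintf("gene%03d", seq_len(n_genes)),
                      start = 0L, end = 0L,
                      strand = rep(c("+", "-"), length.out = n_genes))
  at <- intergenic_length
  for (k in seq_len(n_genes)) {
    cds <- paste0("ATG", paste(random_codons(n_codons, base_prob),
                               collapse = ""),
                  sample(STOP_CODONS, 1))
    if (genes$strand[k] == "-") cds <- revcomp_chr(cds)
    pieces[2 * k] <- cds
    genes$start[k] <- at
    genes$end[k] <- at + gene_length
    at <- at + gene_length
    pieces[2 * k + 1] <- spacer(intergenic_length)
    at <- at + intergenic_length
  }
  genome_model(paste(pieces, collapse = ""), genes)
}

#' Default substitution spectrum for synthetic SNP tables
#'
#' A transition-biased spectrum (transitions 4x transversions, the broad
#' shape typical of proofreading-deficient enterobacteria) scaled to a
#' requested per-clone SNP count.
#'
#' @param total total SNP count the spectrum should sum to.
#' @return named counts over the 12 reference-strand types.
#' @export
default_spectrum <- function(total = 250) {
  types <- substitution_types()
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  w <- ifelse(types %in% transitions, 4, 1)
  exact <- total * w / sum(w)
  counts <- floor(exact)
  # largest-remainder apportionment of the rounding deficit
  rem <- total - sum(counts)
  if (rem > 0) {
    take <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), types)
}

# pick a nonsynonymous (site, alt) inside a gene, uniformly
sample_ns_site <- function(gm, gene) {
  long <- gm$effects$long
  cand <- long[long$gene == gene & long$effect == "nonsynonymous", ]
  if (nrow(cand) == 0L) stop(sprintf("gene %s has no nonsynonymous site", gene))
  cand[sample.int(nrow(cand), 1L), ]
}

#' Generate a per-clone SNP table with optional planted parallel targets
#'
#' Background SNPs are placed independently per clone by the
#' spectrum-preserving null (\code{\link{randomize_snps}}), so per-type
#' counts equal the spectrum exactly in every clone. Planted targets then
#' receive one extra nonsynonymous SNP in each of \code{n_clones_hit}
#' distinct clones, emulating parallel adaptive mutation.
#'
#' @param gm a \code{\link{genome_model}}.
#' @param spectrum per-clone background spectrum (named \code{"ref>alt"}
#'   counts).
#' @param n_clones number of clones.
#' @param planted optional data.frame with columns \code{gene} and
#'   \code{n_clones_hit}.
#' @return list with \code{table} (columns \code{clone}, \code{position},
#'   \code{ref}, \code{alt}, \code{gene}, \code{effect}, \code{planted})
#'   and \code{truth} (generator parameters and planted targets).
#' @export
make_snp_table <- function(gm, spectrum = default_spectrum(), n_clones = 10,
                           planted = NULL) {
  stopifnot(inherits(gm, "genome_model"), n_clones >= 1)
  clones <- sprintf("clone%02d", seq_len(n_clones))
  rows <- lapply(clones, function(cl) {
    tab <- randomize_snps(gm, spectrum)
    if (nrow(tab) == 0L) return(NULL)
    cbind(clone = cl, tab, planted = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(planted) && nrow(planted) > 0L) {
    stopifnot(all(c("gene", "n_clones_hit") %in% names(planted)),
              all(planted$gene %in% gm$genes$gene),
              all(planted$n_clones_hit <= n_clones))
    extra <- lapply(seq_len(nrow(planted)), function(k) {
      hit_clones <- sample(clones, planted$n_clones_hit[k])
      do.call(rbind, lapply(hit_clones, function(cl) {
        site <- sample_ns_site(gm, planted$gene[k])
        data.frame(clone = cl, position = site$position,
                   ref = gm$bases[site$position + 1L], alt = site$alt,
                   effect = "nonsynonymous", gene = site$gene,
                   planted = TRUE)
      }))
    })
    tab <- rbind(tab, do.call(rbind, extra))
  }
  tab <- tab[order(tab$clone, tab$position), , drop = FALSE]
  rownames(tab) <- NULL
  truth <- list(n_clones = n_clones, spectrum = as.list(spectrum),
                planted = if (is.null(planted)) list() else planted)
  list(table = tab, truth = truth)
}

#' Generate fluctuation-assay count tables for several clones
#'
#' Wraps \code{\link{simulate_cultures}} per clone; clones may have
#' different planted mutation rates (e.g. ancestor vs mutator).
#'
#' @param rates named vector of mutation rates per cell per generation,
#'   one per clone.
#' @param Nt final cell count per culture; a scalar, or one value per
#'   clone (strong mutators are assayed at smaller effective culture
#'   sizes, as plating a dilution does experimentally, so that
#'   \code{m = rate * Nt} stays in the estimable range).
#' @param n_cultures parallel cultures per clone.
#' @return list with \code{table} (columns \code{clone}, \code{culture},
#'   \code{Nt}, \code{r}) and \code{truth} (the planted rates).
#' @export
make_fluctuation_data <- function(rates, Nt = 4e9, n_cultures = 20) {
  if (is.null(names(rates))) names(rates) <- sprintf("clone%02d", seq_along(rates))
  if (length(Nt) == 1L) Nt <- rep(Nt, length(rates))
  stopifnot(length(Nt) == length(rates))
  names(Nt) <- names(rates)
  rows <- lapply(names(rates), function(cl) {
    ex <- simulate_cultures(rates[[cl]], Nt[[cl]], n_cultures)
    data.frame(clone = cl, culture = seq_len(n_cultures), Nt = ex$Nt, r = ex$r)
  })
  list(table = do.call(rbind, rows),
       truth = list(rates = as.list(rates), Nt = as.list(Nt),
                    n_cultures = n_cultures))
}

#' Generate a two-clone competition CFU series with a known selection
#' coefficient
#'
#' The underlying log ratio \code{ln(A/B)} declines deterministically at
#' \code{s} per generation from \code{log(initial_ratio)}; observed counts
#' are a binomial split of \code{sampling_depth} colonies per time point,
#' emulating plate counts of two marked clones.
#'
#' @param s selection coefficient per generation of clone A relative to B
#'   (negative = decline).
#' @param generations_per_day conversion constant (19 in the gut).
#' @param days number of days sampled (time points at 0..days).
#' @param initial_ratio initial A:B ratio.
#' @param sampling_depth colonies counted per time point.
#' @return list with \code{table} (columns \code{time}, \code{countA},
#'   \code{countB}) and \code{truth} (\code{s}, conversions).
#' @export
make_competition_counts <- function(s, generations_per_day = 19, days = 3,
                                    initial_ratio = 5, sampling_depth = 500) {
  stopifnot(sampling_depth >= 1, generations_per_day > 0, days >= 1,
            initial_ratio > 0)
  time <- 0:days
  lr <- log(initial_ratio) + s * time * generations_per_day
  pA <- exp(lr) / (1 + exp(lr))
  countA <- stats::rbinom(length(time), sampling_depth, pA)
  countB <- sampling_depth - countA
  list(table = data.frame(time = time, countA = countA, countB = countB),
       truth = list(s = s, generations_per_day = generations_per_day,
                    initial_ratio = initial_ratio,
                    sampling_depth = sampling_depth))
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' @param x a list with elements \code{table} and \code{truth} as returned
#'   by the \code{make_*} generators.
#' @param path output TSV path; the sidecar is written next to it as
#'   \code{<path>.truth.json}.
#' @param seed the seed used to generate the dataset, recorded in the
#'   sidecar.
#' @export
write_synthetic <- function(x, path, seed = NULL) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- x$truth
  truth$seed <- seed
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
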