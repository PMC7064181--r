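# Spectrum-preserving randomisation test for parallel (adaptive)
# mutational targets across hypermutator clones, based on per-gene
# G scores compared to randomised datasets, plus the simple cross-host
# parallel-target listing used for nonmutator clones.

#' Expected number of nonsynonymous SNPs in a gene
#'
#' \code{E_i = N_tot * L_i / L_tot}: hits proportional to gene length.
#'
#' @param N_tot total number of (nonsynonymous) SNPs.
#' @param L_i gene length in bases.
#' @param L_tot total coding length in bases (> 0).
#' @return expected count \code{E_i}.
#' @export
expected_count <- function(N_tot, L_i, L_tot) {
  if (any(L_tot <= 0)) stop("L_tot must be > 0")
  N_tot * L_i / L_tot
}

#' Per-gene G score
#'
#' \code{G_i = 2 * N_i * ln(N_i / E_i)}, with \code{G_i = 0} when
#' \code{N_i = 0}. \code{N_i} may be non-integer (the halving correction
#' divides counts by 2).
#'
#' @param N_i observed count (>= 0).
#' @param E_i expected count (> 0).
#' @return G score (vectorised).
#' @export
g_score <- function(N_i, E_i) {
  if (any(E_i <= 0)) stop("E_i must be > 0")
  if (any(N_i < 0)) stop("N_i must be >= 0")
  out <- ifelse(N_i == 0, 0, 2 * N_i * log(N_i / E_i))
  unname(out)
}

#' Randomly redistribute SNPs preserving the substitution spectrum
#'
#' For each substitution type (e.g. \code{"A>C"}) with count c in the
#' spectrum, places c SNPs uniformly at random among genome positions
#' whose reference base matches the type, anywhere on the genome (coding
#' or intergenic); the effect of each placed SNP is then classified.
#' Per-type counts are preserved exactly.
#'
#' @param gm a \code{\link{genome_model}}.
#' @param spectrum named counts over the 12 reference-strand
#'   \code{"ref>alt"} types (see \code{\link{substitution_types}}; a
#'   6-type strand-collapsed tally can be made with
#'   \code{\link{collapse_spectrum}} for reporting, but placement always
#'   works on reference-strand types).
#' @return data.frame of SNP records: \code{position}, \code{ref},
#'   \code{alt}, \code{effect}, \code{gene}.
#' @export
randomize_snps <- function(gm, spectrum) {
  stopifnot(inherits(gm, "genome_model"))
  spectrum <- spectrum[spectrum > 0]
  if (length(spectrum) == 0L)
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), effect = character(),
                      gene = character()))
  types <- names(spectrum)
  if (any(is.na(types)) || !all(grepl("^[ACGT]>[ACGT]$", types)))
    stop("spectrum names must be 'ref>alt' over ACGT")
  full <- substitution_types()
  if (!all(types %in% full) || any(duplicated(types))) stop("bad spectrum types")
  pos <- integer(0); ref <- character(0); alt <- character(0)
  for (t in types) {
    b <- substr(t, 1, 1); a <- substr(t, 3, 3)
    cand <- gm$base_positions[[b]]
    if (length(cand) == 0L)
      stop(sprintf("reference base %s absent from the genome", b))
    k <- spectrum[[t]]
    pos <- c(pos, cand[sample.int(length(cand), k, replace = TRUE)])
    ref <- c(ref, rep(b, k)); alt <- c(alt, rep(a, k))
  }
  eff <- classify_snp_effect(gm, pos, alt)
  gl <- genes_at(gm, pos)
  data.frame(position = pos, ref = ref, alt = alt, effect = eff,
             gene = vapply(gl, function(g) if (length(g)) g[1] else NA_character_,
                           character(1)))
}

# gene-level counts of nonsynonymous SNPs; overlapping genes each count
# the SNP (synthetic genomes have no overlaps, so Ntot = sum of counts)
gene_ns_counts <- function(table, gm) {
  ns <- table[table$effect == "nonsynonymous", , drop = FALSE]
  counts <- stats::setNames(numeric(nrow(gm$genes)), gm$genes$gene)
  if (nrow(ns) > 0L) {
    gl <- genes_at(gm, ns$position)
    hits <- unlist(gl)
    if (length(hits)) {
      tab <- table(hits)
      counts[names(tab)] <- as.numeric(tab)
    }
  }
  list(counts = counts, N_tot = nrow(ns), ns = ns)
}

#' Spectrum-preserving randomisation test for parallel mutational targets
#'
#' Tests, per gene, whether more independent nonsynonymous SNPs accumulated
#' across clones than expected given gene length and the observed
#' substitution spectrum. The procedure: (1) the substitution spectrum of
#' all SNPs (synonymous, nonsynonymous and intergenic) is tabulated;
#' (2) \code{n_sims} spectrum-preserving randomised datasets are generated
#' with \code{\link{randomize_snps}} and a per-gene G score computed from
#' the nonsynonymous SNPs of each; (3) the observed per-gene G score is
#' computed, with observed \code{N_i} and \code{N_tot} halved when
#' \code{halve} is on (a conservative correction for up to 2-fold
#' mutation-rate variation along the genome); (4) per-gene Z scores
#' \code{Z_i = (G_obs - mean(G_sim)) / sd(G_sim)} are converted to
#' one-sided upper-tail normal p-values and Benjamini-Hochberg adjusted
#' across all genes with at least one observed nonsynonymous SNP;
#' (5) candidate targets are the genes hit in at least \code{min_clones}
#' distinct clones with \code{q < alpha}.
#'
#' @param table SNP table (columns \code{clone}, \code{position},
#'   \code{ref}, \code{alt}, and optionally \code{effect}; effects are
#'   recomputed if absent).
#' @param gm a \code{\link{genome_model}}.
#' @param n_sims number of randomised datasets (default 100).
#' @param halve apply the conservative halving of observed counts
#'   (default TRUE).
#' @param min_clones minimum number of distinct clones hit for a gene to
#'   be a candidate (default 3).
#' @param alpha BH-adjusted significance cutoff for candidates
#'   (default 0.05).
#' @return data.frame of class \code{parallelism_result}, one row per gene
#'   with >= 1 observed nonsynonymous SNP: \code{gene}, \code{N_i} (after
#'   halving, when applied), \code{E_i}, \code{n_clones_hit}, \code{G_obs},
#'   \code{G_sim_mean}, \code{G_sim_sd}, \code{Z}, \code{p}, \code{q},
#'   \code{candidate}; sorted by \code{q}. The per-gene simulated G matrix
#'   is attached as attribute \code{"G_sim"}.
#' @export
parallelism_test <- function(table, gm, n_sims = 100, halve = TRUE,
                             min_clones = 3, alpha = 0.05) {
  stopifnot(inherits(gm, "genome_model"), n_sims >= 2, nrow(table) > 0)
  if (is.null(table$effect))
    table$effect <- classify_snp_effect(gm, table$position, table$alt)
  spectrum <- spectrum_counts(table)
  L_i <- gm$L_i; L_tot <- gm$L_tot
  obs <- gene_ns_counts(table, gm)
  # distinct clones with a nonsynonymous hit, per gene
  clones_hit <- stats::setNames(integer(length(L_i)), names(L_i))
  if (nrow(obs$ns) > 0L) {
    gl <- genes_at(gm, obs$ns$position)
    reps <- lengths(gl)
    df <- data.frame(gene = unlist(gl), clone = rep(obs$ns$clone, reps))
    tab <- tapply(df$clone, df$gene, function(x) length(unique(x)))
    clones_hit[names(tab)] <- as.integer(tab)
  }
  # simulated G per gene per randomised dataset
  G_sim <- matrix(0, nrow = length(L_i), ncol = n_sims,
                  dimnames = list(names(L_i), NULL))
  for (k in seq_len(n_sims)) {
    sim <- randomize_snps(gm, spectrum)
    sc <- gene_ns_counts(sim, gm)
    # a dataset without nonsynonymous SNPs contributes all-zero G scores
    if (sc$N_tot == 0L) next
    E <- expected_count(sc$N_tot, L_i, L_tot)
    G_sim[, k] <- g_score(sc$counts, E)
  }
  if (obs$N_tot == 0L)
    stop("no nonsynonymous SNPs observed; nothing to test")
  # observed G with the conservative halving
  div <- if (halve) 2 else 1
  N_obs <- obs$counts / div
  E_obs <- expected_count(obs$N_tot / div, L_i, L_tot)
  G_obs <- g_score(N_obs, E_obs)
  mu <- rowMeans(G_sim)
  sdv <- apply(G_sim, 1, stats::sd)
  tested <- obs$counts >= 1
  degenerate <- tested & sdv == 0
  if (any(degenerate)) {
    warning(sprintf("%d gene(s) with zero simulation sd excluded: %s",
                    sum(degenerate),
                    paste(names(L_i)[degenerate], collapse = ", ")))
    tested <- tested & !degenerate
  }
  genes <- names(L_i)[tested]
  Z <- (G_obs[tested] - mu[tested]) / sdv[tested]
  p <- stats::pnorm(Z, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = genes, N_i = N_obs[tested], E_i = E_obs[tested],
                    n_clones_hit = clones_hit[tested],
                    G_obs = G_obs[tested], G_sim_mean = mu[tested],
                    G_sim_sd = sdv[tested], Z = Z, p = p, q = q)
  res$candidate <- res$n_clones_hit >= min_clones & res$q < alpha
  res <- res[order(res$q, -res$Z), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "G_sim") <- G_sim
  class(res) <- c("parallelism_result", class(res))
  res
}

#' Empirical (permutation) p-values for a parallelism result
#'
#' Upper-tail empirical p-values of the observed G scores against the
#' simulated G distribution kept by \code{\link{parallelism_test}}; an
#' independent check on the normal-tail approximation behind \code{Z}.
#'
#' @param res a \code{parallelism_result}.
#' @return numeric vector of permutation p-values, aligned with
#'   \code{res$gene}, computed as \code{(1 + #\{G_sim >= G_obs\}) /
#'   (1 + n_sims)}.
#' @export
permutation_p <- function(res) {
  G_sim <- attr(res, "G_sim")
  if (is.null(G_sim)) stop("result carries no simulated G matrix")
  n <- ncol(G_sim)
  vapply(seq_len(nrow(res)), function(k) {
    g <- G_sim[res$gene[k], ]
    (1 + sum(g >= res$G_obs[k])) / (1 + n)
  }, numeric(1))
}

#' Cross-host parallel mutational targets
#'
#' The listing used for nonmutator clones, where mutation counts are so
#' low that any target independently mutated in more than one clone is a
#' candidate for adaptation.
#'
#' @param hits data.frame with columns \code{clone}, \code{host} and
#'   \code{target} (gene or named operon/intergenic unit), one row per
#'   mutated target per clone.
#' @return data.frame of targets mutated in >= 2 distinct clones, with
#'   \code{n_clones} and \code{n_hosts}, sorted by decreasing host count.
#' @export
cross_host_parallel_targets <- function(hits) {
  stopifnot(all(c("clone", "host", "target") %in% names(hits)))
  if (length(unique(hits$clone)) < 2L) stop("need >= 2 clones")
  hits <- unique(hits[, c("clone", "host", "target")])
  n_clones <- tapply(hits$clone, hits$target, function(x) length(unique(x)))
  n_hosts <- tapply(hits$host, hits$target, function(x) length(unique(x)))
  keep <- n_clones >= 2
  out <- data.frame(target = names(n_clones)[keep],
                    n_clones = as.integer(n_clones[keep]),
                    n_hosts = as.integer(n_hosts[keep]))
  out <- out[order(-out$n_hosts, -out$n_clones, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
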