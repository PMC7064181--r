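# Observed, expected (spectrum-corrected) and normalised dN/dS per clone.
#
# Because the probability that an SNP is nonsynonymous differs between
# substitution types (e.g. transitions at third codon positions are often
# synonymous), the raw N/S ratio is normalised by its expectation under the
# clone's own mutational spectrum, obtained by exhaustive enumeration of
# all coding (site, alt) opportunities in the genome.

#' Observed nonsynonymous and synonymous counts
#'
#' @param table SNP table with an \code{effect} column (intergenic SNPs are
#'   ignored).
#' @return named integer vector \code{c(N = ..., S = ...)}.
#' @export
observed_ns <- function(table) {
  if (nrow(table) == 0L) return(c(N = 0L, S = 0L))
  c(N = sum(table$effect == "nonsynonymous"),
    S = sum(table$effect == "synonymous"))
}

#' Expected N/S ratio under a substitution spectrum
#'
#' For each substitution type, all coding (site, alt) opportunities in the
#' genome are enumerated (each coding site counts once per possible alt
#' allele; stop-gaining changes count as nonsynonymous) and the fraction of
#' nonsynonymous opportunities recorded. Expected N and S are the
#' spectrum-weighted sums of these opportunity fractions; the function
#' returns expected N / expected S.
#'
#' @param gm a \code{\link{genome_model}}.
#' @param spectrum named counts over \code{"ref>alt"} types with positive
#'   total.
#' @return the expected N/S ratio (scalar).
#' @export
expected_ns_ratio <- function(gm, spectrum) {
  stopifnot(inherits(gm, "genome_model"))
  spectrum <- spectrum[spectrum > 0]
  if (length(spectrum) == 0L || sum(spectrum) <= 0)
    stop("spectrum total must be > 0")
  opp <- coding_opportunities(gm)
  expN <- 0; expS <- 0
  for (t in names(spectrum)) {
    row <- opp[opp$type == t, ]
    if (nrow(row) == 0L || row$n_total == 0L) {
      warning(sprintf("substitution type %s has no coding opportunity; excluded", t))
      next
    }
    w <- spectrum[[t]]
    expN <- expN + w * row$n_nonsyn / row$n_total
    expS <- expS + w * row$n_syn / row$n_total
  }
  if (expS <= 0) stop("expected synonymous opportunity is 0; ratio undefined")
  expN / expS
}

# per-substitution-type tallies of coding opportunities (cached on the
# genome model's effect lookup; overlaps resolved as in classify_snp_effect)
coding_opportunities <- function(gm) {
  m <- gm$effects$matrix
  types <- substitution_types()
  out <- data.frame(type = types, n_syn = 0L, n_nonsyn = 0L, n_total = 0L)
  for (k in seq_along(types)) {
    b <- substr(types[k], 1, 1); a <- substr(types[k], 3, 3)
    pos <- gm$base_positions[[b]] + 1L
    code <- m[pos, a]
    out$n_syn[k] <- sum(code == 1L)
    out$n_nonsyn[k] <- sum(code == 2L)
    out$n_total[k] <- out$n_syn[k] + out$n_nonsyn[k]
  }
  out
}

#' Normalised dN/dS with a binomial test
#'
#' \code{dnds_normalized = (N/S) / expected_ns_ratio}; a value of 1 means
#' the clone's N/S matches the neutral expectation under its own spectrum.
#' The p-value is a two-sided binomial test of N nonsynonymous SNPs among
#' N + S coding SNPs with success probability
#' \code{expected_ns_ratio / (1 + expected_ns_ratio)}.
#'
#' @param N,S observed nonsynonymous / synonymous counts (N + S > 0).
#' @param expected_ratio expected N/S ratio (> 0).
#' @return list: \code{dnds_normalized} (NA, flagged, when S = 0),
#'   \code{p}, \code{N}, \code{S}, \code{expected_ns_ratio}.
#' @export
normalized_dnds <- function(N, S, expected_ratio) {
  if (N + S <= 0) stop("N + S must be > 0")
  if (expected_ratio <= 0) stop("expected_ratio must be > 0")
  pr <- expected_ratio / (1 + expected_ratio)
  pval <- stats::binom.test(N, N + S, p = pr)$p.value
  list(dnds_normalized = if (S > 0) (N / S) / expected_ratio else NA_real_,
       p = pval, N = N, S = S, expected_ns_ratio = expected_ratio)
}

#' Per-clone normalised dN/dS
#'
#' Splits a SNP table by clone, tabulates each clone's substitution
#' spectrum (all SNPs, including intergenic), and computes observed,
#' expected and normalised dN/dS with the binomial test.
#'
#' @param table SNP table (columns \code{clone}, \code{position},
#'   \code{ref}, \code{alt}; \code{effect} recomputed if absent).
#' @param gm a \code{\link{genome_model}}.
#' @return data.frame, one row per clone: \code{clone}, \code{N},
#'   \code{S}, \code{expected_ns_ratio}, \code{dnds_normalized}, \code{p}.
#' @export
dnds_per_clone <- function(table, gm) {
  if (is.null(table$effect))
    table$effect <- classify_snp_effect(gm, table$position, table$alt)
  clones <- unique(table$clone)
  rows <- lapply(clones, function(cl) {
    sub <- table[table$clone == cl, , drop = FALSE]
    ns <- observed_ns(sub)
    if (sum(ns) == 0L)
      return(data.frame(clone = cl, N = 0L, S = 0L,
                        expected_ns_ratio = NA_real_,
                        dnds_normalized = NA_real_, p = NA_real_))
    ratio <- expected_ns_ratio(gm, spectrum_counts(sub))
    r <- normalized_dnds(ns[["N"]], ns[["S"]], ratio)
    data.frame(clone = cl, N = r$N, S = r$S,
               expected_ns_ratio = r$expected_ns_ratio,
               dnds_normalized = r$dnds_normalized, p = r$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
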