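test_that("observed N and S count only coding SNPs", {
  expect_equal(observed_ns(data.frame()), c(N = 0L, S = 0L))
  tab <- data.frame(effect = c("nonsynonymous", "nonsynonymous",
                               "nonsynonymous", "synonymous"))
  expect_equal(observed_ns(tab), c(N = 3L, S = 1L))
  inter <- data.frame(effect = rep("intergenic", 4))
  expect_equal(observed_ns(inter), c(N = 0L, S = 0L))
})

test_that("ATG-only toy gene makes every third-position G>A nonsynonymous", {
  # gene of repeated ATG codons (Met is encoded only by ATG, so any change
  # is nonsynonymous) closed by TAA; G>A has zero synonymous opportunity
  cds <- paste0("ATG", strrep("ATG", 10), "TAA")
  seq <- paste0("CC", cds, "CC")
  gm <- genome_model(seq, data.frame(gene = "metgene", start = 2L,
                                     end = 2L + nchar(cds), strand = "+"))
  opp <- hypermutr:::coding_opportunities(gm)
  ga <- opp[opp$type == "G>A", ]
  expect_gt(ga$n_nonsyn, 0)
  expect_equal(ga$n_syn, 0)
  # a spectrum of only G>A therefore has expected S = 0: undefined ratio
  expect_error(expected_ns_ratio(gm, c("G>A" = 10L)), "undefined")
  expect_error(expected_ns_ratio(gm, c("G>A" = 0L)), "total")
})

test_that("uniform spectrum on a random genome gives an N/S ratio near 3", {
  set.seed(71)
  gm <- make_genome(n_genes = 30, gene_length = 300, intergenic_length = 20)
  sp <- stats::setNames(rep(10L, 12), substitution_types())
  ratio <- expected_ns_ratio(gm, sp)
  expect_gt(ratio, 2); expect_lt(ratio, 4.5)
  # exact check against direct enumeration over all coding opportunities
  opp <- hypermutr:::coding_opportunities(gm)
  expN <- sum(10 * opp$n_nonsyn / opp$n_total)
  expS <- sum(10 * opp$n_syn / opp$n_total)
  expect_equal(ratio, expN / expS, tolerance = 1e-12)
})

test_that("expected ratio is invariant to duplicating the genome", {
  set.seed(72)
  gm <- make_genome(n_genes = 6, gene_length = 90, intergenic_length = 15)
  g2 <- gm$genes
  shift <- gm$length
  g2$start <- g2$start + shift; g2$end <- g2$end + shift
  g2$gene <- paste0(g2$gene, "b")
  gm_dup <- genome_model(paste0(gm$sequence, gm$sequence),
                         rbind(gm$genes, g2))
  sp <- default_spectrum(120)
  expect_equal(expected_ns_ratio(gm, sp), expected_ns_ratio(gm_dup, sp),
               tolerance = 1e-12)
})

test_that("normalised dN/dS and the binomial test match direct computation", {
  r <- normalized_dnds(6, 2, 3)
  expect_equal(r$dnds_normalized, 1)
  expect_equal(r$p, 1, tolerance = 1e-9)
  r0 <- normalized_dnds(0, 10, 3)
  expect_equal(r0$dnds_normalized, 0)
  # independent two-sided binomial p at 0 successes from the density sum
  d <- stats::dbinom(0:10, 10, 0.75)
  expect_equal(r0$p, sum(d[d <= d[1] * (1 + 1e-7)]), tolerance = 1e-9)
  s0 <- normalized_dnds(5, 0, 3)
  expect_true(is.na(s0$dnds_normalized))
  expect_false(is.na(s0$p))
  expect_error(normalized_dnds(0, 0, 3), "N \\+ S")
  expect_error(normalized_dnds(3, 1, 0), "expected_ratio")
})

test_that("spectrum-randomised tables are null-calibrated around dN/dS = 1", {
  set.seed(73)
  gm <- make_genome(n_genes = 40, gene_length = 300, intergenic_length = 20)
  vals <- c(); rej <- c()
  for (k in 1:15) {
    tab <- cbind(clone = "c1", randomize_snps(gm, default_spectrum(400)))
    d <- dnds_per_clone(tab, gm)
    vals <- c(vals, d$dnds_normalized)
    rej <- c(rej, d$p < 0.05)
  }
  se <- sqrt(stats::var(vals) / length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / length(rej)))
})

test_that("per-clone dN/dS handles empty and coding-free clones", {
  set.seed(74)
  gm <- make_genome(n_genes = 5, gene_length = 60, intergenic_length = 40)
  # one clone with only intergenic SNPs
  inter_pos <- which(vapply(genes_at(gm, 0:(gm$length - 1)), length,
                            integer(1)) == 0)[1:3] - 1
  tab <- data.frame(clone = "lonely", position = inter_pos,
                    ref = gm$bases[inter_pos + 1], alt = NA)
  tab$alt <- vapply(tab$ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
  d <- dnds_per_clone(tab, gm)
  expect_equal(d$N, 0L)
  expect_true(is.na(d$dnds_normalized))
})
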