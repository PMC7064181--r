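test_that("expected counts and G scores evaluate the stated formulas", {
  expect_equal(expected_count(100, 10, 1000), 1)
  expect_equal(expected_count(100, 0, 1000), 0)
  expect_equal(expected_count(3245, 1, 1000), 3.245)
  expect_error(expected_count(10, 1, 0), "L_tot")
  expect_equal(g_score(5, 5), 0)
  expect_equal(g_score(0, 2), 0)
  expect_equal(g_score(5, 1), 10 * log(5))
  expect_error(g_score(1, 0), "E_i")
  # monotone in N_i above E_i
  g <- g_score(3:10, 2)
  expect_true(all(diff(g) > 0))
})

test_that("randomisation preserves per-type counts and reference bases", {
  set.seed(61)
  gm <- make_genome(n_genes = 10, gene_length = 90, intergenic_length = 30)
  sp <- c("A>G" = 25L, "C>T" = 13L, "G>C" = 7L)
  tab <- randomize_snps(gm, sp)
  expect_equal(nrow(tab), 45)
  got <- spectrum_counts(tab)
  expect_equal(got[names(sp)], sp)
  expect_equal(sum(got), sum(sp))
  expect_true(all(gm$bases[tab$position + 1] == tab$ref))
  empty <- randomize_snps(gm, c("A>G" = 0L))
  expect_equal(nrow(empty), 0)
})

test_that("placed coding SNPs hit the nonsynonymous fraction from enumeration", {
  set.seed(62)
  gm <- make_genome(n_genes = 20, gene_length = 300, intergenic_length = 20)
  sp <- c("A>G" = 4000L)
  tab <- randomize_snps(gm, sp)
  coding <- tab[tab$effect != "intergenic", ]
  # exhaustive enumeration of all coding A->G opportunities
  long <- gm$effects$long
  ag <- long[long$alt == "G" & gm$bases[long$position + 1] == "A", ]
  frac_oracle <- mean(ag$effect == "nonsynonymous")
  frac_obs <- mean(coding$effect == "nonsynonymous")
  se <- sqrt(frac_oracle * (1 - frac_oracle) / nrow(coding))
  expect_lt(abs(frac_obs - frac_oracle), 3 * se)
})

test_that("bookkeeping: gene hits plus intergenic equals total placed SNPs", {
  set.seed(63)
  gm <- make_genome(n_genes = 15, gene_length = 150, intergenic_length = 50)
  tab <- randomize_snps(gm, default_spectrum(300))
  n_intergenic <- sum(tab$effect == "intergenic")
  n_coding <- sum(tab$effect != "intergenic")
  expect_equal(n_intergenic + n_coding, 300)
  # no overlapping genes in synthetic genomes: gene assignment is unique
  expect_true(all(!is.na(tab$gene[tab$effect != "intergenic"])))
  expect_true(all(is.na(tab$gene[tab$effect == "intergenic"])))
})

test_that("a planted parallel target is recovered at q < 0.05", {
  set.seed(64)
  gm <- make_genome(n_genes = 100, gene_length = 300, intergenic_length = 50)
  made <- make_snp_table(gm, default_spectrum(8), n_clones = 10,
                         planted = data.frame(gene = "gene042",
                                              n_clones_hit = 6))
  res <- parallelism_test(made$table, gm, n_sims = 100)
  row <- res[res$gene == "gene042", ]
  expect_equal(nrow(row), 1)
  expect_lt(row$q, 0.05)
  expect_gte(row$n_clones_hit, 6)
  expect_true(row$candidate)
})

test_that("permutation p-values are concordant with the normal tail for the hit", {
  set.seed(65)
  gm <- make_genome(n_genes = 60, gene_length = 300, intergenic_length = 50)
  made <- make_snp_table(gm, default_spectrum(6), n_clones = 8,
                         planted = data.frame(gene = "gene010",
                                              n_clones_hit = 6))
  res <- parallelism_test(made$table, gm, n_sims = 200)
  pp <- permutation_p(res)
  k <- which(res$gene == "gene010")
  # the planted gene is extreme under both readings of the null
  expect_lt(res$p[k], 0.01)
  expect_lte(pp[k], 2 / 201)
})

test_that("null tables produce no more than the nominal fraction of hits", {
  set.seed(66)
  gm <- make_genome(n_genes = 50, gene_length = 300, intergenic_length = 30)
  fracs <- vapply(1:10, function(k) {
    tab <- make_snp_table(gm, default_spectrum(5), n_clones = 6)$table
    res <- parallelism_test(tab, gm, n_sims = 60)
    if (nrow(res) == 0) return(0)
    mean(res$q < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("relaxing the conservative filters never hurts the planted gene", {
  set.seed(67)
  gm <- make_genome(n_genes = 40, gene_length = 300, intergenic_length = 30)
  made <- make_snp_table(gm, default_spectrum(4), n_clones = 8,
                         planted = data.frame(gene = "gene005",
                                              n_clones_hit = 5))
  set.seed(100); strict <- parallelism_test(made$table, gm, n_sims = 80,
                                            halve = TRUE, min_clones = 3)
  set.seed(100); loose <- parallelism_test(made$table, gm, n_sims = 80,
                                           halve = FALSE, min_clones = 2)
  qs <- strict$q[strict$gene == "gene005"]
  ql <- loose$q[loose$gene == "gene005"]
  expect_lte(ql, qs + 1e-12)
})

test_that("no gene hit in enough clones means no candidates", {
  set.seed(68)
  gm <- make_genome(n_genes = 30, gene_length = 90, intergenic_length = 30)
  # two nonsynonymous SNPs in different genes, one clone each
  long <- gm$effects$long
  ns <- long[long$effect == "nonsynonymous" &
               long$gene %in% c("gene001", "gene002"), ]
  pick <- ns[!duplicated(ns$gene), ]
  tab <- data.frame(clone = c("c1", "c2"), position = pick$position,
                    ref = gm$bases[pick$position + 1], alt = pick$alt)
  # with so few SNPs some genes get a degenerate (all-zero) simulated G
  # distribution and are excluded with a warning
  expect_warning(res <- parallelism_test(tab, gm, n_sims = 20, min_clones = 3),
                 "zero simulation sd")
  expect_false(any(res$candidate))
})

test_that("cross-host parallel targets are listed with host counts", {
  hits <- data.frame(
    clone = c("c1", "c2", "c3", "c4", "c1", "c2", "c1"),
    host = c("m1", "m2", "m3", "m1", "m1", "m2", "m1"),
    target = c("dgoR", "dgoR", "dgoR", "dgoR", "srlR", "srlR", "unique1"))
  out <- cross_host_parallel_targets(hits)
  expect_equal(out$target, c("dgoR", "srlR"))
  expect_equal(out$n_clones, c(4L, 2L))
  expect_equal(out$n_hosts, c(3L, 2L))
  none <- cross_host_parallel_targets(data.frame(
    clone = c("c1", "c2"), host = c("m1", "m2"), target = c("a", "b")))
  expect_equal(nrow(none), 0)
})
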