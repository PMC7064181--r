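test_that("genome arithmetic: n genes and spacers give the stated length", {
  set.seed(81)
  gm <- make_genome(n_genes = 10, gene_length = 300, intergenic_length = 100)
  expect_equal(gm$length, 10 * 300 + 11 * 100)
  expect_equal(nrow(gm$genes), 10)
  expect_setequal(unique(gm$genes$strand), c("+", "-"))
  expect_error(make_genome(gene_length = 100), "gene_length")
})

test_that("generated genes have intact reading frames", {
  set.seed(82)
  gm <- make_genome(n_genes = 8, gene_length = 120, intergenic_length = 10)
  for (k in seq_len(nrow(gm$genes))) {
    g <- gm$genes[k, ]
    cds <- substr(gm$sequence, g$start + 1, g$end)
    if (g$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("GC content of a long genome matches the target within 3 SE", {
  set.seed(83)
  gm <- make_genome(n_genes = 20, gene_length = 300, intergenic_length = 200,
                    gc_content = 0.4)
  gc <- mean(gm$bases %in% c("G", "C"))
  # coding constraint (start/stop codons) distorts composition slightly;
  # allow that plus binomial noise
  expect_lt(abs(gc - 0.4), 3 * sqrt(0.4 * 0.6 / gm$length) + 0.02)
})

test_that("default spectrum sums exactly to the requested total", {
  sp <- default_spectrum(250)
  expect_equal(sum(sp), 250)
  expect_setequal(names(sp), substitution_types())
  # transition bias: each transition type exceeds each transversion type
  expect_gt(min(sp[c("A>G", "G>A", "C>T", "T>C")]),
            max(sp[setdiff(names(sp), c("A>G", "G>A", "C>T", "T>C"))]))
})

test_that("SNP tables carry exact background spectra and planted hits", {
  set.seed(84)
  gm <- make_genome(n_genes = 30, gene_length = 150, intergenic_length = 30)
  sp <- default_spectrum(40)
  made <- make_snp_table(gm, sp, n_clones = 5,
                         planted = data.frame(gene = "gene007",
                                              n_clones_hit = 3))
  tab <- made$table
  for (cl in unique(tab$clone)) {
    bg <- tab[tab$clone == cl & !tab$planted, ]
    expect_equal(spectrum_counts(bg), sp)
  }
  pl <- tab[tab$planted, ]
  expect_equal(nrow(pl), 3)
  expect_equal(unique(pl$gene), "gene007")
  expect_equal(length(unique(pl$clone)), 3)
  expect_true(all(pl$effect == "nonsynonymous"))
  expect_error(make_snp_table(gm, sp, n_clones = 2,
                              planted = data.frame(gene = "nope",
                                                   n_clones_hit = 1)))
})

test_that("fluctuation generator recovers a 1,000-fold mutator end to end", {
  set.seed(85)
  # the mutator is assayed on a 100-fold dilution (smaller effective Nt),
  # as done experimentally, keeping m in the estimable range for both
  d <- make_fluctuation_data(c(anc = 5e-10, mut = 5e-7),
                             Nt = c(anc = 4e9, mut = 4e7), n_cultures = 30)
  by_clone <- split(d$table, d$table$clone)
  est <- lapply(by_clone, function(x)
    estimate_m_mss(fluctuation_experiment(x$Nt, x$r)))
  fold <- mutator_strength(est$mut$rate, est$anc$rate)
  expect_gt(fold, 300); expect_lt(fold, 3000)
  z <- make_fluctuation_data(c(a = 0), Nt = 1e9, n_cultures = 5)
  expect_true(all(z$table$r == 0))
})

test_that("synthetic generators are byte-identical under a fixed seed", {
  gm <- local({ set.seed(86); make_genome(5, 60, 10) })
  set.seed(87); a <- make_snp_table(gm, default_spectrum(20), 3)
  set.seed(87); b <- make_snp_table(gm, default_spectrum(20), 3)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_synthetic(a, f1, seed = 87); write_synthetic(b, f2, seed = 87)
  expect_identical(readLines(f1), readLines(f2))
  truth <- jsonlite::read_json(paste0(f1, ".truth.json"))
  expect_equal(truth$seed, 87)
  unlink(c(f1, f2, paste0(f1, ".truth.json"), paste0(f2, ".truth.json")))
})

test_that("competition counts decline at the planted rate and can hit the floor", {
  set.seed(88)
  d <- make_competition_counts(s = 0, days = 3, sampling_depth = 1000)
  expect_equal(nrow(d$table), 4)
  expect_equal(d$table$countA + d$table$countB, rep(1000, 4))
  crash <- make_competition_counts(s = -0.2, generations_per_day = 19,
                                   days = 3, initial_ratio = 1,
                                   sampling_depth = 50)
  expect_true(any(crash$table$countA == 0))
  lr <- log_ratio_series(crash$table$countA, crash$table$countB)
  expect_true(any(lr$detection_limited))
})
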