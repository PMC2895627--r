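test_that("GC3 target sampling honours weights, clipping and determinism", {
  cfg <- synthetic_config(n_genes = 500, seed = 3,
                          gc3_mixture = list(weight_low = 1, mean_low = 0.6,
                                             sd_low = 0.06, mean_high = 0.9,
                                             sd_high = 0.04))
  t1 <- sample_gc3_targets(cfg)
  expect_true(all(t1$class_true == "low"))
  expect_true(all(t1$target_gc3 >= 0.05 & t1$target_gc3 <= 0.99))
  t2 <- sample_gc3_targets(cfg)
  expect_identical(t1, t2)
  # default mixture: planted valley sits between the component means
  v <- attr(sample_gc3_targets(synthetic_config(n_genes = 100, seed = 1)),
            "planted_valley")
  expect_true(v > 0.7 && v < 0.85)
})

test_that("generated CDS translate back to their protein", {
  set.seed(21)
  for (i in 1:10) {
    g <- generate_cds(120, runif(1, 0.2, 0.95), runif(1, -0.5, 0.5),
                      runif(1, -0.1, 0.1))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(g$sequence)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_equal(strsplit(substr(aa, 2, nchar(aa) - 1), "")[[1]], g$protein)
  }
})

test_that("extreme targets force third positions as designed", {
  tab <- gc3sig:::.codon_tables()
  both <- tab$aa18[tab$n_c > 0 & tab$n_g > 0]  # amino acids with C and G endings
  set.seed(22)
  prot <- sample(both, 200, replace = TRUE)
  g <- generate_cds(target_gc3 = 1, skew = 1, protein = prot)
  thirds <- substring(g$sequence, seq(3, nchar(g$sequence), 3),
                      seq(3, nchar(g$sequence), 3))
  interior <- thirds[2:(length(thirds) - 1)]
  expect_true(all(interior == "C"))          # skew +1 forces C everywhere
  g2 <- generate_cds(target_gc3 = 1, skew = -1, protein = prot)
  thirds2 <- substring(g2$sequence, seq(3, nchar(g2$sequence), 3),
                       seq(3, nchar(g2$sequence), 3))
  expect_true(all(thirds2[2:(length(thirds2) - 1)] == "G"))
  expect_equal(g$n_skew_forced, 0L)
})

test_that("realized GC3 tracks the target", {
  set.seed(23)
  realized <- vapply(1:300, function(i) {
    generate_cds(330, 0.75, 0, 0)$realized_gc3
  }, numeric(1))
  expect_true(mean(realized) > 0.72 && mean(realized) < 0.78)
})

test_that("covariate plants are exact when noise is switched off", {
  cfg <- synthetic_config(n_genes = 1500, seed = 9)
  cfg$expr$noise_sd <- 1e-12
  sim <- simulate_dataset(cfg)
  gc3 <- sim$truth$per_gene$realized_gc3
  sd_true <- sim$truth$per_gene$sd_true
  latent <- (sd_true - cfg$expr$sd_center) / cfg$expr$sd_scale
  ok <- sd_true > 0.051  # away from the positivity floor
  bf <- binned_fit(zscore(gc3)[ok], latent[ok], genes_per_bin = 100)
  expect_equal(bf$fit$slope, cfg$expr$sd_slope, tolerance = 1e-6)
  bf2 <- binned_fit(zscore(gc3)[ok], latent[ok], genes_per_bin = 300)
  expect_equal(bf2$fit$slope, cfg$expr$sd_slope, tolerance = 1e-6)
})

test_that("infeasible intron correlation targets are refused with the bound", {
  cfg <- synthetic_config(n_genes = 300, seed = 5)
  cfg$introns$target_pearson <- -0.99
  expect_error(simulate_dataset(cfg), "infeasible")
})

test_that("planted clumps are found and layouts regenerate identically", {
  cfg <- synthetic_config(n_genes = 800, seed = 13)
  cfg$layout$clump_spec <- list(list(chrom = 1, size = 12))
  sim <- simulate_dataset(cfg)
  lab <- setNames(sim$truth$per_gene$class_true, sim$truth$per_gene$gene_id)
  cr <- find_clumps(sim$table, unname(lab[sim$table$gene_id]),
                    min_size = 12, max_gap_genes = 0)
  expect_gte(nrow(cr$clumps), 1L)
  expect_true(any(cr$clumps$n_high_genes >= 12 & cr$clumps$chrom == "chr01"))
  # asking for more planted high genes than exist fails loudly
  cfg2 <- synthetic_config(n_genes = 60, seed = 13)
  cfg2$layout$clump_spec <- list(list(chrom = 1, size = 500))
  expect_error(simulate_dataset(cfg2), "high genes")
  # same config, same draws
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$cds$sequence, sim2$cds$sequence)
  expect_identical(sim$table$start, sim2$table$start)
})

test_that("planted associations appear in a small end-to-end run", {
  sim <- small_sim()
  comp <- composition_profile(sim$cds)
  # generator truth and pipeline composition agree exactly
  expect_equal(comp$gc3, sim$truth$per_gene$realized_gc3, tolerance = 1e-12)
  # SNP line and intron correlation are in the right regime even at n = 600
  tab <- sim$table
  sf <- snp_fit(comp$gc3, tab$snp_per_kb, genes_per_bin = 60)
  expect_equal(sf$fit$slope, 0.583, tolerance = 0.25)
  expect_lt(pearson_cor(comp$gc3, tab$intron_density), -0.15)
})
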