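test_that("z-scores use the n-1 denominator and are affine invariant", {
  expect_equal(zscore(c(0, 2)), c(-1, 1) / sqrt(2))
  x <- rnorm(50)
  expect_equal(zscore(3 * x - 7), zscore(x))
  expect_equal(mean(zscore(x)), 0, tolerance = 1e-12)
  expect_equal(sd(zscore(x)), 1, tolerance = 1e-12)
  expect_error(zscore(rep(1, 10)), "constant")
})

test_that("expression variability is the per-gene sample SD", {
  cds <- make_cds(g1 = "ATGGCC", g2 = "ATGAAA",
                  policy = validation_policy(min_codons = 1))
  tab <- read_gene_table(cds, covariates = data.frame(
    gene_id = c("g1", "g2"),
    expr_001 = c(5, 1), expr_002 = c(5, 3), expr_003 = c(5, 5)))
  v <- expression_variability(tab)
  expect_equal(unname(v), c(0, 2), ignore_attr = TRUE)
  # too few conditions is an error
  tab2 <- read_gene_table(cds, covariates = data.frame(
    gene_id = c("g1", "g2"), expr_001 = c(1, 2), expr_002 = c(3, 4)))
  expect_error(expression_variability(tab2), ">= 3")
})

test_that("binned fit recovers exact lines at any binning", {
  set.seed(11)
  x <- rnorm(2000)
  bf <- binned_fit(x, x, genes_per_bin = 200)
  expect_equal(bf$fit$slope, 1, tolerance = 1e-9)
  expect_equal(bf$fit$intercept, 0, tolerance = 1e-9)
  expect_equal(bf$fit$r_squared, 1, tolerance = 1e-9)
  bf2 <- binned_fit(x, x, genes_per_bin = 50)
  expect_equal(bf2$fit$slope, bf$fit$slope, tolerance = 1e-9)
  # equal-count bins differ in size by at most one and partition n
  expect_lte(diff(range(bf$bins$n_per_bin)), 1L)
  expect_equal(sum(bf$bins$n_per_bin), 2000L)
  expect_error(binned_fit(x[1:100], x[1:100], genes_per_bin = 200), "smaller")
  # a planted noiseless SNP line comes back exactly
  gc3 <- runif(1000)
  sf <- snp_fit(gc3, 1.114 + 0.583 * gc3, genes_per_bin = 100)
  expect_equal(sf$fit$intercept, 1.114, tolerance = 1e-9)
  expect_equal(sf$fit$slope, 0.583, tolerance = 1e-9)
  # independent y: slope near zero
  bf3 <- binned_fit(rnorm(4000), rnorm(4000), genes_per_bin = 200)
  expect_lt(abs(bf3$fit$slope), 0.1)
})

test_that("pearson_cor flags degenerate inputs", {
  x <- rnorm(100)
  expect_equal(pearson_cor(x, -x), -1)
  expect_warning(r <- pearson_cor(x, rep(2, 100)), "constant")
  expect_true(is.na(r))
  set.seed(12)
  expect_lt(abs(pearson_cor(rnorm(10000), rnorm(10000))), 0.03)
})

test_that("TATA scan is windowed, strand-forward and IUPAC-aware", {
  pad <- function(nt) paste(rep("G", nt), collapse = "")
  # motif ending 35 nt upstream of the TSS: inside the 50 nt window
  p1 <- paste0(pad(500), "TATAAATA", pad(35))
  # motif at -60: outside the window
  p2 <- paste0(pad(500), "TATAAATA", pad(60))
  p3 <- paste0(pad(500), pad(43))
  hits <- tata_scan(c(a = p1, b = p2, c = p3))
  expect_identical(as.logical(hits), c(TRUE, FALSE, FALSE))
  # TATAWAW matches TATATAT too
  expect_true(tata_scan(paste0(pad(100), "TATATAT", pad(10))))
  expect_warning(tata_scan("TATAAATAGG"), "truncated")
})

test_that("indicator frequency curves respond to planted dependence", {
  set.seed(13)
  gc3 <- runif(7000)
  always <- frequency_by_gc3(rep(TRUE, 7000), gc3, genes_per_bin = 700)
  expect_true(all(always$fraction == 1))
  p <- 0.18 + (0.52 - 0.18) * gc3
  ind <- rbinom(7000, 1, p) == 1
  fc <- frequency_by_gc3(ind, gc3, genes_per_bin = 700)
  expect_gt(fc$fraction[nrow(fc)], fc$fraction[1] + 0.2)
  flat <- frequency_by_gc3(rbinom(7000, 1, 0.3) == 1, gc3, genes_per_bin = 700)
  expect_lt(diff(range(flat$fraction)), 0.12)
})

test_that("high-class probability curve and chi-squared behave", {
  set.seed(14)
  n <- 2000
  cov <- rnorm(n)
  # strong dependence: high class iff covariate above median, plus noise
  lab <- ifelse(cov + rnorm(n, 0, 0.5) > 0, "high", "low")
  hp <- high_class_probability(cov, lab, genes_per_bin = 200)
  expect_lt(hp$p_value, 1e-6)
  expect_gt(cor(hp$curve$x_mean, hp$curve$p_high), 0.9)
  # chi-squared equals the closed form on the returned table
  expect_equal(unname(hp$chi2_stat), chi2_closed_form(unclass(hp$table)),
               tolerance = 1e-9)
  # independence: statistic small, p large
  lab2 <- sample(c("high", "low"), n, replace = TRUE)
  hp2 <- high_class_probability(cov, lab2, genes_per_bin = 200)
  expect_equal(unname(hp2$chi2_stat), chi2_closed_form(unclass(hp2$table)),
               tolerance = 1e-9)
  expect_error(high_class_probability(cov[1:50], lab[1:50]), ">= 100")
})

test_that("category profiles recover planted shifts", {
  set.seed(15)
  gc3 <- c(rnorm(100, 0.5, 0.02), rnorm(100, 0.8, 0.02))
  gc12 <- rnorm(200, 0.5, 0.01)
  cats <- rep(c("low_cat", "high_cat"), each = 100)
  cp <- category_profile(gc3, gc12, cats)
  per <- cp$per_category
  expect_equal(per$mean_gc3[per$category == "high_cat"], 0.8, tolerance = 0.02)
  expect_equal(per$mean_gc3[per$category == "low_cat"], 0.5, tolerance = 0.02)
  expect_gt(cp$cv_ratio, 1)
  # identical values within a category: CV exactly 0
  cp2 <- category_profile(rep(0.6, 10), rep(0.5, 10), rep("only", 10))
  expect_equal(cp2$per_category$cv_gc3, 0)
  expect_equal(cp2$per_category$mean_gc3, 0.6)
})

test_that("codon usage matrix normalises within amino-acid blocks", {
  tab <- gc3sig:::.codon_tables()
  # a gene using only GCC for Ala
  s <- paste(rep("GCC", 40), collapse = "")
  m <- codon_usage_matrix(make_cds(g = s, policy = validation_policy(min_codons = 1)),
                          min_codons = 1)
  ala <- tab$codons[tab$aa == "A"]
  expect_equal(unname(m[1, ala]), c(0, 1, 0, 0))  # GCA, GCC, GCG, GCT
  expect_true(all(attr(m, "imputed")[1, ala] == FALSE))
  # absent amino acids are imputed and flagged
  lys <- tab$codons[tab$aa == "K"]
  expect_true(all(attr(m, "imputed")[1, lys]))
  # random ensemble: every present block sums to 1 within 1e-12
  set.seed(16)
  seqs <- setNames(vapply(1:20, function(i) random_seq(3 * 200), character(1)),
                   paste0("g", 1:20))
  m2 <- codon_usage_matrix(as_cds_set(seqs))
  for (a in tab$aa18) {
    block <- m2[, tab$codons[tab$aa == a], drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 20), tolerance = 1e-12)
  }
  # identical genes give identical rows
  m3 <- codon_usage_matrix(make_cds(a = s, b = s, policy = validation_policy(min_codons = 1)),
                           min_codons = 1)
  expect_equal(m3[1, ], m3[2, ])
})

test_that("codon-usage PCA reports coherent variance fractions", {
  set.seed(17)
  seqs <- setNames(vapply(1:60, function(i) random_seq(3 * 300), character(1)),
                   paste0("g", 1:60))
  cds <- as_cds_set(seqs)
  m <- codon_usage_matrix(cds)
  gc3 <- composition_profile(cds)$gc3
  pr <- pca_codon_usage(m, setNames(gc3, cds$gene_id))
  expect_equal(sum(pr$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(pr$variance_fraction) <= 1e-12))
  expect_lte(pr$abs_corr_pc1_gc3, 1)
  # PC scores are mutually uncorrelated
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  cc <- cor(p$x[, 1:5])
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
})
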