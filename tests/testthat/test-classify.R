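test_that("boundary-reflected density integrates to 1 and finds point masses", {
  set.seed(1)
  d <- estimate_density(runif(5000))
  expect_lt(abs(gc3sig:::.trapz(d$grid, d$density) - 1), 1e-6)
  # uniform sample: flat within Monte-Carlo tolerance (reflection prevents
  # the usual boundary dip)
  expect_lt(max(abs(d$density - 1)), 0.15)
  # point mass: single sharp mode at the value
  d2 <- estimate_density(rep(0.6, 100))
  expect_equal(d2$grid[which.max(d2$density)], 0.6, tolerance = 0.01)
  expect_error(estimate_density(runif(10)), "fixed")
})

test_that("valley thresholding separates planted components and knows unimodal", {
  set.seed(2)
  comp <- rbinom(10000, 1, 0.3)
  x <- ifelse(comp == 1, rnorm(10000, 0.9, 0.05), rnorm(10000, 0.6, 0.05))
  x <- pmin(pmax(x, 0), 1)
  v <- find_valley_threshold(estimate_density(x))
  expect_equal(v$modality, "bimodal")
  expect_true(v$threshold >= 0.70 && v$threshold <= 0.85)
  # single component: no valley is a valid outcome
  v2 <- find_valley_threshold(estimate_density(pmin(pmax(rnorm(5000, 0.6, 0.06), 0), 1)))
  expect_equal(v2$modality, "unimodal")
  expect_true(is.na(v2$threshold))
})

test_that("class assignment uses the inclusive-high boundary", {
  ca <- assign_classes(c(a = 0.8, b = 0.7999999, c = 0.2), 0.8)
  expect_equal(as.character(ca$labels), c("high", "low", "low"))
  expect_equal(unname(ca$counts), c(2L, 1L))
  # every gene labelled exactly once; counts partition n
  expect_equal(sum(ca$counts), 3L)
  # empty high class is reported, not an error
  ca2 <- assign_classes(c(0.1, 0.2), 0.9)
  expect_equal(unname(ca2$counts["high"]), 0L)
})

test_that("adjacent-gene correlation pairs within chromosomes only", {
  set.seed(3)
  n <- 10000
  cds <- make_cds(setNames(rep("ATGGCCGCC", n), sprintf("g%05d", 1:n)),
                  policy = validation_policy(min_codons = 1))
  lay <- data.frame(gene_id = cds$gene_id,
                    chrom = rep(c("chr1", "chr2"), each = n / 2),
                    start = rep(seq_len(n / 2) * 100L, 2),
                    end = rep(seq_len(n / 2) * 100L + 50L, 2),
                    strand = "+", stringsAsFactors = FALSE)
  tab <- read_gene_table(cds, layout = lay)
  gc3 <- runif(n)  # independent of position
  r <- adjacent_correlation(tab, gc3)
  expect_lt(abs(as.numeric(r)), 0.05)
  expect_equal(attr(r, "n_pairs"), n - 2L)
  # genes sorted by gc3 along one chromosome: near-perfect correlation
  tab1 <- tab[tab$chrom == "chr1", ]
  r2 <- adjacent_correlation(tab1, sort(runif(n / 2)))
  expect_gt(as.numeric(r2), 0.95)
  # two chromosomes of one gene each: no pairs
  tab2 <- tab[c(1, n), ]
  tab2$gene_index_on_chrom <- c(1L, 1L)
  expect_error(adjacent_correlation(tab2, c(0.5, 0.6)), "no within")
})

test_that("clump finder handles gaps exactly as specified", {
  lab12 <- rep("high", 12)
  cds <- make_cds(setNames(rep("ATGGCC", 20), paste0("g", 1:20)),
                  policy = validation_policy(min_codons = 1))
  tab <- toy_table(cds)
  cr <- find_clumps(tab, c(lab12, rep("low", 8)), min_size = 10, max_gap_genes = 0)
  expect_equal(nrow(cr$clumps), 1L)
  expect_equal(cr$clumps$n_high_genes, 12L)
  # all low: zero clumps
  expect_equal(nrow(find_clumps(tab, rep("low", 20), 10, 0)$clumps), 0L)
  # H5 L1 H5: one clump of 10 with gap 1, none with gap 0
  pat <- c(rep("high", 5), "low", rep("high", 5), rep("low", 9))
  expect_equal(find_clumps(tab, pat, 10, 1)$clumps$n_high_genes, 10L)
  expect_equal(nrow(find_clumps(tab, pat, 10, 0)$clumps), 0L)
})

test_that("clump finder agrees with the regex enumeration oracle", {
  set.seed(4)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    lab <- sample(c("high", "low"), n, replace = TRUE, prob = c(0.4, 0.6))
    min_size <- sample(2:5, 1)
    max_gap <- sample(0:3, 1)
    cds <- make_cds(setNames(rep("ATGGCC", n), paste0("g", seq_len(n))),
                    policy = validation_policy(min_codons = 1))
    tab <- toy_table(cds)
    got <- find_clumps(tab, lab, min_size, max_gap)$clumps
    want <- clump_oracle(lab, min_size, max_gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$first_index, want$first)
      expect_equal(got$last_index, want$last)
      expect_equal(got$n_high_genes, want$n_high)
    }
  }
})

test_that("flanking GC association recovers identity and independence", {
  set.seed(6)
  gc3 <- runif(2000)
  expect_equal(flanking_gc_association(gc3, gc3, n_perm = 200)$r, 1)
  expect_equal(flanking_gc_association(gc3, 0.9 - gc3, n_perm = 200)$r, -1)
  ind <- flanking_gc_association(gc3, runif(2000), n_perm = 2000)
  expect_lt(abs(ind$r), 0.05)
  expect_gt(ind$p_value, 0.05)
  expect_warning(flanking_gc_association(runif(20), runif(20), n_perm = 50),
                 "low power")
})
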