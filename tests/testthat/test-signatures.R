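test_that("dinucleotide relative abundance matches hand-computable cases", {
  expect_equal(unname(relative_abundance_di("AAAA")[1, "AA"]), 1)
  expect_equal(unname(relative_abundance_di("CGCGCGCG")[1, "CG"]), 16 / 7)
  # undefined when a marginal is zero
  expect_true(is.na(relative_abundance_di("AAAA")[1, "CG"]))
})

test_that("rho values approach 1 for i.i.d. sequences of any composition", {
  set.seed(202)
  for (rep in 1:3) {
    prob <- runif(4) + 0.2
    prob <- prob / sum(prob)
    seqs <- vapply(1:500, function(i) random_seq(600, prob), character(1))
    rho <- relative_abundance_di(seqs)
    expect_true(all(abs(colMeans(rho) - 1) < 0.02))
    cwg <- relative_abundance_cwg(seqs)
    expect_lt(abs(mean(cwg) - 1), 0.02)
  }
})

test_that("CWG relative abundance matches the brute-force counter", {
  set.seed(12)
  for (i in 1:50) {
    s <- random_seq(sample(30:200, 1))
    expect_equal(relative_abundance_cwg(s), bf_rho_cwg(s), tolerance = 1e-12)
  }
  expect_equal(relative_abundance_cwg("CAGCAGCAG"), bf_rho_cwg("CAGCAGCAG"),
               tolerance = 1e-12)
  # no A or T anywhere: f(W) = 0, undefined
  expect_true(is.na(relative_abundance_cwg("CGCGCGCG")))
})

test_that("GC correction is pluggable and defaults to identity", {
  s <- c(a = "CGCGATAT", b = "CGCGCGAT")
  plain <- gc_corrected_rho_cg(s)
  expect_false(attr(plain, "corrected"))
  half <- gc_corrected_rho_cg(s, function(gc) rep(2, length(gc)))
  expect_equal(as.numeric(half), as.numeric(plain) / 2)
  expect_true(attr(half, "corrected"))
  expect_error(gc_corrected_rho_cg(s, function(gc) gc - 1), "<= 0")
  # a decreasing tau boosts GC-rich sequences relative to GC-poor ones
  tau <- function(gc) 1.5 - gc
  rho <- as.numeric(relative_abundance_di(s)[, "CG"])
  corr <- as.numeric(gc_corrected_rho_cg(s, tau))
  expect_equal(corr, rho / tau(c(0.5, 0.75)))
})

test_that("positional rho matches the brute-force joint/marginal counter", {
  # degenerate: every codon ACG -> joint equals product of marginals
  expect_equal(positional_rho("ACGACGACG", "C2G3"), 1)
  # forced-zero joint
  expect_equal(positional_rho(paste0(rep(c("ACA", "AAG"), 5), collapse = ""),
                              "C2G3"), 0)
  set.seed(77)
  for (i in 1:50) {
    s <- random_seq(3 * sample(2:80, 1))
    expect_equal(positional_rho(s, "C2G3"), bf_positional_rho(s, "C2G3"),
                 tolerance = 1e-12)
    expect_equal(positional_rho(s, "C3G1"), bf_positional_rho(s, "C3G1"),
                 tolerance = 1e-12)
  }
})

test_that("conditional third-position ratios flag degenerate denominators", {
  # all ACG: P(G3|C2) = 1, P(C3|C2) = 0 -> infinite, flagged
  expect_identical(conditional_ratio("ACGACGACG", "G3_given_C2"), Inf)
  # equal ACG / ACC counts -> ratio exactly 1
  expect_equal(conditional_ratio("ACGACCACGACC", "G3_given_C2"), 1)
  # conditioning event absent -> NA
  expect_true(is.na(conditional_ratio("AAAAAA", "G3_given_C2")))
  set.seed(78)
  for (i in 1:50) {
    s <- random_seq(3 * sample(2:80, 1))
    expect_equal(conditional_ratio(s, "G3_given_C2"),
                 bf_conditional_ratio(s, "G3_given_C2"), tolerance = 1e-12)
    expect_equal(conditional_ratio(s, "C3_given_G1"),
                 bf_conditional_ratio(s, "C3_given_G1"), tolerance = 1e-12)
  }
})

test_that("rho is asymptotically scale invariant and pooling is concatenation", {
  set.seed(9)
  s <- random_seq(2000)
  r1 <- relative_abundance_di(s)
  r2 <- relative_abundance_di(paste0(s, s))
  expect_true(all(abs(r1 - r2) < 0.01, na.rm = TRUE))
  cds <- make_cds(a = random_seq(300), b = random_seq(450))
  pooled <- pooled_signature(cds)
  direct <- relative_abundance_di(paste(cds$sequence, collapse = ""))
  expect_equal(pooled, direct)
})

test_that("signature distributions separate planted class differences", {
  set.seed(55)
  # high class: CG-enriched by construction; low class: plain random
  hi <- vapply(1:80, function(i) paste0(random_seq(200),
                                        paste(rep("CG", 30), collapse = "")),
               character(1))
  lo <- vapply(1:80, function(i) random_seq(260), character(1))
  prof <- data.frame(gene_id = paste0("g", 1:160),
                     rho_CG = as.numeric(relative_abundance_di(c(hi, lo))[, "CG"]))
  lab <- rep(c("high", "low"), each = 80)
  sd <- signature_distributions(prof, lab, statistics = "rho_CG")
  expect_lt(sd$tests$p_value[1], 1e-6)
  counts <- tapply(sd$histograms$count, sd$histograms$class, sum)
  expect_equal(as.integer(counts), c(80L, 80L))
  # identical profiles in both classes -> identical histograms
  prof2 <- data.frame(gene_id = prof$gene_id, rho_CG = rep(prof$rho_CG[1:80], 2))
  sd2 <- signature_distributions(prof2, lab, statistics = "rho_CG")
  h <- split(sd2$histograms$count, sd2$histograms$class)
  expect_identical(h$high, h$low)
  # a single class is allowed in pooled use (no rank-sum test emitted)
  one <- signature_distributions(prof, rep("high", 160), statistics = "rho_CG")
  expect_null(one$tests)
})

test_that("full signature profile is internally consistent", {
  set.seed(31)
  cds <- make_cds(a = random_seq(300), b = random_seq(300), c = random_seq(300))
  sp <- signature_profile(cds)
  expect_equal(sp$f_A + sp$f_C + sp$f_G + sp$f_T, rep(1, 3), tolerance = 1e-12)
  expect_equal(sp$rho_CG, as.numeric(relative_abundance_di(cds)[, "CG"]))
  expect_equal(sp$rho_cg_corrected, sp$rho_CG)  # default: uncorrected
  expect_false(attr(sp, "rho_cg_corrected_flag"))
})
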