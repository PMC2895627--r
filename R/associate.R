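# Covariate analyses: z-scores, equal-count binned regressions, Pearson
# correlations, TATA-box scanning and frequency curves, high-class
# probability curves with chi-squared tests, per-category profiles, and the
# codon-usage matrix + PCA.

#' Standardise a vector to z-scores
#'
#' `(x - mean) / sd` with the sample standard deviation (denominator n-1).
#' Affine transformations of the input leave the z-scores unchanged.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
zscore <- function(values) {
  stopifnot(length(values) >= 2)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) .stopf("cannot z-score a constant vector")
  (values - mean(values, na.rm = TRUE)) / s
}

#' Per-gene standard deviation of log expression
#'
#' Sample SD of each gene's (log-scale) expression vector across conditions.
#' Genes with a fully absent expression vector are returned as `NA` and
#' counted in the `n_excluded` attribute.
#'
#' @param table A `gene_table` whose `"expression"` attribute holds the
#'   genes x conditions matrix of log intensities.
#' @return Named numeric vector of per-gene SDs.
#' @export
expression_variability <- function(table) {
  expr <- attr(table, "expression")
  if (is.null(expr)) .stopf("gene table has no expression matrix")
  if (ncol(expr) < 3) .stopf("need >= 3 expression conditions, got %d", ncol(expr))
  out <- apply(expr, 1L, sd, na.rm = TRUE)
  absent <- apply(expr, 1L, function(r) all(is.na(r)))
  out[absent] <- NA_real_
  attr(out, "n_excluded") <- sum(absent)
  out
}

.equal_count_bins <- function(n, nbins) ceiling(seq_len(n) * nbins / n)

#' Equal-count binned scatter and linear fit
#'
#' Genes are sorted by `x` and cut into equal-count bins (sizes differing by
#' at most one); per-bin means of `x` and `y` are computed and an ordinary
#' least-squares line is fitted to the bin means. The reported R-squared is
#' that of the binned fit, which is much higher than a per-gene R-squared
#' would be for the same data.
#'
#' @param x,y Per-gene values (NA pairs dropped).
#' @param genes_per_bin Target genes per bin (default 200).
#' @param mode `"equal_count"` (default) or `"equal_width"` binning.
#' @return List with `bins` (data frame `bin_id`, `x_mean`, `y_mean`,
#'   `n_per_bin`), `fit` (`slope`, `intercept`, `r_squared`) and
#'   `binning_mode`.
#' @export
binned_fit <- function(x, y, genes_per_bin = 200L,
                       mode = c("equal_count", "equal_width")) {
  mode <- match.arg(mode)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 * genes_per_bin) {
    .stopf("only %d genes for %d per bin; use smaller bins", n, genes_per_bin)
  }
  if (mode == "equal_count") {
    ord <- order(x)
    nbins <- n %/% genes_per_bin
    bin <- .equal_count_bins(n, nbins)
    xb <- x[ord]; yb <- y[ord]
  } else {
    nbins <- max(2L, n %/% genes_per_bin)
    bin <- as.integer(cut(x, breaks = nbins, include.lowest = TRUE))
    xb <- x; yb <- y
  }
  xm <- tapply(xb, bin, mean)
  ym <- tapply(yb, bin, mean)
  np <- as.integer(tapply(xb, bin, length))
  fit <- lm(ym ~ xm)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ym - mean(ym))^2)
  list(
    bins = data.frame(bin_id = as.integer(names(xm)), x_mean = as.numeric(xm),
                      y_mean = as.numeric(ym), n_per_bin = np),
    fit = list(slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
    binning_mode = mode
  )
}

#' Binned linear fit of SNP density on GC3
#'
#' Same engine as [binned_fit()], on the raw (unstandardised) scales:
#' SNPs per kb as a function of GC3.
#'
#' @param gc3 Per-gene GC3.
#' @param snp_per_kb Per-gene SNP density.
#' @param genes_per_bin Genes per bin (default 200).
#' @return As [binned_fit()].
#' @export
snp_fit <- function(gc3, snp_per_kb, genes_per_bin = 200L) {
  binned_fit(gc3, snp_per_kb, genes_per_bin = genes_per_bin)
}

#' Pearson correlation with degenerate-input flagging
#'
#' @param x,y Aligned numeric vectors (NA pairs dropped), n >= 3.
#' @return Sample correlation coefficient; `NA` with a warning when either
#'   vector is constant.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) .stopf("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    .warnf("constant vector; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Scan promoters for a TATA box
#'
#' Promoter sequences are TSS-anchored: the 3' end of each sequence is
#' position -1. The scan reports whether the IUPAC motif matches anywhere on
#' the forward strand within the last `window_nt` nucleotides (positions
#' `-window_nt .. -1`). Promoters shorter than the window are scanned over
#' their full length with a warning.
#'
#' @param promoters Character vector (or `DNAStringSet`) of promoter
#'   sequences.
#' @param motif IUPAC pattern; the canonical TATA box is represented by
#'   default as `"TATAWAW"`.
#' @param window_nt Scan window upstream of the TSS (default 50).
#' @return Logical vector (TATA+ per promoter), with the motif and window
#'   recorded as attributes.
#' @export
tata_scan <- function(promoters, motif = "TATAWAW", window_nt = 50L) {
  seqs <- as.character(promoters)
  len <- nchar(seqs)
  if (any(len < window_nt)) {
    .warnf("%d promoter(s) shorter than the %d nt window; scan truncated",
           sum(len < window_nt), window_nt)
  }
  windows <- substr(seqs, pmax(1L, len - window_nt + 1L), len)
  hits <- Biostrings::vcountPattern(motif, Biostrings::DNAStringSet(windows),
                                    fixed = FALSE) > 0
  names(hits) <- names(promoters)
  attr(hits, "motif") <- motif
  attr(hits, "window_nt") <- as.integer(window_nt)
  hits
}

#' Fraction of indicator-positive genes across GC3 bins
#'
#' Genes are cut into equal-count GC3 bins and the fraction of
#' indicator-positive genes is reported per bin (e.g. the TATA+ frequency as
#' a function of GC3).
#'
#' @param indicator Per-gene logical.
#' @param gc3 Per-gene GC3.
#' @param genes_per_bin Genes per bin; default 700 so each point is well
#'   determined.
#' @return Data frame `bin_id`, `x_mean` (bin-mean GC3), `fraction`,
#'   `n_per_bin`.
#' @export
frequency_by_gc3 <- function(indicator, gc3, genes_per_bin = 700L) {
  ok <- is.finite(gc3) & !is.na(indicator)
  gc3 <- gc3[ok]; indicator <- as.logical(indicator[ok])
  n <- length(gc3)
  if (n < genes_per_bin) .stopf("only %d genes for %d per bin", n, genes_per_bin)
  ord <- order(gc3)
  nbins <- max(1L, n %/% genes_per_bin)
  bin <- .equal_count_bins(n, nbins)
  data.frame(
    bin_id = seq_len(nbins),
    x_mean = as.numeric(tapply(gc3[ord], bin, mean)),
    fraction = as.numeric(tapply(indicator[ord], bin, mean)),
    n_per_bin = as.integer(tapply(bin, bin, length))
  )
}

#' Probability of the high-GC3 class as a function of a covariate
#'
#' Reports `P(high | covariate bin)` over equal-count covariate bins, plus a
#' 2x2 chi-squared test of class against the covariate dichotomised at its
#' median (configurable split point).
#'
#' @param covariate Per-gene values (NA dropped; >= 100 genes required).
#' @param labels A `class_assignment` or aligned `"high"`/`"low"` vector.
#' @param genes_per_bin Genes per curve bin (default 200).
#' @param split Covariate split point for the contingency table; `"median"`
#'   or a number.
#' @param yates Apply Yates continuity correction (default FALSE; the
#'   intended regime is large n).
#' @return List with `curve` (data frame), `table` (2x2 counts),
#'   `chi2_stat`, `p_value`, `correction`.
#' @export
high_class_probability <- function(covariate, labels, genes_per_bin = 200L,
                                   split = "median", yates = FALSE) {
  lab <- if (inherits(labels, "class_assignment")) {
    as.character(labels$labels)
  } else {
    as.character(labels)
  }
  ok <- is.finite(covariate) & !is.na(lab)
  covariate <- covariate[ok]; lab <- lab[ok]
  n <- length(covariate)
  if (n < 100) .stopf("covariate present for only %d genes (need >= 100)", n)
  ord <- order(covariate)
  nbins <- max(2L, n %/% genes_per_bin)
  bin <- .equal_count_bins(n, nbins)
  curve <- data.frame(
    bin_id = seq_len(nbins),
    x_mean = as.numeric(tapply(covariate[ord], bin, mean)),
    p_high = as.numeric(tapply(lab[ord] == "high", bin, mean)),
    n_per_bin = as.integer(tapply(bin, bin, length))
  )
  cut_at <- if (identical(split, "median")) median(covariate) else as.numeric(split)
  tab <- table(factor(covariate >= cut_at, levels = c(FALSE, TRUE),
                      labels = c("below", "above")),
               factor(lab, levels = c("low", "high")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    .stopf("contingency table has a zero margin")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  list(curve = curve, table = tab,
       chi2_stat = unname(ct$statistic), p_value = ct$p.value,
       correction = if (yates) "yates" else "none")
}

#' Per-category GC3/GC12 profile
#'
#' For every category label: gene count, mean and coefficient of variation of
#' GC3 and GC12. The global summary compares across-category variability of
#' the two measures: `cv_ratio` is the CV of per-category mean GC3 divided by
#' the CV of per-category mean GC12.
#'
#' @param gc3,gc12 Per-gene values.
#' @param categories List of label vectors per gene (as in a `gene_table`),
#'   or a character vector of single labels.
#' @param min_genes Categories below this size are flagged (`small = TRUE`),
#'   not dropped.
#' @return List with `per_category` data frame and `cv_ratio`.
#' @export
category_profile <- function(gc3, gc12, categories, min_genes = 5L) {
  if (!is.list(categories)) categories <- as.list(categories)
  stopifnot(length(categories) == length(gc3), length(gc3) == length(gc12))
  idx <- rep(seq_along(categories), lengths(categories))
  labs <- unlist(categories, use.names = FALSE)
  keep <- !is.na(labs)
  idx <- idx[keep]; labs <- labs[keep]
  if (!length(labs)) .stopf("no category labels present")
  cv <- function(v) if (mean(v) > 0) sd(v) / mean(v) else NA_real_
  per <- do.call(rbind, lapply(split(idx, labs), function(ii) {
    data.frame(n = length(ii),
               mean_gc3 = mean(gc3[ii]), cv_gc3 = cv(gc3[ii]),
               mean_gc12 = mean(gc12[ii]), cv_gc12 = cv(gc12[ii]))
  }))
  per <- data.frame(category = rownames(per), per,
                    small = per$n < min_genes, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!any(per$n >= min_genes)) {
    .warnf("no category reaches %d genes", min_genes)
  }
  big <- per[!per$small, , drop = FALSE]
  cv_ratio <- if (nrow(big) >= 2) cv(big$mean_gc3) / cv(big$mean_gc12) else NA_real_
  list(per_category = per, cv_ratio = cv_ratio)
}

#' Gene x codon usage matrix
#'
#' `scheme = "within_aa"` (default): each codon's frequency among the
#' synonymous codons of its amino acid within the gene; Met, Trp and stop
#' codons are excluded (59 columns). Amino acids absent from a gene leave
#' their block undefined; those cells are imputed with the ensemble-mean
#' usage of the amino acid (PCA requires a complete matrix) and flagged in
#' the `"imputed"` attribute. `scheme = "global"`: codon count over total
#' codons (64 columns).
#'
#' @param cds A `cds_set`.
#' @param scheme `"within_aa"` or `"global"`.
#' @param min_codons Genes with fewer codons are excluded with a warning.
#' @return Numeric matrix, rownames gene ids; attributes `scheme` and (for
#'   `within_aa`) `imputed`.
#' @export
codon_usage_matrix <- function(cds, scheme = c("within_aa", "global"),
                               min_codons = 30L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cds, "cds_set"))
  tab <- .codon_tables()
  m <- .codon_count_matrix(cds)
  keep <- rowSums(m) >= min_codons
  if (!all(keep)) {
    .warnf("excluding %d gene(s) with < %d codons", sum(!keep), min_codons)
  }
  m <- m[keep, , drop = FALSE]
  if (scheme == "global") {
    out <- m / rowSums(m)
    attr(out, "scheme") <- "global"
    return(out)
  }
  cols <- tab$usage_codons
  out <- matrix(NA_real_, nrow(m), length(cols),
                dimnames = list(rownames(m), cols))
  imputed <- matrix(FALSE, nrow(m), length(cols),
                    dimnames = list(rownames(m), cols))
  for (a in tab$aa18) {
    cc <- tab$codons[tab$aa == a]
    block <- m[, cc, drop = FALSE]
    tot <- rowSums(block)
    freq <- block / ifelse(tot > 0, tot, NA_real_)
    absent <- tot == 0
    if (any(absent)) {
      ens <- colMeans(freq[!absent, , drop = FALSE])
      if (anyNA(ens)) ens <- rep(1 / length(cc), length(cc))
      freq[absent, ] <- matrix(ens, sum(absent), length(cc), byrow = TRUE)
      imputed[absent, cc] <- TRUE
    }
    out[, cc] <- freq
  }
  attr(out, "scheme") <- "within_aa"
  attr(out, "imputed") <- imputed
  out
}

#' PCA of codon usage
#'
#' Centred (not scaled) principal component analysis of a codon-usage
#' matrix; reports the per-component variance fractions, PC1 scores and the
#' correlation of PC1 with GC3. The sign of a principal component is
#' arbitrary, so the absolute correlation is reported alongside the signed
#' one.
#'
#' @param matrix Gene x codon matrix from [codon_usage_matrix()].
#' @param gc3 Per-gene GC3 aligned to the matrix rows (or named; matched by
#'   rowname).
#' @return List with `variance_fraction`, `pc1_scores`, `corr_pc1_gc3`,
#'   `abs_corr_pc1_gc3`, `loadings`.
#' @export
pca_codon_usage <- function(matrix, gc3) {
  if (!is.null(names(gc3)) && !is.null(rownames(matrix))) {
    gc3 <- gc3[rownames(matrix)]
  }
  stopifnot(length(gc3) == nrow(matrix))
  p <- prcomp(matrix, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  r <- cor(p$x[, 1], gc3)
  list(variance_fraction = vf,
       pc1_scores = setNames(p$x[, 1], rownames(matrix)),
       corr_pc1_gc3 = r, abs_corr_pc1_gc3 = abs(r),
       loadings = p$rotation)
}
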