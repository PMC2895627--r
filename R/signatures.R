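# Genome-signature statistics: mono/di/tri-nucleotide frequencies, relative
# abundances rho_XY = f(XY)/(f(X) f(Y)), the plant methylation context CWG,
# position-specific rho at the wobble position, and conditional
# third-position preference ratios. All frequencies are computed from
# overlapping counts on the forward strand of the CDS.

.mono_freq_matrix <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(x, width = 1L)
  m / pmax(rowSums(m), 1)
}

#' Dinucleotide relative abundances
#'
#' For each sequence, the 16 values `rho_XY = f(XY) / (f(X) f(Y))` where
#' `f(XY)` is the overlapping dinucleotide frequency and `f(X)` the
#' mononucleotide frequency. Undefined values (zero marginal product) are
#' `NA`.
#'
#' @param x A `cds_set` or a character vector of sequences.
#' @return Numeric matrix, one row per sequence, columns `AA` .. `TT`.
#' @export
relative_abundance_di <- function(x) {
  seqs <- if (inherits(x, "cds_set")) x$sequence else x
  if (any(nchar(seqs) < 2)) .stopf("sequences must have length >= 2")
  di <- .dinuc_count_matrix(seqs)
  fdi <- di / pmax(rowSums(di), 1)
  fm <- .mono_freq_matrix(seqs)
  out <- fdi
  for (a in .BASES) for (b in .BASES) {
    d <- fm[, a] * fm[, b]
    out[, paste0(a, b)] <- ifelse(d > 0, fdi[, paste0(a, b)] / d, NA_real_)
  }
  rn <- if (inherits(x, "cds_set")) x$gene_id else names(seqs)
  if (!is.null(rn)) rownames(out) <- rn
  out
}

.tri_freq <- function(seqs, codons) {
  x <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(x, width = 3L, step = 1L)
  rowSums(m[, codons, drop = FALSE]) / pmax(rowSums(m), 1)
}

#' CWG trinucleotide relative abundance
#'
#' `rho_CWG = f(CWG) / (f(C) f(W) f(G))` with `W` in `{A, T}`, i.e.
#' `f(CWG) = f(CAG) + f(CTG)` and `f(W) = f(A) + f(T)`, computed from
#' overlapping trinucleotide windows. CWG is a plant methylation-target
#' context distinct from CG. `NA` when the denominator is zero.
#'
#' @param x A `cds_set` or a character vector of sequences.
#' @return Numeric vector.
#' @export
relative_abundance_cwg <- function(x) {
  seqs <- if (inherits(x, "cds_set")) x$sequence else x
  if (any(nchar(seqs) < 3)) .stopf("sequences must have length >= 3")
  fcwg <- .tri_freq(seqs, c("CAG", "CTG"))
  fm <- .mono_freq_matrix(seqs)
  den <- fm[, "C"] * (fm[, "A"] + fm[, "T"]) * fm[, "G"]
  unname(ifelse(den > 0, fcwg / den, NA_real_))
}

#' GC-corrected CG relative abundance
#'
#' The observed/expected CG ratio understates CpG depletion in GC-rich
#' sequences; a correction that is a function of the G+C fraction can be
#' divided out. The correction is pluggable: the default (`NULL`) applies no
#' correction and marks the result as uncorrected via the `"corrected"`
#' attribute.
#'
#' @param x A `cds_set` or a character vector of sequences.
#' @param correction `NULL`, or a function of the G+C fraction returning a
#'   strictly positive factor `tau(GC)`; the result is `rho_CG / tau(GC)`.
#' @return Numeric vector with attribute `corrected` (logical).
#' @export
gc_corrected_rho_cg <- function(x, correction = NULL) {
  rho <- relative_abundance_di(x)[, "CG"]
  if (is.null(correction)) {
    attr(rho, "corrected") <- FALSE
    return(rho)
  }
  seqs <- if (inherits(x, "cds_set")) x$sequence else x
  fm <- .mono_freq_matrix(seqs)
  tau <- correction(fm[, "C"] + fm[, "G"])
  if (any(!is.na(tau) & tau <= 0)) .stopf("correction returned a value <= 0")
  out <- rho / tau
  attr(out, "corrected") <- TRUE
  out
}

.codon_chars <- function(s) {
  n <- nchar(s) %/% 3L
  list(first = substring(s, seq(1L, 3L * n, 3L), seq(1L, 3L * n, 3L)),
       second = substring(s, seq(2L, 3L * n, 3L), seq(2L, 3L * n, 3L)),
       third = substring(s, seq(3L, 3L * n, 3L), seq(3L, 3L * n, 3L)))
}

#' Position-specific CG relative abundance at the wobble position
#'
#' `kind = "C2G3"`: the within-codon signature
#' `P(C2 and G3 in the same codon) / (P(C2) P(G3))`, with probabilities
#' estimated position-specifically over codons.
#' `kind = "C3G1"`: the same construction across the codon boundary (C at
#' position 3 of codon i, G at position 1 of codon i+1); the marginals are
#' estimated over the pair-eligible codons (positions 1..n-1 for C3, 2..n for
#' G1). `NA` when a marginal is zero.
#'
#' @param x A `cds_set` or a character vector of in-frame sequences.
#' @param kind `"C2G3"` or `"C3G1"`.
#' @return Numeric vector.
#' @export
positional_rho <- function(x, kind = c("C2G3", "C3G1")) {
  kind <- match.arg(kind)
  if (!inherits(x, "cds_set")) x <- new_cds_set(paste0("s", seq_along(x)), x, FALSE)
  tab <- .codon_tables()
  if (kind == "C2G3") {
    m <- .codon_count_matrix(x)
    n <- unname(pmax(rowSums(m), 1))
    joint <- as.numeric(m %*% (tab$second == "C" & tab$third == "G")) / n
    pc2 <- as.numeric(m %*% (tab$second == "C")) / n
    pg3 <- as.numeric(m %*% (tab$third == "G")) / n
    return(ifelse(pc2 * pg3 > 0, joint / (pc2 * pg3), NA_real_))
  }
  vapply(seq_along(x$gene_id), function(i) {
    n <- x$n_codons[i]
    if (n < 2) return(NA_real_)
    cc <- .codon_chars(x$sequence[i])
    c3 <- cc$third[-n] == "C"
    g1 <- cc$first[-1L] == "G"
    pj <- mean(c3 & g1)
    den <- mean(c3) * mean(g1)
    if (den > 0) pj / den else NA_real_
  }, numeric(1))
}

#' Conditional third-position preference ratios
#'
#' `kind = "G3_given_C2"`: among codons with C at position 2, the ratio
#' `P(G3 | C2) / P(C3 | C2)`. `kind = "C3_given_G1"`: among codons that are
#' immediately followed by a codon starting with G, the ratio
#' `P(C3 | G1) / P(G3 | G1)`. A zero denominator with a positive numerator
#' is flagged `Inf`; both zero (or an absent conditioning event) is `NA`.
#'
#' @param x A `cds_set` or a character vector of in-frame sequences.
#' @param kind `"G3_given_C2"` or `"C3_given_G1"`.
#' @return Numeric vector.
#' @export
conditional_ratio <- function(x, kind = c("G3_given_C2", "C3_given_G1")) {
  kind <- match.arg(kind)
  if (!inherits(x, "cds_set")) x <- new_cds_set(paste0("s", seq_along(x)), x, FALSE)
  tab <- .codon_tables()
  ratio <- function(num, den) {
    ifelse(num == 0 & den == 0, NA_real_,
           ifelse(den == 0, Inf, num / den))
  }
  if (kind == "G3_given_C2") {
    m <- .codon_count_matrix(x)
    num <- as.numeric(m %*% (tab$second == "C" & tab$third == "G"))
    den <- as.numeric(m %*% (tab$second == "C" & tab$third == "C"))
    cond <- as.numeric(m %*% (tab$second == "C"))
    return(ifelse(cond == 0, NA_real_, ratio(num, den)))
  }
  vapply(seq_along(x$gene_id), function(i) {
    n <- x$n_codons[i]
    if (n < 2) return(NA_real_)
    cc <- .codon_chars(x$sequence[i])
    sel <- cc$first[-1L] == "G"
    if (!any(sel)) return(NA_real_)
    thirds <- cc$third[-n][sel]
    ratio(sum(thirds == "C"), sum(thirds == "G"))
  }, numeric(1))
}

#' Full per-gene signature profile
#'
#' Computes every signature statistic for each gene: mononucleotide
#' frequencies, the 16 dinucleotide relative abundances, CWG frequency and
#' relative abundance, (optionally GC-corrected) rho_CG, the
#' position-specific rho_C2G3 / rho_C3G1 and the two conditional
#' third-position ratios.
#'
#' @param cds A `cds_set`.
#' @param correction Passed to [gc_corrected_rho_cg()].
#' @return Data frame with one row per gene.
#' @export
signature_profile <- function(cds, correction = NULL) {
  stopifnot(inherits(cds, "cds_set"))
  fm <- .mono_freq_matrix(cds$sequence)
  rho <- relative_abundance_di(cds)
  colnames(rho) <- paste0("rho_", colnames(rho))
  corrected <- gc_corrected_rho_cg(cds, correction)
  out <- data.frame(
    gene_id = cds$gene_id,
    f_A = fm[, "A"], f_C = fm[, "C"], f_G = fm[, "G"], f_T = fm[, "T"],
    rho, check.names = FALSE, stringsAsFactors = FALSE
  )
  out$f_cwg <- .tri_freq(cds$sequence, c("CAG", "CTG"))
  out$rho_cwg <- relative_abundance_cwg(cds)
  out$rho_cg_corrected <- as.numeric(corrected)
  out$rho_c2g3 <- positional_rho(cds, "C2G3")
  out$rho_c3g1 <- positional_rho(cds, "C3G1")
  out$ratio_g3_given_c2 <- conditional_ratio(cds, "G3_given_C2")
  out$ratio_c3_given_g1 <- conditional_ratio(cds, "C3_given_G1")
  attr(out, "rho_cg_corrected_flag") <- !is.null(correction)
  rownames(out) <- NULL
  out
}

#' Pooled signature of a CDS set
#'
#' Pooling is defined as concatenation of the retained sequences in input
#' order; the pooled relative abundances are those of the concatenated
#' sequence.
#'
#' @param cds A `cds_set`.
#' @return One-row result of [relative_abundance_di()] on the concatenation.
#' @export
pooled_signature <- function(cds) {
  stopifnot(inherits(cds, "cds_set"))
  relative_abundance_di(paste(cds$sequence, collapse = ""))
}

#' Per-class distributions of signature statistics
#'
#' Bins each requested statistic into fixed-width histograms per class and
#' reports a two-sample rank-sum (Wilcoxon) comparison between the high and
#' low classes for each statistic. Non-finite values (flagged undefined
#' ratios) are excluded and counted.
#'
#' @param profile Result of [signature_profile()] (or any data frame with a
#'   `gene_id` column and numeric statistic columns).
#' @param labels A [assign_classes()] result, or a character vector of class
#'   labels aligned to the profile rows.
#' @param statistics Character vector of column names to summarise.
#' @param binwidth Histogram bin width.
#' @return List with `histograms` (class, statistic, bin_left, bin_right,
#'   count), `tests` (statistic, W, p_value) and `n_excluded`.
#' @export
signature_distributions <- function(profile, labels,
                                    statistics = c("rho_CG", "rho_cwg"),
                                    binwidth = 0.1) {
  lab <- if (is.list(labels) && !is.null(labels$labels)) {
    as.character(labels$labels)
  } else {
    as.character(labels)
  }
  stopifnot(length(lab) == nrow(profile))
  classes <- sort(unique(lab))
  for (cl in classes) {
    if (!any(lab == cl)) .stopf("class '%s' is empty", cl)
  }
  hists <- list()
  tests <- list()
  n_excluded <- 0L
  for (st in statistics) {
    v <- profile[[st]]
    if (is.null(v)) .stopf("no statistic column '%s'", st)
    ok <- is.finite(v)
    n_excluded <- n_excluded + sum(!ok)
    vv <- v[ok]
    ll <- lab[ok]
    if (!length(vv)) next
    breaks <- seq(floor(min(vv) / binwidth) * binwidth,
                  ceiling(max(vv) / binwidth) * binwidth + binwidth,
                  by = binwidth)
    for (cl in classes) {
      cnt <- tabulate(findInterval(vv[ll == cl], breaks,
                                   rightmost.closed = TRUE),
                      nbins = length(breaks) - 1L)
      hists[[length(hists) + 1L]] <- data.frame(
        class = cl, statistic = st,
        bin_left = head(breaks, -1), bin_right = breaks[-1],
        count = cnt, stringsAsFactors = FALSE)
    }
    if (all(c("high", "low") %in% ll)) {
      wt <- wilcox.test(vv[ll == "high"], vv[ll == "low"], exact = FALSE)
      tests[[length(tests) + 1L]] <- data.frame(
        statistic = st, W = unname(wt$statistic), p_value = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(histograms = do.call(rbind, hists),
       tests = if (length(tests)) do.call(rbind, tests) else NULL,
       n_excluded = n_excluded)
}
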