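# GC3 distribution modelling and class assignment: boundary-reflected kernel
# density on [0,1], valley thresholding between the two main modes, and the
# spatial analyses (adjacent-gene correlation, clump detection, flanking-GC
# association).

#' Boundary-reflected Gaussian kernel density of GC3 values
#'
#' Estimates the gene-level GC3 density on a fixed 512-point grid over
#' \[0, 1\], reflecting the data at both boundaries so no mass leaks outside
#' the unit interval; the result is renormalised to integrate to 1.
#' Bandwidth defaults to Silverman's rule (`stats::bw.nrd0`) on the raw
#' scale.
#'
#' @param gc3_values Numeric vector in \[0, 1\], length >= 50.
#' @param bandwidth Numeric bandwidth, or `NULL` for Silverman's rule.
#' @param n_grid Grid size (512 by default).
#' @return Object of class `gc3_density`: list with `grid`, `density`,
#'   `bandwidth`, `n_genes`.
#' @export
estimate_density <- function(gc3_values, bandwidth = NULL, n_grid = 512L) {
  gc3_values <- gc3_values[!is.na(gc3_values)]
  if (length(gc3_values) < 50) {
    .stopf(paste("need >= 50 GC3 values for density estimation;",
                 "use assign_classes() with a fixed threshold instead"))
  }
  if (any(gc3_values < 0 | gc3_values > 1)) .stopf("GC3 values must lie in [0,1]")
  bw <- bandwidth %||% bw.nrd0(gc3_values)
  if (!is.finite(bw) || bw <= 0) bw <- 0.01
  aug <- c(gc3_values, -gc3_values, 2 - gc3_values)
  d <- density(aug, bw = bw, from = 0, to = 1, n = n_grid)
  y <- 3 * d$y
  y <- y / .trapz(d$x, y)
  structure(list(grid = d$x, density = y, bandwidth = bw,
                 n_genes = length(gc3_values)),
            class = "gc3_density")
}

#' @export
print.gc3_density <- function(x, ...) {
  cat(sprintf("<gc3_density> n = %d, bandwidth = %.4f, %d grid points\n",
              x$n_genes, x$bandwidth, length(x$grid)))
  invisible(x)
}

#' Find the inter-peak valley threshold of a bimodal GC3 density
#'
#' Identifies strict local maxima of the density, keeps those reaching at
#' least `prominence` times the primary mode's height (a filter against
#' kernel wiggles), and, if two or more survive, returns the grid point of
#' minimum density strictly between the two highest maxima. The absence of a
#' valley is a valid outcome, reported as modality `"unimodal"`.
#'
#' @param density A `gc3_density` from [estimate_density()].
#' @param prominence Minimum secondary-mode height as a fraction of the
#'   primary mode (default 0.05).
#' @return List with `threshold` (numeric or `NA`), `modality`
#'   (`"bimodal"` or `"unimodal"`), `modes` (grid positions of the two modes
#'   used, or `NULL`).
#' @export
find_valley_threshold <- function(density, prominence = 0.05) {
  stopifnot(inherits(density, "gc3_density"))
  y <- density$density
  g <- density$grid
  n <- length(y)
  ismax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  # boundary modes count too
  if (y[1] > y[2]) ismax[1] <- TRUE
  if (y[n] > y[n - 1]) ismax[n] <- TRUE
  peaks <- which(ismax)
  peaks <- peaks[y[peaks] >= prominence * max(y)]
  if (length(peaks) < 2) {
    return(list(threshold = NA_real_, modality = "unimodal", modes = NULL))
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- (lo + 1L):(hi - 1L)
  v <- between[which.min(y[between])]
  list(threshold = g[v], modality = "bimodal", modes = sort(g[top2]))
}

#' Assign high/low GC3 class labels
#'
#' The boundary is inclusive to the high class: `label = "high"` iff
#' `gc3 >= threshold`.
#'
#' @param gc3 Per-gene GC3 values (optionally named by gene id).
#' @param threshold Threshold in (0, 1); e.g. the valley from
#'   [find_valley_threshold()], or a fixed operating point such as 0.8.
#' @param method Provenance of the threshold, `"valley"` or `"fixed"`.
#' @param modality Modality reported alongside (default `"bimodal"` for a
#'   valley threshold).
#' @return Object of class `class_assignment`: list with `threshold`,
#'   `method`, `labels` (factor, levels low/high), `modality`, `counts`.
#' @export
assign_classes <- function(gc3, threshold, method = c("valley", "fixed"),
                           modality = "bimodal") {
  method <- match.arg(method)
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold < 1)
  lab <- factor(ifelse(gc3 >= threshold, "high", "low"),
                levels = c("low", "high"))
  names(lab) <- names(gc3)
  structure(list(threshold = threshold, method = method, labels = lab,
                 modality = modality,
                 counts = c(low = sum(lab == "low", na.rm = TRUE),
                            high = sum(lab == "high", na.rm = TRUE))),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("<class_assignment> threshold = %.4f (%s): %d low, %d high\n",
              x$threshold, x$method, x$counts["low"], x$counts["high"]))
  invisible(x)
}

#' Correlation of GC3 between adjacent genes
#'
#' Pearson correlation over all within-chromosome neighbouring pairs
#' (`gene_index_on_chrom` i, i+1), in annotation order by start coordinate
#' regardless of strand. Pairs never span chromosomes.
#'
#' @param table A `gene_table` with layout columns.
#' @param gc3 Per-gene GC3 values aligned to the table rows (or named by
#'   gene id).
#' @return Correlation coefficient with attribute `n_pairs`; a low-power
#'   warning is emitted when fewer than 10 pairs exist.
#' @export
adjacent_correlation <- function(table, gc3) {
  stopifnot(!is.null(table$chrom), !is.null(table$gene_index_on_chrom))
  if (!is.null(names(gc3))) gc3 <- gc3[table$gene_id]
  xs <- ys <- list()
  for (ch in unique(table$chrom[!is.na(table$chrom)])) {
    idx <- which(table$chrom == ch)
    idx <- idx[order(table$gene_index_on_chrom[idx])]
    if (length(idx) >= 2) {
      xs[[ch]] <- gc3[idx[-length(idx)]]
      ys[[ch]] <- gc3[idx[-1]]
    }
  }
  x <- unlist(xs, use.names = FALSE)
  y <- unlist(ys, use.names = FALSE)
  if (length(x) == 0) .stopf("no within-chromosome adjacent pairs")
  if (length(x) < 10) .warnf("only %d adjacent pairs; low power", length(x))
  r <- cor(x, y, use = "complete.obs")
  attr(r, "n_pairs") <- length(x)
  r
}

#' Find clumps of high-GC3 genes along chromosomes
#'
#' Scans each chromosome in gene order. A clump is a maximal run of
#' high-labelled genes in which at most `max_gap_genes` consecutive
#' low-labelled genes may intervene; clumps with at least `min_size` high
#' genes are reported. Reported indices are `gene_index_on_chrom` of the
#' first and last high gene of the clump.
#'
#' @param table A `gene_table` with layout columns.
#' @param labels A `class_assignment` (or factor/character vector aligned to
#'   the table rows, values `"high"`/`"low"`).
#' @param min_size Minimum number of high genes per clump (default 10).
#' @param max_gap_genes Maximum run of interposed low genes (default 2).
#' @return Object of class `clump_report`: list with `clumps` data frame
#'   (`chrom`, `first_index`, `last_index`, `n_high_genes`) and `parameters`.
#' @export
find_clumps <- function(table, labels, min_size = 10L, max_gap_genes = 2L) {
  lab <- if (inherits(labels, "class_assignment")) {
    as.character(labels$labels)
  } else {
    as.character(labels)
  }
  stopifnot(length(lab) == nrow(table))
  res <- list()
  for (ch in unique(table$chrom[!is.na(table$chrom)])) {
    idx <- which(table$chrom == ch)
    idx <- idx[order(table$gene_index_on_chrom[idx])]
    hi_pos <- which(lab[idx] == "high")
    if (!length(hi_pos)) next
    gap <- c(0L, diff(hi_pos) - 1L)
    grp <- cumsum(gap > max_gap_genes)
    for (g in split(hi_pos, grp)) {
      if (length(g) >= min_size) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch,
          first_index = table$gene_index_on_chrom[idx[g[1]]],
          last_index = table$gene_index_on_chrom[idx[g[length(g)]]],
          n_high_genes = length(g), stringsAsFactors = FALSE)
      }
    }
  }
  clumps <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), first_index = integer(0),
               last_index = integer(0), n_high_genes = integer(0))
  structure(list(clumps = clumps,
                 parameters = list(min_size = as.integer(min_size),
                                   max_gap_genes = as.integer(max_gap_genes))),
            class = "clump_report")
}

#' @export
print.clump_report <- function(x, ...) {
  cat(sprintf("<clump_report> %d clumps (min_size = %d, max_gap = %d)\n",
              nrow(x$clumps), x$parameters$min_size, x$parameters$max_gap_genes))
  invisible(x)
}

#' Association between GC3 and flanking-region GC content
#'
#' Pearson correlation between per-gene GC3 and the GC fraction of a
#' flanking window (for example 1,000 nt upstream), with a permutation
#' p-value. Randomness is drawn from R's RNG; seed with `set.seed()` for
#' reproducibility.
#'
#' @param gc3 Per-gene GC3 values.
#' @param flank_gc Per-gene flanking GC fraction, aligned by position (or
#'   both vectors named by gene id).
#' @param n_perm Number of permutations (default 10,000).
#' @return List with `r`, `p_value`, `n`, `n_perm`.
#' @export
flanking_gc_association <- function(gc3, flank_gc, n_perm = 10000L) {
  if (!is.null(names(gc3)) && !is.null(names(flank_gc))) {
    flank_gc <- flank_gc[names(gc3)]
  }
  ok <- is.finite(gc3) & is.finite(flank_gc)
  x <- gc3[ok]; y <- flank_gc[ok]
  n <- length(x)
  if (n < 30) .warnf("only %d genes for flanking-GC association; low power", n)
  r <- cor(x, y)
  rp <- vapply(seq_len(n_perm), function(i) cor(x, y[sample.int(n)]), numeric(1))
  p <- (1 + sum(abs(rp) >= abs(r))) / (n_perm + 1)
  list(r = r, p_value = p, n = n, n_perm = n_perm)
}
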