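# Codon-position composition: GCk, GC12, GC3, CG3 skew, CG/GC ratio and
# 5'->3' sliding-window gradients. All per-gene counting goes through one
# codon-count matrix (genes x 64), so fractions are exact ratios of integer
# counts.

.codon_count_matrix <- function(cds) {
  tab <- .codon_tables()
  x <- Biostrings::DNAStringSet(cds$sequence)
  m <- Biostrings::oligonucleotideFrequency(x, width = 3L, step = 3L)
  m <- m[, tab$codons, drop = FALSE]
  rownames(m) <- cds$gene_id
  m
}

.dinuc_count_matrix <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::oligonucleotideFrequency(x, width = 2L, step = 1L)
}

#' Per-gene codon-position composition profile
#'
#' Computes, for every gene of a CDS set, the GC fraction at each codon
#' position (`gc1`, `gc2`, `gc3`), the combined first-and-second position
#' fraction `gc12`, overall `gc_total`, the four third-position nucleotide
#' counts, the CG3 skew and the overlapping-dinucleotide CG/GC ratio.
#' All counts are taken over retained codons only.
#'
#' CG3 skew is `(C3 - G3) / (C3 + G3)`: positive when cytosine is preferred
#' at the wobble position (the orientation of the high-GC3 class). It is `NA`
#' (flagged undefined, never silently 0) when `C3 + G3 = 0`. The CG/GC ratio
#' is `f(CG)/f(GC)` over all overlapping dinucleotides of the whole CDS,
#' including codon boundaries; `NA` when there are no GC dinucleotides.
#'
#' @param cds A `cds_set`.
#' @return A data frame with one row per gene, in input order.
#' @export
composition_profile <- function(cds) {
  stopifnot(inherits(cds, "cds_set"))
  tab <- .codon_tables()
  m <- .codon_count_matrix(cds)
  n <- as.numeric(rowSums(m))

  cnt3 <- function(base) as.numeric(m %*% (tab$third == base))
  a3 <- cnt3("A"); c3 <- cnt3("C"); g3 <- cnt3("G"); t3 <- cnt3("T")
  gc1c <- as.numeric(m %*% tab$is_gc1)
  gc2c <- as.numeric(m %*% tab$is_gc2)
  gc3c <- c3 + g3

  di <- .dinuc_count_matrix(cds$sequence)
  cg <- as.numeric(di[, "CG"])
  gc_di <- as.numeric(di[, "GC"])

  out <- data.frame(
    gene_id = cds$gene_id,
    n_codons_used = as.integer(n),
    a3 = as.integer(a3), c3 = as.integer(c3),
    g3 = as.integer(g3), t3 = as.integer(t3),
    gc1 = ifelse(n > 0, gc1c / n, NA_real_),
    gc2 = ifelse(n > 0, gc2c / n, NA_real_),
    gc3 = ifelse(n > 0, gc3c / n, NA_real_),
    gc12 = ifelse(n > 0, (gc1c + gc2c) / (2 * n), NA_real_),
    gc_total = ifelse(n > 0, (gc1c + gc2c + gc3c) / (3 * n), NA_real_),
    cg3_skew = ifelse(gc3c > 0, (c3 - g3) / gc3c, NA_real_),
    cg_gc_ratio = ifelse(gc_di > 0, cg / gc_di, NA_real_),
    stringsAsFactors = FALSE
  )
  out
}

#' CG3 skew of coding sequences
#'
#' `(C3 - G3)/(C3 + G3)` over third codon positions; `NA` when no third
#' position carries C or G.
#'
#' @param x A `cds_set` or a character vector of in-frame sequences.
#' @return Numeric vector.
#' @export
cg3_skew <- function(x) {
  if (!inherits(x, "cds_set")) x <- new_cds_set(paste0("s", seq_along(x)), x, FALSE)
  composition_profile(x)$cg3_skew
}

#' CG/GC overlapping-dinucleotide ratio
#'
#' `f(CG)/f(GC)` over all overlapping dinucleotides of each sequence; `NA`
#' when the sequence contains no GC dinucleotide.
#'
#' @param x A `cds_set` or a character vector of sequences.
#' @return Numeric vector.
#' @export
cg_gc_ratio <- function(x) {
  seqs <- if (inherits(x, "cds_set")) x$sequence else x
  di <- .dinuc_count_matrix(seqs)
  unname(ifelse(di[, "GC"] > 0, di[, "CG"] / di[, "GC"], NA_real_))
}

#' 5'-to-3' sliding-window gradient profile
#'
#' Genes are aligned at the start codon and mean GC3 and mean CG3 skew are
#' computed in a sliding window of approximately `window_size_nt` nucleotides,
#' snapped to whole codons (third-position statistics require codon
#' alignment): the window at offset `o` covers codons
#' `floor(o/3)+1 .. ceiling((o+window_size_nt)/3)`. Genes too short to cover
#' a window are excluded from that window (never padded); windows with fewer
#' than `min_genes` covering genes are reported as `NA`. Genes flagged short
#' by the validation policy are excluded entirely.
#'
#' @param cds A `cds_set`.
#' @param class_labels Optional character/factor vector (aligned to the CDS
#'   set or named by gene id) stratifying genes, e.g. high/low GC3 class.
#'   When `NULL` all genes form one stratum `"all"`.
#' @param window_size_nt Window span in nucleotides (50 by default).
#' @param step_nt Offset increment in nucleotides; default 3 (one codon).
#' @param min_genes Minimum genes covering a window for it to be defined.
#' @param max_offset_nt Largest window start offset considered; default stops
#'   where no window could reach `min_genes`.
#' @return Data frame: `class`, `window_index`, `offset_nt`, `n_genes`,
#'   `mean_gc3`, `mean_cg3_skew`.
#' @export
gradient_profile <- function(cds, class_labels = NULL, window_size_nt = 50L,
                             step_nt = 3L, min_genes = 100L,
                             max_offset_nt = NULL) {
  stopifnot(inherits(cds, "cds_set"), window_size_nt >= 3L, step_nt >= 1L)
  keep <- !cds$short_flag
  if (!any(keep)) .stopf("no gene passes the short-gene filter")
  sub <- cds[keep]

  labels <- if (is.null(class_labels)) {
    rep("all", length(sub))
  } else {
    if (!is.null(names(class_labels))) {
      as.character(class_labels[sub$gene_id])
    } else {
      as.character(class_labels[keep])
    }
  }

  n_cod <- sub$n_codons
  max_cod <- max(n_cod)
  first_end <- ceiling(window_size_nt / 3)
  if (sum(n_cod >= first_end) == 0) .stopf("no gene covers the first window")

  # Per-gene cumulative third-position counts up to a codon cap.
  cap <- min(max_cod, max(first_end, 1024L))
  ind_mat <- function(base_set) {
    m <- matrix(0L, length(sub), cap)
    for (i in seq_along(sub$gene_id)) {
      s <- sub$sequence[i]
      k <- min(n_cod[i], cap)
      thirds <- substring(s, seq(3L, 3L * k, 3L), seq(3L, 3L * k, 3L))
      m[i, seq_len(k)] <- as.integer(thirds %in% base_set)
    }
    t(apply(m, 1L, cumsum))
  }
  cum_c <- ind_mat("C")
  cum_g <- ind_mat("G")

  offsets <- seq(0L, by = step_nt,
                 length.out = max(1L, ((cap * 3L - window_size_nt) %/% step_nt) + 1L))
  if (!is.null(max_offset_nt)) offsets <- offsets[offsets <= max_offset_nt]

  res <- list()
  for (cl in sort(unique(labels))) {
    sel <- labels == cl
    for (w in seq_along(offsets)) {
      o <- offsets[w]
      c1 <- o %/% 3L + 1L
      c2 <- ceiling((o + window_size_nt) / 3)
      if (c2 > cap) break
      covered <- sel & n_cod >= c2
      ng <- sum(covered)
      if (ng >= min_genes) {
        lo <- if (c1 > 1L) cum_c[covered, c1 - 1L] else 0
        cwin <- cum_c[covered, c2] - lo
        lo <- if (c1 > 1L) cum_g[covered, c1 - 1L] else 0
        gwin <- cum_g[covered, c2] - lo
        mg <- mean((cwin + gwin) / (c2 - c1 + 1L))
        tot <- cwin + gwin
        ok <- tot > 0
        ms <- if (any(ok)) mean((cwin[ok] - gwin[ok]) / tot[ok]) else NA_real_
      } else {
        mg <- NA_real_
        ms <- NA_real_
      }
      res[[length(res) + 1L]] <- data.frame(
        class = cl, window_index = w, offset_nt = o, n_genes = ng,
        mean_gc3 = mg, mean_cg3_skew = ms, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "window_size_nt") <- window_size_nt
  attr(out, "step_nt") <- step_nt
  attr(out, "min_genes") <- min_genes
  out
}
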