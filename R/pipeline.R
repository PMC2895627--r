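# End-to-end orchestration: composition -> signatures -> classification ->
# covariate associations -> PCA, with TSV/JSON outputs per stage. Each stage
# is an ordinary exported function; run_pipeline() chains them and degrades
# gracefully when covariates are absent.

#' Run the full GC3 analysis pipeline
#'
#' Accepts either a dataset directory (as written by [simulate_dataset()])
#' or an in-memory dataset (a list with `cds` and `table`). Stages:
#' per-gene composition; per-gene signatures; density estimation, valley
#' thresholding and class assignment; spatial analyses; covariate
#' associations (expression variability, SNP fit, intron correlation, TATA
#' curve, high-class probability, categories); gradient profiles; and
#' codon-usage PCA. Stages whose inputs are absent are skipped with a
#' logged reason. Every scalar statistic lands in `summary`; when
#' `out_dir` is given the stage tables are written as TSV and the summary
#' as `summary.json`.
#'
#' @param x Dataset directory or list with `cds` (a `cds_set`) and `table`
#'   (a `gene_table`).
#' @param out_dir Optional output directory.
#' @param seed Seed for the permutation test (all other stages are
#'   deterministic given the data).
#' @param analyses Character vector of optional stages to run; subset of
#'   `c("signatures", "gradient", "pca", "flanking")`. Defaults to all.
#' @param fixed_threshold Used when the density has no valley (or fewer than
#'   50 genes); default 0.8, the canonical grass operating point.
#' @param tata_endpoints GC3 cut points `c(lo, hi)` for the reported TATA
#'   endpoint fractions (default 0.45 / 0.95).
#' @param genes_per_bin Genes per bin for the z-score and SNP binned fits.
#' @param tata_genes_per_bin Genes per bin for the TATA frequency curve.
#' @return List with all stage results and `summary`; invisibly.
#' @export
run_pipeline <- function(x, out_dir = NULL, seed = 1L,
                         analyses = c("signatures", "gradient", "pca",
                                      "flanking"),
                         fixed_threshold = 0.8,
                         tata_endpoints = c(0.45, 0.95),
                         genes_per_bin = 200L,
                         tata_genes_per_bin = 700L) {
  if (is.character(x) && length(x) == 1) x <- load_dataset(x)
  cds <- x$cds
  table <- x$table
  res <- list()
  summary <- list(n_genes = length(cds),
                  n_rejected = nrow(attr(cds, "rejected")))

  comp <- composition_profile(cds)
  res$composition <- comp
  gc3 <- setNames(comp$gc3, comp$gene_id)

  if ("signatures" %in% analyses) {
    res$signatures <- signature_profile(cds)
  }

  # classification
  if (length(gc3) >= 50) {
    dens <- estimate_density(gc3)
    valley <- find_valley_threshold(dens)
    res$density <- dens
    res$valley <- valley
    thr <- if (valley$modality == "bimodal") valley$threshold else fixed_threshold
    method <- if (valley$modality == "bimodal") "valley" else "fixed"
  } else {
    .msgf("fewer than 50 genes; using fixed threshold %.2f", fixed_threshold)
    thr <- fixed_threshold
    method <- "fixed"
    res$valley <- list(threshold = NA_real_, modality = "indeterminate")
  }
  classes <- assign_classes(gc3, thr, method = method,
                            modality = res$valley$modality %||% "indeterminate")
  res$classes <- classes
  summary$threshold <- classes$threshold
  summary$threshold_method <- method
  summary$modality <- res$valley$modality
  summary$n_low <- unname(classes$counts["low"])
  summary$n_high <- unname(classes$counts["high"])

  has_layout <- !is.null(table$chrom) && any(!is.na(table$chrom))
  if (has_layout) {
    r_adj <- adjacent_correlation(table, gc3)
    summary$adjacent_gene_r <- as.numeric(r_adj)
    lab_tab <- classes$labels[table$gene_id]
    clumps <- find_clumps(table, as.character(lab_tab))
    res$clumps <- clumps
    summary$n_clumps <- nrow(clumps$clumps)
  } else {
    .msgf("no layout: skipping adjacent-gene correlation and clump scan")
  }

  # associations
  m <- match(table$gene_id, comp$gene_id)
  gc3_t <- comp$gc3[m]
  gc12_t <- comp$gc12[m]
  lab_t <- as.character(classes$labels[table$gene_id])

  expr <- attr(table, "expression")
  if (!is.null(expr) && ncol(expr) >= 3) {
    sd_expr <- expression_variability(table)
    ok <- is.finite(sd_expr) & is.finite(gc3_t)
    if (sum(ok) >= 2 * genes_per_bin) {
      bf <- binned_fit(zscore(gc3_t[ok]), zscore(sd_expr[ok]),
                       genes_per_bin = genes_per_bin)
      res$expression_fit <- bf
      summary$expr_sd_slope <- bf$fit$slope
      summary$expr_sd_intercept <- bf$fit$intercept
      summary$expr_sd_r_squared <- bf$fit$r_squared
    }
  } else {
    .msgf("no expression matrix: skipping expression-variability analysis")
  }

  if (!is.null(table$snp_per_kb) && sum(is.finite(table$snp_per_kb)) >=
      2 * genes_per_bin) {
    sf <- snp_fit(gc3_t, table$snp_per_kb, genes_per_bin = genes_per_bin)
    res$snp_fit <- sf
    summary$snp_intercept <- sf$fit$intercept
    summary$snp_slope <- sf$fit$slope
    summary$snp_r_squared <- sf$fit$r_squared
  }

  if (!is.null(table$intron_density)) {
    summary$intron_density_pearson <- pearson_cor(gc3_t, table$intron_density)
    hp <- try(high_class_probability(table$intron_density, lab_t,
                                     genes_per_bin = genes_per_bin),
              silent = TRUE)
    if (!inherits(hp, "try-error")) {
      res$intron_class_curve <- hp
      summary$intron_class_chi2 <- hp$chi2_stat
      summary$intron_class_p <- hp$p_value
    }
  }

  if (!is.null(table$promoter_seq) && any(!is.na(table$promoter_seq))) {
    pro_ok <- which(!is.na(table$promoter_seq))
    tata <- tata_scan(setNames(table$promoter_seq[pro_ok],
                               table$gene_id[pro_ok]))
    gc3_p <- gc3_t[pro_ok]
    res$tata <- tata
    if (length(tata) >= tata_genes_per_bin) {
      res$tata_curve <- frequency_by_gc3(tata, gc3_p,
                                         genes_per_bin = tata_genes_per_bin)
    }
    lo_sel <- gc3_p < tata_endpoints[1]
    hi_sel <- gc3_p > tata_endpoints[2]
    summary$tata_frac_low_gc3 <- if (any(lo_sel)) mean(tata[lo_sel]) else NA_real_
    summary$tata_frac_high_gc3 <- if (any(hi_sel)) mean(tata[hi_sel]) else NA_real_
    summary$tata_frac_overall <- mean(tata)

    if ("flanking" %in% analyses) {
      di <- .mono_freq_matrix(table$promoter_seq[pro_ok])
      flank_gc <- di[, "C"] + di[, "G"]
      set.seed(derive_seed(seed, 9L))
      fl <- flanking_gc_association(gc3_p, flank_gc)
      res$flanking <- fl
      summary$flanking_gc_r <- fl$r
      summary$flanking_gc_p <- fl$p_value
      hp2 <- try(high_class_probability(flank_gc, lab_t[pro_ok],
                                        genes_per_bin = genes_per_bin),
                 silent = TRUE)
      if (!inherits(hp2, "try-error")) res$promoter_class_curve <- hp2
    }
  } else {
    .msgf("no promoters: skipping TATA and flanking analyses")
  }

  if (!is.null(table$categories)) {
    cp <- try(category_profile(gc3_t, gc12_t, table$categories), silent = TRUE)
    if (!inherits(cp, "try-error")) {
      res$categories <- cp
      summary$category_cv_ratio <- cp$cv_ratio
    }
  }

  if ("gradient" %in% analyses) {
    gp <- try(gradient_profile(cds, classes$labels), silent = TRUE)
    if (!inherits(gp, "try-error")) {
      res$gradient <- gp
      plateau <- function(cl) {
        g <- gp[gp$class == cl & !is.na(gp$mean_cg3_skew), ]
        if (!nrow(g)) return(NA_real_)
        mean(tail(g$mean_cg3_skew, max(1L, nrow(g) %/% 4L)))
      }
      summary$cg3_skew_plateau_high <- plateau("high")
      summary$cg3_skew_plateau_low <- plateau("low")
    }
  }

  if ("pca" %in% analyses) {
    um <- try(codon_usage_matrix(cds), silent = TRUE)
    if (!inherits(um, "try-error") && nrow(um) > 3) {
      pr <- pca_codon_usage(um, gc3[rownames(um)])
      res$pca <- pr
      summary$pc1_variance_fraction <- pr$variance_fraction[1]
      summary$corr_pc1_gc3 <- pr$corr_pc1_gc3
      summary$abs_corr_pc1_gc3 <- pr$abs_corr_pc1_gc3
    }
  }

  res$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(comp, file.path(out_dir, "composition.tsv"))
    if (!is.null(res$signatures)) {
      .write_tsv(res$signatures, file.path(out_dir, "signatures.tsv"))
    }
    .write_tsv(data.frame(gene_id = names(gc3), gc3 = as.numeric(gc3),
                          label = as.character(classes$labels)),
               file.path(out_dir, "classes.tsv"))
    if (!is.null(res$clumps)) {
      .write_tsv(res$clumps$clumps, file.path(out_dir, "clumps.tsv"))
    }
    assoc_dir <- file.path(out_dir, "associations")
    dir.create(assoc_dir, showWarnings = FALSE)
    if (!is.null(res$expression_fit)) {
      .write_tsv(res$expression_fit$bins, file.path(assoc_dir, "expression_bins.tsv"))
    }
    if (!is.null(res$snp_fit)) {
      .write_tsv(res$snp_fit$bins, file.path(assoc_dir, "snp_bins.tsv"))
    }
    if (!is.null(res$tata_curve)) {
      .write_tsv(res$tata_curve, file.path(assoc_dir, "tata_curve.tsv"))
    }
    if (!is.null(res$gradient)) {
      .write_tsv(res$gradient, file.path(out_dir, "gradient.tsv"))
    }
    if (!is.null(res$pca)) {
      pca_dir <- file.path(out_dir, "pca")
      dir.create(pca_dir, showWarnings = FALSE)
      .write_tsv(data.frame(gene_id = names(res$pca$pc1_scores),
                            pc1 = as.numeric(res$pca$pc1_scores)),
                 file.path(pca_dir, "pc1_scores.tsv"))
      .write_tsv(data.frame(component = seq_along(res$pca$variance_fraction),
                            variance_fraction = res$pca$variance_fraction),
                 file.path(pca_dir, "variance.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(res)
}
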