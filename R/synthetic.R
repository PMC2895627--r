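# Seeded generator of a full synthetic dataset: CDS FASTA, promoters,
# genomic layout and covariate tables, with planted truth for every
# association the pipeline estimates. The generator is a test harness that
# plants the effect structure reported for grass genomes; it is not a
# generative model of rice biology.

#' Configuration for the synthetic dataset generator
#'
#' Defaults are the study conditions the pipeline is validated under: a
#' two-component GC3 mixture (70% low around 0.60, 30% high around 0.90),
#' class-dependent CG3 skew (+0.05 high / -0.10 low), mild 5'->3' GC3
#' gradients, TATA frequency rising from 18% below GC3 0.45 to 52% above
#' 0.95, expression-SD z-score tied to the GC3 z-score with slope 0.228 and
#' intercept 0.0294, intron density with Pearson -0.3 against GC3, and SNP
#' density 1.114 + 0.583 GC3.
#'
#' @param n_genes Number of genes.
#' @param seed Global seed; all randomness flows from it through
#'   deterministic per-gene substreams, so regeneration is order-independent.
#' @param gc3_mixture `weight_low`, `mean_low`, `sd_low`, `mean_high`,
#'   `sd_high` of the two Beta components (parameterised by mean and sd;
#'   Gaussian components would leak outside \[0,1\]).
#' @param skew_by_class Target realized CG3 skew per class. Internally
#'   converted to the choice-level skew applied where both C- and G-ending
#'   synonyms exist, compensating for amino acids whose single GC-ending
#'   synonym forces C3 or G3.
#' @param gradient Target 5'->3' change in GC3 per class (difference between
#'   the 3' and 5' local targets).
#' @param protein_length `median_codons` and lognormal `sigma` of total
#'   codons per gene (incl. start and stop).
#' @param tata `p_low`, `p_high`, the GC3 anchor points `gc3_lo`, `gc3_hi`
#'   between which the TATA probability is interpolated, the `motif`
#'   inserted, its centre `position` (upstream of the TSS) and `jitter`.
#' @param expr `n_conditions`, `sd_slope`, `sd_intercept`, `noise_sd` (the
#'   default completes the planted linear term to unit variance on the
#'   z-scale, which is what calibrates the recovered binned fit to the
#'   planted line), and the affine map (`sd_center`, `sd_scale`) from the
#'   z-scale latent to a positive per-gene SD.
#' @param introns `target_pearson` between GC3 and intron density,
#'   `rate_per_kb` baseline and the `unspliced_factor` mapping CDS length to
#'   unspliced transcript length.
#' @param snp `intercept`, `slope`, `noise_sd` of SNPs/kb on GC3.
#' @param layout `n_chrom` and optional `clump_spec`: a list of
#'   `list(chrom =, size =)` runs of consecutive high-class genes to plant.
#' @param promoter `length` (nt) and background `gc` fraction (independent
#'   of the gene's GC3, so flanking GC is uncorrelated by construction).
#' @param paralog `base`, `slope`: geometric paralog counts with mean
#'   `base - slope * gc3`.
#' @param categories `n_categories` and `effect_sd`: genes pick a category
#'   with log-odds proportional to a category effect times their GC3
#'   z-score, planting category-specific GC3 shifts. 0 categories disables.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_genes = 15000L,
    seed = 1L,
    gc3_mixture = list(weight_low = 0.7, mean_low = 0.60, sd_low = 0.06,
                       mean_high = 0.90, sd_high = 0.04),
    skew_by_class = c(high = 0.05, low = -0.10),
    gradient = c(high = 0.05, low = -0.05),
    protein_length = list(median_codons = 300, sigma = 0.45),
    tata = list(p_low = 0.18, p_high = 0.52, gc3_lo = 0.45, gc3_hi = 0.95,
                motif = "TATAAATA", position = 35L, jitter = 5L),
    expr = list(n_conditions = 106L, sd_slope = 0.228, sd_intercept = 0.0294,
                noise_sd = sqrt(1 - 0.228^2), sd_center = 1.0, sd_scale = 0.3),
    introns = list(target_pearson = -0.3, rate_per_kb = 3, unspliced_factor = 2.5),
    snp = list(intercept = 1.114, slope = 0.583, noise_sd = 0.1),
    layout = list(n_chrom = 12L, clump_spec = NULL),
    promoter = list(length = 1000L, gc = 0.40),
    paralog = list(base = 3, slope = 2),
    categories = list(n_categories = 12L, effect_sd = 0.6)) {
  mx <- gc3_mixture
  stopifnot(n_genes >= 1, mx$weight_low >= 0, mx$weight_low <= 1,
            mx$sd_low > 0, mx$sd_high > 0,
            tata$p_low >= 0, tata$p_low <= 1, tata$p_high >= 0, tata$p_high <= 1,
            protein_length$median_codons >= 30)
  structure(list(
    n_genes = as.integer(n_genes), seed = as.integer(seed),
    gc3_mixture = mx, skew_by_class = skew_by_class, gradient = gradient,
    protein_length = protein_length, tata = tata, expr = expr,
    introns = introns, snp = snp, layout = layout, promoter = promoter,
    paralog = paralog, categories = categories),
    class = "synthetic_config")
}

.beta_ab <- function(m, s) {
  k <- m * (1 - m) / s^2 - 1
  if (k <= 0) .stopf("Beta sd %.3f too large for mean %.3f", s, m)
  c(a = m * k, b = (1 - m) * k)
}

.mixture_density <- function(mx, grid) {
  lo <- .beta_ab(mx$mean_low, mx$sd_low)
  hi <- .beta_ab(mx$mean_high, mx$sd_high)
  mx$weight_low * stats::dbeta(grid, lo["a"], lo["b"]) +
    (1 - mx$weight_low) * stats::dbeta(grid, hi["a"], hi["b"])
}

.planted_valley <- function(mx) {
  if (mx$weight_low >= 1 || mx$weight_low <= 0 ||
      isTRUE(all.equal(mx$mean_low, mx$mean_high))) {
    return(NA_real_)
  }
  lo <- min(mx$mean_low, mx$mean_high)
  hi <- max(mx$mean_low, mx$mean_high)
  grid <- seq(lo, hi, length.out = 2001L)
  d <- .mixture_density(mx, grid)
  grid[which.min(d)]
}

#' Draw per-gene target GC3 values and class truth
#'
#' Samples `n_genes` targets from the two-component Beta mixture, clipped to
#' \[0.05, 0.99\]; component membership is the planted class truth. The
#' planted valley (density minimum of the target mixture between the
#' component means) is stored in the `"planted_valley"` attribute.
#'
#' @param config A [synthetic_config()].
#' @return Data frame `gene_id`, `target_gc3`, `class_true`.
#' @export
sample_gc3_targets <- function(config) {
  mx <- config$gc3_mixture
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  if (isTRUE(all.equal(mx$mean_low, mx$mean_high))) {
    .warnf("mixture components coincide; modality truth is unimodal")
  }
  is_low <- runif(n) < mx$weight_low
  lo <- .beta_ab(mx$mean_low, mx$sd_low)
  hi <- .beta_ab(mx$mean_high, mx$sd_high)
  gc3 <- numeric(n)
  gc3[is_low] <- stats::rbeta(sum(is_low), lo["a"], lo["b"])
  gc3[!is_low] <- stats::rbeta(sum(!is_low), hi["a"], hi["b"])
  gc3 <- pmin(pmax(gc3, 0.05), 0.99)
  out <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    target_gc3 = gc3,
    class_true = ifelse(is_low, "low", "high"),
    stringsAsFactors = FALSE)
  attr(out, "planted_valley") <- .planted_valley(mx)
  out
}

#' Generate one coding sequence with planted composition
#'
#' Draws (or accepts) a protein over the 18 amino acids that have both
#' AT-ending and GC-ending synonyms available in at least one direction
#' (everything except Met and Trp), then chooses a synonymous codon per
#' residue: a GC-ending synonym with probability equal to the local target
#' (`target_gc3` plus the gradient ramp), the C-vs-G ending resolved by the
#' skew whenever the amino acid offers both. Codons whose amino acid offers
#' only a C- or only a G-ending synonym are forced and bookkept. The
#' sequence starts with ATG and ends with a stop codon; the translation of
#' the output equals the input protein.
#'
#' Uses the current RNG stream; callers seed it (the dataset generator uses
#' a per-gene substream).
#'
#' @param n_codons Total codons including start and stop (>= 30); ignored
#'   when `protein` is given.
#' @param target_gc3 Target third-position GC fraction.
#' @param skew Target CG3 skew among GC-ending choices, in \[-1, 1\].
#' @param gradient_delta 5'->3' difference in the local GC3 target.
#' @param protein Optional character vector of interior amino acids
#'   (single-letter, no Met/Trp/stop).
#' @return List: `sequence`, `protein` (interior residues), and bookkeeping
#'   `realized_gc3`, `c3`, `g3`, `n_codons`, `n_skew_eligible`,
#'   `n_skew_forced`.
#' @export
generate_cds <- function(n_codons, target_gc3, skew = 0, gradient_delta = 0,
                         protein = NULL) {
  tab <- .codon_tables()
  if (is.null(protein)) {
    stopifnot(n_codons >= 30)
    m <- as.integer(n_codons) - 2L
    protein <- sample(tab$aa18, m, replace = TRUE)
  } else {
    stopifnot(all(protein %in% tab$aa18))
    m <- length(protein)
  }
  ai <- match(protein, tab$aa18)
  j <- seq_len(m)
  t_local <- pmin(pmax(target_gc3 + gradient_delta * ((j - 0.5) / m - 0.5),
                       0), 1)
  u_gc <- runif(m)
  u_cg <- runif(m)
  u_pick <- runif(m)
  n_c <- tab$n_c[ai]
  n_g <- tab$n_g[ai]
  want_gc <- u_gc < t_local
  both <- n_c > 0L & n_g > 0L
  use_c <- want_gc & ((both & u_cg < (1 + skew) / 2) | (!both & n_c > 0L))
  use_g <- want_gc & !use_c
  codons <- character(m)
  pick_k <- function(nn) pmin(pmax(nn, 1L), pmax(1L, ceiling(u_pick * nn)))
  if (any(!want_gc)) {
    k <- pick_k(tab$n_at[ai])
    codons[!want_gc] <- tab$at_mat[cbind(ai, k)][!want_gc]
  }
  if (any(use_c)) {
    k <- pick_k(n_c)
    codons[use_c] <- tab$c_mat[cbind(ai, k)][use_c]
  }
  if (any(use_g)) {
    k <- pick_k(n_g)
    codons[use_g] <- tab$g_mat[cbind(ai, k)][use_g]
  }
  # stop codon: TAG is the only GC-ending stop
  t_end <- pmin(pmax(target_gc3 + gradient_delta / 2, 0), 1)
  stop_codon <- if (runif(1) < t_end) "TAG" else sample(c("TAA", "TGA"), 1L)

  thirds <- c("G", substr(codons, 3L, 3L), substr(stop_codon, 3L, 3L))
  n_tot <- m + 2L
  c3 <- sum(thirds == "C")
  g3 <- sum(thirds == "G")
  list(sequence = paste0("ATG", paste(codons, collapse = ""), stop_codon),
       protein = protein,
       realized_gc3 = (c3 + g3) / n_tot,
       c3 = c3, g3 = g3, n_codons = n_tot,
       n_skew_eligible = sum(want_gc & both),
       n_skew_forced = sum(want_gc & !both))
}

# Convert a target realized CG3 skew into the choice-level skew applied to
# amino acids with both C- and G-ending synonyms. Under a uniform protein
# over the 18 usable amino acids, GC-ending codons split 8 both-available :
# 7 C-forced : 3 G-forced, so the realized skew is (8 s + 4) / 18 and the
# required choice-level skew is s = (18 sigma - 4) / 8.
.choice_skew <- function(target_skew) {
  pmin(pmax((18 * target_skew - 4) / 8, -1), 1)
}

.generate_genes <- function(targets, config) {
  n <- nrow(targets)
  pl <- config$protein_length
  skew <- .choice_skew(config$skew_by_class[targets$class_true])
  grad <- config$gradient[targets$class_true]
  seqs <- character(n)
  realized <- numeric(n)
  n_cod <- integer(n)
  c3 <- integer(n); g3 <- integer(n)
  eligible <- integer(n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, 1000L + i))
    len <- max(30L, as.integer(round(
      rlnorm(1, log(pl$median_codons), pl$sigma))))
    g <- generate_cds(len, targets$target_gc3[i], skew[i], grad[i])
    seqs[i] <- g$sequence
    realized[i] <- g$realized_gc3
    n_cod[i] <- g$n_codons
    c3[i] <- g$c3; g3[i] <- g$g3
    eligible[i] <- g$n_skew_eligible
  }
  names(seqs) <- targets$gene_id
  list(cds = as_cds_set(seqs),
       truth = data.frame(gene_id = targets$gene_id,
                          realized_gc3 = realized, n_codons = n_cod,
                          c3 = c3, g3 = g3, n_skew_eligible = eligible,
                          stringsAsFactors = FALSE))
}

.interp_prob <- function(gc3, lo, hi, p_lo, p_hi) {
  w <- pmin(pmax((gc3 - lo) / (hi - lo), 0), 1)
  p_lo + (p_hi - p_lo) * w
}

.random_dna <- function(n, len, gc) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  m <- matrix(.BASES[sample.int(4L, n * len, replace = TRUE, prob = prob)],
              nrow = n, ncol = len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate planted covariates for a set of genes
#'
#' Plants every modelled association on the realized GC3 values: an
#' expression matrix whose per-gene SD follows the configured line on the
#' z-scale; Poisson intron counts whose density achieves the target Pearson
#' correlation with GC3 (the linear-rate coefficient is solved in closed
#' form, with an error when the target exceeds the bound achievable under
#' Poisson noise); SNPs/kb on the configured line; a TATA indicator with
#' probability interpolated between the endpoint anchors, realised as a
#' motif inserted into an otherwise motif-free promoter window; geometric
#' paralog counts with GC3-decreasing mean; and optional category labels
#' with planted GC3 shifts.
#'
#' @param gc3 Per-gene realized GC3 (named by gene id).
#' @param n_codons Per-gene codon counts (for transcript lengths).
#' @param config A [synthetic_config()].
#' @return List with `covariates` (data frame), `expression` (matrix),
#'   `promoters` (named character), and `truth` (per-gene planted values).
#' @export
generate_covariates <- function(gc3, n_codons, config) {
  set.seed(derive_seed(config$seed, 2L))
  n <- length(gc3)
  ids <- names(gc3) %||% sprintf("g%05d", seq_len(n))
  zx <- zscore(gc3)

  # expression: latent z-scale SD, mapped affinely to a positive SD
  ex <- config$expr
  latent <- ex$sd_slope * zx + ex$sd_intercept + rnorm(n, 0, ex$noise_sd)
  sd_true <- pmax(ex$sd_center + ex$sd_scale * latent, 0.05)
  mu <- rnorm(n, 6, 1)
  expr <- matrix(rnorm(n * ex$n_conditions, mean = mu, sd = sd_true),
                 nrow = n, ncol = ex$n_conditions)
  rownames(expr) <- ids
  colnames(expr) <- sprintf("expr_%03d", seq_len(ex$n_conditions))

  # introns: Poisson counts with linear-in-z rate; closed-form calibration
  ic <- config$introns
  l_kb <- pmax(n_codons * 3 * ic$unspliced_factor / 1000, 0.05)
  r <- ic$target_pearson
  mu0 <- ic$rate_per_kb
  beta <- r * sqrt(mu0 * mean(1 / l_kb)) / (mu0 * sqrt(1 - r^2))
  if (max(abs(beta * zx)) >= 1) {
    .stopf(paste("intron Pearson target %.2f infeasible under Poisson noise;",
                 "|beta * z| reaches %.2f (must stay < 1)"),
           r, max(abs(beta * zx)))
  }
  lambda <- l_kb * mu0 * (1 + beta * zx)
  intron_count <- rpois(n, pmax(lambda, 1e-6))
  intron_density <- intron_count / l_kb

  # SNP density
  sn <- config$snp
  snp_per_kb <- pmax(sn$intercept + sn$slope * gc3 + rnorm(n, 0, sn$noise_sd), 0)

  # TATA indicator and promoters
  ta <- config$tata
  p_tata <- .interp_prob(gc3, ta$gc3_lo, ta$gc3_hi, ta$p_low, ta$p_high)
  tata <- rbinom(n, 1L, p_tata) == 1L
  pr <- config$promoter
  promoters <- .random_dna(n, pr$length, pr$gc)
  # scrub chance motifs from the scan window of TATA- promoters
  win <- 50L
  for (pass in 1:25) {
    hit <- tata_scan(promoters, window_nt = win)
    bad <- which(!tata & hit)
    if (!length(bad)) break
    repl <- .random_dna(length(bad), win, pr$gc)
    substr(promoters[bad], pr$length - win + 1L, pr$length) <- repl
  }
  ins <- which(tata)
  if (length(ins)) {
    offset <- ta$position + sample(-ta$jitter:ta$jitter, length(ins),
                                   replace = TRUE)
    start <- pr$length - offset + 1L
    substr(promoters[ins], start, start + nchar(ta$motif) - 1L) <- ta$motif
  }
  names(promoters) <- ids

  # paralogs: geometric, mean decreasing in GC3
  pa <- config$paralog
  pmean <- pmax(pa$base - pa$slope * gc3, 0.1)
  paralog_count <- rgeom(n, prob = 1 / (1 + pmean))

  # categories with planted GC3 shifts
  ca <- config$categories
  cat_lab <- rep(NA_character_, n)
  cat_eff <- NULL
  if (ca$n_categories > 0) {
    cat_eff <- seq(-ca$effect_sd, ca$effect_sd, length.out = ca$n_categories)
    w <- exp(outer(zx, cat_eff))
    w <- w / rowSums(w)
    cum <- t(apply(w, 1L, cumsum))
    u <- runif(n)
    pick <- max.col(cum >= u, ties.method = "first")
    cat_lab <- sprintf("cat%02d", pick)
  }

  cov <- data.frame(gene_id = ids,
                    intron_count = intron_count,
                    intron_density = intron_density,
                    paralog_count = paralog_count,
                    snp_per_kb = snp_per_kb,
                    categories = cat_lab,
                    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, sd_true = sd_true, p_tata = p_tata,
                      tata_true = tata, lambda_intron = lambda,
                      stringsAsFactors = FALSE)
  list(covariates = cov, expression = expr, promoters = promoters,
       truth = truth, category_effects = cat_eff, intron_beta = beta)
}

#' Generate a genomic layout with null adjacent-gene correlation
#'
#' Genes are placed in a random order across `n_chrom` chromosomes with
#' sequential non-overlapping coordinates, so the GC3 correlation between
#' adjacent genes is zero by construction. `clump_spec` optionally forces
#' runs of consecutive high-class genes at the start of stated chromosomes.
#'
#' @param gene_id Gene ids.
#' @param n_codons Per-gene codon counts (genomic span is scaled CDS length).
#' @param class_true Per-gene class truth (needed when planting clumps).
#' @param config A [synthetic_config()].
#' @return Layout data frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
generate_layout <- function(gene_id, n_codons, class_true, config) {
  set.seed(derive_seed(config$seed, 3L))
  n <- length(gene_id)
  ord <- sample.int(n)
  spec <- config$layout$clump_spec
  if (!is.null(spec)) {
    slots_used <- 0L
    per_chrom <- ceiling(n / config$layout$n_chrom)
    taken <- logical(n)
    for (s in spec) {
      hi <- setdiff(which(class_true == "high"), which(taken))
      if (length(hi) < s$size) {
        .stopf("clump_spec needs %d high genes; only %d remain", s$size, length(hi))
      }
      put <- hi[seq_len(s$size)]
      taken[put] <- TRUE
      slot0 <- (s$chrom - 1L) * per_chrom + 1L
      slots <- slot0:(slot0 + s$size - 1L)
      # swap the chosen genes into consecutive slots
      for (k in seq_along(slots)) {
        cur <- which(ord == put[k])
        tmp <- ord[slots[k]]
        ord[slots[k]] <- put[k]
        ord[cur] <- tmp
      }
      slots_used <- slots_used + s$size
    }
  }
  chrom_of <- rep(seq_len(config$layout$n_chrom),
                  each = ceiling(n / config$layout$n_chrom))[seq_len(n)]
  span <- as.integer(round(n_codons[ord] * 3 * config$introns$unspliced_factor))
  start <- integer(n)
  end <- integer(n)
  pos <- rep(1L, config$layout$n_chrom)
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    start[i] <- pos[ch]
    end[i] <- pos[ch] + span[i] - 1L
    pos[ch] <- end[i] + 2000L
  }
  data.frame(gene_id = gene_id[ord],
             chrom = sprintf("chr%02d", chrom_of),
             start = start, end = end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic dataset
#'
#' Draws GC3 targets, generates coding sequences, covariates, promoters and
#' a genomic layout, and (optionally) writes the dataset to disk as
#' `cds.fasta`, `promoters.fasta`, `layout.gff3`, `covariates.tsv`,
#' `truth.json` and `config.json`. Regeneration from the same `(config,
#' seed)` is byte-identical.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory, or `NULL` for an in-memory dataset only.
#' @return List with `config`, `cds` (a `cds_set`), `table` (a `gene_table`
#'   with expression attribute and promoter sequences), and `truth` (list:
#'   `per_gene` data frame and `globals`).
#' @export
simulate_dataset <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  targets <- sample_gc3_targets(config)
  gen <- .generate_genes(targets, config)
  gc3 <- setNames(gen$truth$realized_gc3, gen$truth$gene_id)
  cov <- generate_covariates(gc3, gen$truth$n_codons, config)
  layout <- generate_layout(targets$gene_id, gen$truth$n_codons,
                            targets$class_true, config)

  per_gene <- cbind(targets[, c("gene_id", "target_gc3", "class_true")],
                    gen$truth[, -1, drop = FALSE],
                    cov$truth[, -1, drop = FALSE])
  globals <- list(
    planted_valley = attr(targets, "planted_valley"),
    expr_sd_slope = config$expr$sd_slope,
    expr_sd_intercept = config$expr$sd_intercept,
    snp_intercept = config$snp$intercept,
    snp_slope = config$snp$slope,
    intron_pearson = config$introns$target_pearson,
    intron_beta = cov$intron_beta,
    tata_p_low = config$tata$p_low,
    tata_p_high = config$tata$p_high,
    skew_high = unname(config$skew_by_class["high"]),
    skew_low = unname(config$skew_by_class["low"]),
    category_effects = cov$category_effects)

  table <- read_gene_table(gen$cds, layout = layout,
                           covariates = cov$covariates,
                           promoters = cov$promoters)
  attr(table, "expression") <- cov$expression

  out <- list(config = config, cds = gen$cds, table = table,
              truth = list(per_gene = per_gene, globals = globals))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_cds_fasta(gen$cds, file.path(dir, "cds.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(cov$promoters),
      file.path(dir, "promoters.fasta"), width = 80L)
    gr <- GenomicRanges::GRanges(
      seqnames = layout$chrom,
      ranges = IRanges::IRanges(start = layout$start, end = layout$end),
      strand = layout$strand)
    gr$type <- "gene"
    gr$ID <- layout$gene_id
    rtracklayer::export(gr, file.path(dir, "layout.gff3"), format = "gff3")
    cov_out <- cbind(cov$covariates,
                     as.data.frame(cov$expression, stringsAsFactors = FALSE))
    .write_tsv(cov_out, file.path(dir, "covariates.tsv"))
    jsonlite::write_json(
      list(per_gene = per_gene, globals = globals),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    out$dir <- dir
  }
  out
}

#' Load a synthetic (or equivalently structured) dataset directory
#'
#' Reads back the files written by [simulate_dataset()].
#'
#' @param dir Directory with `cds.fasta`, and optionally `promoters.fasta`,
#'   `layout.gff3`, `covariates.tsv`.
#' @param policy A [validation_policy()].
#' @return List with `cds` and `table`.
#' @export
load_dataset <- function(dir, policy = validation_policy()) {
  cds <- read_cds_fasta(file.path(dir, "cds.fasta"), policy)
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  table <- read_gene_table(cds, layout = p("layout.gff3"),
                           covariates = p("covariates.tsv"),
                           promoters = p("promoters.fasta"))
  list(cds = cds, table = table)
}
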