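#' Validation policy for coding sequences
#'
#' Controls how CDS records that are out of frame, ambiguous, or very short
#' are handled when a FASTA file is read.
#'
#' @param frame_policy What to do with a sequence whose length is not a
#'   multiple of 3: `"reject"` drops the gene into the rejection report,
#'   `"trim_tail"` truncates the trailing 1-2 nucleotides.
#' @param ambiguity_policy What to do with codons containing `N` (any
#'   non-ACGT character is mapped to `N` first): `"drop_codon"` removes the
#'   affected codons from the retained sequence, `"reject_gene"` rejects the
#'   whole gene.
#' @param min_codons Genes with fewer retained codons are flagged as short.
#'   They are kept (composition statistics are still defined) but excluded
#'   from sliding-window gradient profiles and the codon-usage matrix.
#' @return An object of class `validation_policy`.
#' @export
validation_policy <- function(frame_policy = c("reject", "trim_tail"),
                              ambiguity_policy = c("drop_codon", "reject_gene"),
                              min_codons = 30L) {
  frame_policy <- match.arg(frame_policy)
  ambiguity_policy <- match.arg(ambiguity_policy)
  min_codons <- as.integer(min_codons)
  stopifnot(min_codons >= 1L)
  structure(list(frame_policy = frame_policy,
                 ambiguity_policy = ambiguity_policy,
                 min_codons = min_codons),
            class = "validation_policy")
}

new_cds_set <- function(gene_id, sequence, short_flag,
                        rejected = NULL, n_input = length(gene_id)) {
  stopifnot(length(gene_id) == length(sequence))
  x <- list(gene_id = as.character(gene_id),
            sequence = toupper(as.character(sequence)),
            n_codons = as.integer(nchar(sequence) / 3L),
            short_flag = as.logical(short_flag))
  attr(x, "rejected") <- rejected %||%
    data.frame(gene_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  attr(x, "n_input") <- n_input
  class(x) <- "cds_set"
  x
}

#' Build a CDS set from an in-memory named character vector
#'
#' Convenience constructor used by the synthetic generator and in tests; the
#' same validation policy as [read_cds_fasta()] is applied.
#'
#' @param sequences Named character vector of nucleotide sequences; names are
#'   gene ids.
#' @param policy A [validation_policy()].
#' @return A `cds_set` with a `rejected` attribute (data frame of gene id and
#'   reason) and an `n_input` attribute.
#' @export
as_cds_set <- function(sequences, policy = validation_policy()) {
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    .stopf("all sequences must be named with a gene id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    .stopf("duplicate gene_id(s): %s", paste(head(dup, 5), collapse = ", "))
  }
  if (length(sequences) == 0) .stopf("empty CDS set")
  .validate_cds(ids, toupper(as.character(sequences)), policy)
}

.validate_cds <- function(ids, seqs, policy) {
  seqs <- gsub("[^ACGT]", "N", seqs)
  reason <- rep(NA_character_, length(ids))

  len <- nchar(seqs)
  off_frame <- len %% 3L != 0L
  if (policy$frame_policy == "reject") {
    reason[off_frame] <- "out_of_frame"
  } else {
    seqs[off_frame] <- substr(seqs[off_frame], 1L, (len %/% 3L * 3L)[off_frame])
  }

  has_n <- grepl("N", seqs, fixed = TRUE)
  fix <- which(has_n & is.na(reason))
  if (policy$ambiguity_policy == "reject_gene") {
    reason[fix] <- "ambiguous"
  } else if (length(fix)) {
    seqs[fix] <- vapply(seqs[fix], function(s) {
      cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
      paste(cod[!grepl("N", cod, fixed = TRUE)], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  empty <- nchar(seqs) == 0L & is.na(reason)
  reason[empty] <- "no_codons_retained"

  keep <- is.na(reason)
  rejected <- data.frame(gene_id = ids[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  short <- (nchar(seqs[keep]) / 3L) < policy$min_codons
  new_cds_set(ids[keep], seqs[keep], short, rejected, n_input = length(ids))
}

#' Read and validate a CDS FASTA file
#'
#' Headers are truncated at the first whitespace to obtain the gene id.
#' Genes failing the policy are reported in the `rejected` attribute of the
#' result, never silently dropped; input order is preserved.
#'
#' @param path Path to a FASTA file of coding sequences.
#' @param policy A [validation_policy()].
#' @return A `cds_set`: list with elements `gene_id`, `sequence` (the
#'   retained, whole-codon sequence), `n_codons`, `short_flag`.
#' @export
read_cds_fasta <- function(path, policy = validation_policy()) {
  if (!file.exists(path)) .stopf("cannot read FASTA file: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) .stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  names(seqs) <- ids
  as_cds_set(seqs, policy)
}

#' Write a CDS set to FASTA
#'
#' @param cds A `cds_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  stopifnot(inherits(cds, "cds_set"))
  x <- Biostrings::DNAStringSet(setNames(cds$sequence, cds$gene_id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @export
length.cds_set <- function(x) length(x$gene_id)

#' @export
print.cds_set <- function(x, ...) {
  rej <- attr(x, "rejected")
  cat(sprintf("<cds_set> %d genes (%d rejected of %d input), %d flagged short\n",
              length(x), nrow(rej), attr(x, "n_input"), sum(x$short_flag)))
  invisible(x)
}

#' @export
`[.cds_set` <- function(x, i) {
  new_cds_set(x$gene_id[i], x$sequence[i], x$short_flag[i],
              rejected = attr(x, "rejected"), n_input = attr(x, "n_input"))
}

#' Extract the codons of one gene
#'
#' @param cds A `cds_set`.
#' @param i Gene index or gene id.
#' @return Character vector of consecutive non-overlapping codons.
#' @export
cds_codons <- function(cds, i) {
  if (is.character(i)) i <- match(i, cds$gene_id)
  s <- cds$sequence[i]
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

# ---- coordinate conversion -------------------------------------------------

#' Convert BED intervals to the internal 1-based inclusive convention
#'
#' @param df Data frame with `start`, `end` in BED convention (0-based,
#'   half-open).
#' @return The data frame in 1-based inclusive coordinates.
#' @export
bed_to_coords <- function(df) {
  df$start <- df$start + 1L
  df
}

#' Convert internal 1-based inclusive intervals back to BED
#'
#' Inverse of [bed_to_coords()].
#'
#' @param df Data frame with 1-based inclusive `start`, `end`.
#' @return The data frame in BED convention.
#' @export
coords_to_bed <- function(df) {
  df$start <- df$start - 1L
  df
}

.read_layout_gff3 <- function(path) {
  g <- rtracklayer::import(path)
  g <- g[g$type == "gene"]
  ids <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
  data.frame(gene_id = sub("^gene:", "", ids),
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

.read_layout_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t|[ ]+")
  bad <- which(lengths(parts) < 6L)
  if (length(bad)) .stopf("malformed BED line %d in %s", bad[1], path)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                   start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
                   end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
                   gene_id = vapply(parts, `[`, "", 4L),
                   strand = vapply(parts, `[`, "", 6L),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) {
    .stopf("malformed BED coordinates at line %d in %s",
           which(is.na(df$start) | is.na(df$end))[1], path)
  }
  bed_to_coords(df)[, c("gene_id", "chrom", "start", "end", "strand")]
}

# ---- gene table ------------------------------------------------------------

#' Assemble the per-gene covariate table
#'
#' Joins genomic layout, covariates and promoter sequences to the validated
#' CDS set. The result has one row per CDS gene; absent covariates are `NA`,
#' never imputed. `gene_index_on_chrom` ranks genes by start coordinate
#' within each chromosome. Expression values (covariate columns named
#' `expr_*`) are collected into a matrix stored in the `"expression"`
#' attribute.
#'
#' @param cds A `cds_set`.
#' @param layout Path to a GFF3 (`gene` features) or 6-column BED file, or a
#'   data frame with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#'   already in 1-based inclusive coordinates.
#' @param covariates Path to a tab-delimited file (header row, `.` for
#'   absent) keyed by `gene_id`, or an equivalent data frame. Recognised
#'   columns: `intron_count`, `intron_density`, `paralog_count`,
#'   `snp_per_kb`, `categories` (comma-separated labels) and any number of
#'   `expr_*` columns.
#' @param promoters Path to a TSS-anchored promoter FASTA (3' end of each
#'   sequence is position -1), or a named character vector.
#' @return A data frame of class `gene_table` with attribute `"expression"`.
#' @export
read_gene_table <- function(cds, layout = NULL, covariates = NULL,
                            promoters = NULL) {
  stopifnot(inherits(cds, "cds_set"))
  tab <- data.frame(gene_id = cds$gene_id, stringsAsFactors = FALSE)

  if (!is.null(layout)) {
    lay <- if (is.data.frame(layout)) {
      layout
    } else if (grepl("\\.bed$", layout, ignore.case = TRUE)) {
      .read_layout_bed(layout)
    } else {
      .read_layout_gff3(layout)
    }
    if (any(lay$start > lay$end)) .stopf("layout has start > end")
    extra <- setdiff(lay$gene_id, tab$gene_id)
    if (length(extra)) {
      .warnf("%d layout gene_id(s) not in the CDS set", length(extra))
    }
    m <- match(tab$gene_id, lay$gene_id)
    tab$chrom <- lay$chrom[m]
    tab$start <- lay$start[m]
    tab$end <- lay$end[m]
    tab$strand <- lay$strand[m]
    tab$gene_index_on_chrom <- NA_integer_
    for (ch in unique(tab$chrom[!is.na(tab$chrom)])) {
      idx <- which(!is.na(tab$chrom) & tab$chrom == ch)
      tab$gene_index_on_chrom[idx] <- rank(tab$start[idx], ties.method = "first")
    }
  }

  if (!is.null(covariates)) {
    cov <- if (is.data.frame(covariates)) covariates else .read_tsv(covariates)
    if (!"gene_id" %in% names(cov)) .stopf("covariate table lacks gene_id")
    extra <- setdiff(cov$gene_id, tab$gene_id)
    if (length(extra)) {
      .warnf("%d covariate gene_id(s) not in the CDS set", length(extra))
    }
    m <- match(tab$gene_id, cov$gene_id)
    expr_cols <- grep("^expr_", names(cov), value = TRUE)
    for (col in setdiff(names(cov), c("gene_id", expr_cols))) {
      v <- cov[[col]][m]
      if (col == "categories") {
        v <- strsplit(ifelse(is.na(v), "", as.character(v)), ",", fixed = TRUE)
      }
      tab[[col]] <- v
    }
    if (length(expr_cols)) {
      expr <- as.matrix(cov[m, expr_cols, drop = FALSE])
      rownames(expr) <- tab$gene_id
      attr(tab, "expression") <- expr
    }
  }

  if (!is.null(promoters)) {
    pro <- if (is.character(promoters) && length(promoters) == 1 &&
               file.exists(promoters)) {
      x <- Biostrings::readDNAStringSet(promoters)
      setNames(as.character(x), sub("\\s.*$", "", names(x)))
    } else {
      promoters
    }
    tab$promoter_seq <- unname(pro[tab$gene_id])
  }

  class(tab) <- c("gene_table", "data.frame")
  tab
}
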