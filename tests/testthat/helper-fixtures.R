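make_cds <- function(..., policy = validation_policy()) {
  seqs <- c(...)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("g", seq_along(seqs))
  }
  as_cds_set(seqs, policy)
}

# one-chromosome layout with genes in the given order
toy_table <- function(cds, chrom = "chr1") {
  n <- length(cds)
  lay <- data.frame(gene_id = cds$gene_id, chrom = chrom,
                    start = seq_len(n) * 1000L,
                    end = seq_len(n) * 1000L + 500L,
                    strand = "+", stringsAsFactors = FALSE)
  read_gene_table(cds, layout = lay)
}

# small in-memory synthetic run shared by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(synthetic_config(n_genes = 600, seed = 42))
    }
    cache
  }
})
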