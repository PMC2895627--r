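# Fixed codon bookkeeping shared by the composition, signature, codon-usage
# and generator code. Everything is keyed to the alphabetical (A < C < G < T)
# codon order, which is also the column order Biostrings uses for
# oligonucleotideFrequency(width = 3).

.BASES <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$tab)) {
    return(.codon_env$tab)
  }
  codons <- as.vector(t(outer(
    as.vector(t(outer(.BASES, .BASES, paste0))), .BASES, paste0
  )))
  codons <- sort(codons)  # AAA, AAC, ..., TTT
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  first <- substr(codons, 1L, 1L)
  second <- substr(codons, 2L, 2L)
  third <- substr(codons, 3L, 3L)

  # Amino acids usable by the generator: everything except Met, Trp and stop.
  aa18 <- sort(setdiff(unique(aa), c("M", "W", "*")))

  # Per amino acid: synonyms split by the third base being A/T, C, or G.
  at_cods <- lapply(aa18, function(a) codons[aa == a & third %in% c("A", "T")])
  c_cods <- lapply(aa18, function(a) codons[aa == a & third == "C"])
  g_cods <- lapply(aa18, function(a) codons[aa == a & third == "G"])
  pad <- function(lst) {
    w <- max(lengths(lst))
    t(vapply(lst, function(x) c(x, rep(NA_character_, w - length(x))), character(w)))
  }
  tab <- list(
    codons = codons, aa = aa, first = first, second = second, third = third,
    is_gc3 = third %in% c("C", "G"),
    is_gc1 = first %in% c("C", "G"),
    is_gc2 = second %in% c("C", "G"),
    aa18 = aa18,
    n_at = lengths(at_cods), n_c = lengths(c_cods), n_g = lengths(g_cods),
    at_mat = pad(at_cods), c_mat = pad(c_cods), g_mat = pad(g_cods),
    # sense codons used by the within-amino-acid usage matrix (59 codons)
    usage_codons = codons[!(aa %in% c("M", "W", "*"))]
  )
  .codon_env$tab <- tab
  tab
}
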