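# Independent brute-force oracles. Everything here works character by
# character (or by regex), deliberately avoiding the matrix/Biostrings code
# paths the package uses.

random_seq <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

bf_chars <- function(seq) strsplit(seq, "")[[1]]

# all overlapping k-mer counts as a named vector over the full 4^k alphabet
bf_kmer_counts <- function(seq, k) {
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1L,
                      function(r) paste(rev(r), collapse = "")))
  out <- setNames(integer(length(kmers)), kmers)
  n <- nchar(seq)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      out[w] <- out[w] + 1L
    }
  }
  out
}

bf_composition <- function(seq) {
  ch <- bf_chars(seq)
  n <- length(ch) %/% 3
  p1 <- ch[seq(1, 3 * n, 3)]
  p2 <- ch[seq(2, 3 * n, 3)]
  p3 <- ch[seq(3, 3 * n, 3)]
  gc <- c("C", "G")
  c3 <- sum(p3 == "C"); g3 <- sum(p3 == "G")
  list(n = n,
       a3 = sum(p3 == "A"), c3 = c3, g3 = g3, t3 = sum(p3 == "T"),
       gc1 = sum(p1 %in% gc) / n, gc2 = sum(p2 %in% gc) / n,
       gc3 = (c3 + g3) / n,
       gc12 = (sum(p1 %in% gc) + sum(p2 %in% gc)) / (2 * n),
       gc_total = sum(c(p1, p2, p3) %in% gc) / (3 * n),
       cg3_skew = if (c3 + g3 > 0) (c3 - g3) / (c3 + g3) else NA_real_)
}

bf_cg_gc_ratio <- function(seq) {
  k <- bf_kmer_counts(seq, 2)
  if (k["GC"] == 0) NA_real_ else unname(k["CG"] / k["GC"])
}

bf_rho_di <- function(seq) {
  n <- nchar(seq)
  k2 <- bf_kmer_counts(seq, 2) / (n - 1)
  k1 <- bf_kmer_counts(seq, 1) / n
  out <- setNames(numeric(16), names(k2))
  for (w in names(k2)) {
    d <- k1[substr(w, 1, 1)] * k1[substr(w, 2, 2)]
    out[w] <- if (d > 0) k2[w] / d else NA_real_
  }
  out
}

bf_rho_cwg <- function(seq) {
  n <- nchar(seq)
  k3 <- bf_kmer_counts(seq, 3) / (n - 2)
  k1 <- bf_kmer_counts(seq, 1) / n
  den <- k1["C"] * (k1["A"] + k1["T"]) * k1["G"]
  if (den > 0) unname((k3["CAG"] + k3["CTG"]) / den) else NA_real_
}

bf_positional_rho <- function(seq, kind) {
  ch <- bf_chars(seq)
  n <- length(ch) %/% 3
  p1 <- ch[seq(1, 3 * n, 3)]
  p2 <- ch[seq(2, 3 * n, 3)]
  p3 <- ch[seq(3, 3 * n, 3)]
  if (kind == "C2G3") {
    joint <- mean(p2 == "C" & p3 == "G")
    den <- mean(p2 == "C") * mean(p3 == "G")
  } else {
    if (n < 2) return(NA_real_)
    joint <- mean(p3[1:(n - 1)] == "C" & p1[2:n] == "G")
    den <- mean(p3[1:(n - 1)] == "C") * mean(p1[2:n] == "G")
  }
  if (den > 0) joint / den else NA_real_
}

bf_conditional_ratio <- function(seq, kind) {
  ch <- bf_chars(seq)
  n <- length(ch) %/% 3
  p1 <- ch[seq(1, 3 * n, 3)]
  p2 <- ch[seq(2, 3 * n, 3)]
  p3 <- ch[seq(3, 3 * n, 3)]
  rat <- function(a, b) {
    if (a == 0 && b == 0) NA_real_ else if (b == 0) Inf else a / b
  }
  if (kind == "G3_given_C2") {
    if (!any(p2 == "C")) return(NA_real_)
    rat(sum(p2 == "C" & p3 == "G"), sum(p2 == "C" & p3 == "C"))
  } else {
    if (n < 2) return(NA_real_)
    sel <- p1[2:n] == "G"
    if (!any(sel)) return(NA_real_)
    t_prev <- p3[1:(n - 1)][sel]
    rat(sum(t_prev == "C"), sum(t_prev == "G"))
  }
}

chi2_closed_form <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# regex-based clump enumeration: separators are runs of > max_gap lows;
# within each remaining segment the high genes form one candidate clump
clump_oracle <- function(labels, min_size, max_gap) {
  n <- length(labels)
  s <- paste(ifelse(labels == "high", "H", "L"), collapse = "")
  sep <- gregexpr(sprintf("L{%d,}", max_gap + 1L), s)[[1]]
  covered <- logical(n)
  if (sep[1] != -1) {
    for (j in seq_along(sep)) {
      covered[sep[j]:(sep[j] + attr(sep, "match.length")[j] - 1L)] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- list()
  for (j in which(!r$values)) {
    hp <- which(labels[starts[j]:ends[j]] == "high") + starts[j] - 1L
    if (length(hp) >= min_size) {
      res[[length(res) + 1L]] <- c(first = hp[1], last = hp[length(hp)],
                                   n_high = length(hp))
    }
  }
  if (length(res)) as.data.frame(do.call(rbind, res)) else
    data.frame(first = integer(0), last = integer(0), n_high = integer(0))
}
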