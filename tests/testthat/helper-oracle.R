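# Independent quadratic dynamic-programming oracle for local alignment
# scores (affine gaps: a gap of length k costs open + k * ext). Used to
# check the compiled aligner; kept deliberately naive.

oracle_sw_score <- function(q, t, open = 10, ext = 1,
                            sm = siftsmapper:::blosum62_matrix()) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sm[qc[i - 1], tc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# aligned (query, target) residue index pairs of an alignment
alignment_pairs <- function(a) {
  cols <- siftsmapper:::alignment_columns(a)
  cols$col <- seq_len(nrow(cols))
  cols[!is.na(cols$qi) & !is.na(cols$ti), c("col", "qi", "ti")]
}

# mutate a fraction of positions by substitution (no indels)
mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  std <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  k <- round(rate * length(chars))
  if (k > 0) {
    pos <- sample(seq_along(chars), k)
    for (p in pos) chars[p] <- sample(setdiff(std, chars[p]), 1)
  }
  paste(chars, collapse = "")
}
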