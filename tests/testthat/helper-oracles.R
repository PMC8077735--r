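# Independent oracles and fixture builders used across test files.

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Brute-force DR counter: a literal double loop over positions and
# distances, independent of the vectorized implementation.
dr_encode_naive <- function(seq, d_max) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  block0 <- setNames(numeric(20), AA20_TEST)
  for (ch in chars) if (ch %in% AA20_TEST) block0[ch] <- block0[ch] + 1
  out <- block0
  for (d in seq_len(d_max)) {
    block <- setNames(numeric(400),
                      paste0(rep(AA20_TEST, each = 20),
                             rep(AA20_TEST, times = 20), "@", d))
    if (len > d) {
      for (t in seq_len(len - d)) {
        i <- chars[t]; j <- chars[t + d]
        if (i %in% AA20_TEST && j %in% AA20_TEST) {
          key <- paste0(i, j, "@", d)
          block[key] <- block[key] + 1
        }
      }
    }
    out <- c(out, block)
  }
  out
}

# Standard four-product MCC from a confusion matrix. Doubles
# throughout: the four-way product overflows 32-bit integers.
mcc_standard <- function(n_pos, n_neg, fn, fp) {
  tp <- as.numeric(n_pos - fn); tn <- as.numeric(n_neg - fp)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(NaN)
  (tp * tn - fp * fn) / den
}

# Direct pairwise AUC by full enumeration.
auc_outer <- function(pos, neg, tie_correction = FALSE) {
  cmp <- outer(pos, neg, `>`)
  a <- mean(cmp)
  if (tie_correction) a <- a + 0.5 * mean(outer(pos, neg, `==`))
  a
}

# Full symmetric KSU dissimilarity matrix by naive loops.
ksu_dissim_naive <- function(m) {
  n <- nrow(m)
  cmax <- apply(m, 2, max)
  pi_mat <- m
  for (t in seq_len(ncol(m))) {
    pi_mat[, t] <- if (cmax[t] == 0) 0 else m[, t] / cmax[t]
  }
  D <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    D[p, q] <- sum((pi_mat[p, ] - pi_mat[q, ])^2) / n
  }
  D
}

random_aa_sequence <- function(len, with_x = FALSE) {
  alphabet <- if (with_x) c(AA20_TEST, "X") else AA20_TEST
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_temp_sites <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
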