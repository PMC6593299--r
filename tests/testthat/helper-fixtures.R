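# Small in-code fixtures and independent brute-force oracles shared by the
# test files. Oracles are written from the definitions, independent of the
# package code paths they check.

tiny_counts <- function(values, features = NULL, samples = NULL) {
  nr <- nrow(values)
  nc <- ncol(values)
  if (is.null(features)) features <- sprintf("miR-%02d", seq_len(nr))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nc))
  m <- matrix(as.integer(values), nrow = nr, dimnames = list(features, samples))
  m
}

write_counts_tsv <- function(m, path = tempfile(fileext = ".tsv"),
                             feature_column = "feature") {
  mirisk::write_count_matrix(m, path, feature_column = feature_column)
  path
}

write_metadata_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_counts <- function(nr, nc, lambda = 50) {
  tiny_counts(matrix(rpois(nr * nc, lambda), nrow = nr))
}

# Step-up BH from the definition: padj_(i) = min_{k>=i} min(1, m p_(k) / k).
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
hyper_enum <- function(k, K, n, N) {
  universe <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(universe[idx]))
  mean(hits >= k)
}

# AUC by explicit pair counting, ties counted half.
auc_pairs <- function(case_scores, control_scores) {
  conc <- 0
  for (x in case_scores) for (y in control_scores) {
    conc <- conc + (x > y) + 0.5 * (x == y)
  }
  conc / (length(case_scores) * length(control_scores))
}

# Best Youden index by scanning every midpoint threshold directly.
youden_bruteforce <- function(case_scores, control_scores) {
  d <- sort(unique(c(case_scores, control_scores)))
  cuts <- c(-Inf, d[-length(d)] + diff(d) / 2, Inf)
  J <- vapply(cuts, function(t) {
    mean(case_scores >= t) + mean(control_scores < t) - 1
  }, numeric(1))
  max(J)
}
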