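# Independent oracles: literal loop transcriptions of the defining formulas,
# kept deliberately naive and separate from the package implementation.

# Off-diagonal Gram by explicit loops.
naive_offdiag_gram <- function(p) {
  ng <- nrow(p)
  g <- matrix(0, ng, ng)
  for (i in seq_len(ng)) for (k in seq_len(ng)) {
    if (i == k) next
    acc <- 0
    for (j in seq_len(ncol(p))) acc <- acc + p[i, j] * p[k, j]
    g[i, k] <- acc
  }
  g
}

# TSC as the trace of the product of the two off-diagonal Grams over the
# product of their Frobenius norms, all by loops.
naive_tsc <- function(p1, p2) {
  g1 <- naive_offdiag_gram(p1)
  g2 <- naive_offdiag_gram(p2)
  ng <- nrow(g1)
  num <- 0
  for (i in seq_len(ng)) for (k in seq_len(ng)) num <- num + g1[i, k] * g2[k, i]
  d1 <- 0
  d2 <- 0
  for (i in seq_len(ng)) for (k in seq_len(ng)) {
    d1 <- d1 + g1[i, k]^2
    d2 <- d2 + g2[i, k]^2
  }
  if (d1 == 0 || d2 == 0) return(NA_real_)
  num / sqrt(d1 * d2)
}

# C-index by brute-force enumeration of all (positive, negative) pairs.
naive_cindex <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Random expression fixture with unique identifiers.
rand_expr <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

# Minimal balanced response table over the samples of an expression matrix.
rand_labels <- function(expr, response = NULL, arm = "combination",
                        er = "ER+") {
  ids <- colnames(expr)
  if (is.null(response))
    response <- rep_len(c(1L, 0L), length(ids))
  response_table(ids, response, rep_len(arm, length(ids)),
                 rep_len(er, length(ids)))
}
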