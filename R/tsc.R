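#' Off-diagonal Gram matrix of a population
#'
#' For a genes x samples matrix `P`, computes `P %*% t(P)` and zeroes its
#' diagonal. The diagonal deletion removes each gene's own squared magnitude
#' so that the similarity built on these matrices reflects between-gene
#' co-expression structure and does not depend on the number of samples in
#' either population.
#'
#' @param pop numeric genes x samples matrix with at least 2 genes (with a
#'   single gene the off-diagonal part would be empty).
#' @return a symmetric genes x genes matrix with exact zeros on the diagonal.
#' @export
offdiag_gram <- function(pop) {
  if (!is.matrix(pop) || !is.numeric(pop))
    stop("population must be a numeric matrix", call. = FALSE)
  if (nrow(pop) < 2L)
    stop("off-diagonal Gram undefined for fewer than 2 genes", call. = FALSE)
  g <- tcrossprod(pop)
  diag(g) <- 0
  g
}

#' Transcriptional similarity coefficient between two populations
#'
#' The TSC between two sample populations restricted to a shared, identically
#' ordered gene list is the cosine similarity between their off-diagonal Gram
#' matrices:
#' \deqn{TSC(P_1, P_2) = \frac{\sum_{ij} (P_{10})_{ij}(P_{20})_{ij}}
#'   {\sqrt{\sum_{ij} (P_{10})_{ij}^2}\sqrt{\sum_{ij} (P_{20})_{ij}^2}}}
#' where \eqn{P_{m0} = P_m P_m' - Diagonal(P_m P_m')}. By Cauchy-Schwarz the
#' value lies in \eqn{[-1, 1]}; it is exactly 1 for a population compared
#' with itself, invariant to duplicating the samples of either population and
#' to nonzero rescaling of either matrix.
#'
#' When either off-diagonal Gram is the zero matrix the coefficient is
#' undefined and `NA_real_` is returned (never 0, which is a meaningful
#' similarity value); callers decide how to treat the undefined case.
#'
#' @param pop1,pop2 numeric genes x samples matrices over the same genes in
#'   the same order (checked via row names when both are present).
#' @return the TSC as a scalar in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
tsc <- function(pop1, pop2) {
  if (nrow(pop1) != nrow(pop2))
    stop("populations must share the same gene universe", call. = FALSE)
  if (!is.null(rownames(pop1)) && !is.null(rownames(pop2)) &&
      !identical(rownames(pop1), rownames(pop2)))
    stop("gene order differs between the two populations", call. = FALSE)
  g1 <- offdiag_gram(pop1)
  g2 <- offdiag_gram(pop2)
  d1 <- sum(g1 * g1)
  d2 <- sum(g2 * g2)
  if (d1 <= 0 || d2 <= 0) return(NA_real_)
  v <- sum(g1 * g2) / sqrt(d1 * d2)
  min(1, max(-1, v))
}

#' TSC between one sample and a reference population
#'
#' Builds the two pathway-restricted population matrices on the intersection
#' of `gene_set` with the measured genes (canonicalized to lexicographic
#' order, so results do not depend on GMT or file ordering) and returns their
#' TSC. The scored sample must not be part of the reference population.
#'
#' @param expr expression matrix (genes x samples).
#' @param sample_id the single sample to score.
#' @param population_ids the reference population sample identifiers.
#' @param gene_set character vector of gene identifiers defining the pathway.
#' @return TSC value, or `NA_real_` when fewer than 2 pathway genes are
#'   measured or the coefficient is undefined.
#' @export
tsc_sample_vs_population <- function(expr, sample_id, population_ids, gene_set) {
  if (length(population_ids) == 0L)
    stop("reference population is empty", call. = FALSE)
  if (sample_id %in% population_ids)
    stop("scored sample must be excluded from the reference population",
         call. = FALSE)
  missing_ids <- setdiff(c(sample_id, population_ids), colnames(expr))
  if (length(missing_ids))
    stop("samples absent from expression matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  genes <- sort(intersect(gene_set, rownames(expr)))
  if (length(genes) < 2L) return(NA_real_)
  tsc(expr[genes, sample_id, drop = FALSE],
      expr[genes, population_ids, drop = FALSE])
}

## Pairwise TSC kernel.
##
## The Gram matrix of a multi-sample population is the sum of its samples'
## rank-1 outer products, and diagonal deletion is linear, so every
## population-level off-diagonal Gram is a sum of single-sample off-diagonal
## Grams A_s0 = x_s x_s' - diag(x_s^2). All TSC values over subsets of a
## cohort therefore reduce to the pairwise inner products
##   K[s, t] = <A_s0, A_t0> = (x_s . x_t)^2 - sum_g x_sg^2 x_tg^2,
## i.e. K = (X'X)^2 - (X^2)'(X^2) elementwise, computed once per pathway:
##   TSC(s, D) = sum_{d in D} K[s, d] / sqrt(K[s, s] * sum_{d, d' in D} K).
## This is exact (no approximation) and is what makes subsampled
## cross-validation affordable.
.pathway_kernel <- function(expr, gene_set) {
  genes <- sort(intersect(gene_set, rownames(expr)))
  if (length(genes) < 2L) return(NULL)
  x <- expr[genes, , drop = FALSE]
  cp <- crossprod(x)
  cp * cp - crossprod(x * x)
}

## TSC of sample index i against population indices pop, from a kernel.
.tsc_from_kernel <- function(k, i, pop) {
  d1 <- k[i, i]
  d2 <- sum(k[pop, pop])
  if (d1 <= 0 || d2 <= 0) return(NA_real_)
  v <- sum(k[i, pop]) / sqrt(d1 * d2)
  min(1, max(-1, v))
}
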