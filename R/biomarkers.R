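#' Concordance index of a score against binary labels
#'
#' The probability that, over a randomly chosen (responder, non-responder)
#' pair, the responder carries the higher score; tied scores contribute 0.5
#' per pair (the standard AUC convention). For binary labels this equals the
#' area under the ROC curve. Computed via midranks in O(n log n), which is
#' exactly the pair-enumeration mean.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector of the same length; pairs with `NA` in
#'   `scores` or `labels` are dropped.
#' @return the C-index in `[0, 1]`, or `NA_real_` when either class is empty.
#' @export
concordance_index <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)                       # midranks handle ties as 0.5
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Permutation significance of a concordance index
#'
#' Returns the fraction of label permutations whose C-index strictly exceeds
#' the observed one. By default the test is one-sided toward high C-index;
#' `alternative = "symmetric"` compares `max(c, 1 - c)` instead, so that
#' anti-concordant features are also flagged. When the number of distinct
#' labelings is small (<= `exhaustive_limit`) all of them are enumerated
#' exactly instead of Monte-Carlo sampling (`mode = "auto"`).
#'
#' @inheritParams concordance_index
#' @param n_perm number of Monte-Carlo permutations (default 1000).
#' @param seed integer seed for the Monte-Carlo shuffles.
#' @param mode `"auto"`, `"montecarlo"` or `"exhaustive"`.
#' @param alternative `"greater"` (default) or `"symmetric"`.
#' @param exhaustive_limit largest number of distinct labelings enumerated
#'   exhaustively under `mode = "auto"` (default 10000).
#' @return fraction in `[0, 1]`.
#' @export
permutation_significance <- function(scores, labels, n_perm = 1000L, seed = 1L,
                                     mode = c("auto", "montecarlo", "exhaustive"),
                                     alternative = c("greater", "symmetric"),
                                     exhaustive_limit = 10000L) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  labels <- as.integer(labels)
  n <- length(labels)
  k <- sum(labels == 1L)
  if (k == 0L || k == n) stop("both classes must be non-empty", call. = FALSE)
  stat <- function(y) {
    ci <- concordance_index(scores, y)
    if (alternative == "symmetric") max(ci, 1 - ci) else ci
  }
  obs <- stat(labels)
  n_distinct <- choose(n, k)
  if (mode == "exhaustive" ||
      (mode == "auto" && n_distinct <= exhaustive_limit)) {
    pos_sets <- combn(n, k)
    perm <- apply(pos_sets, 2L, function(pos) {
      y <- integer(n)
      y[pos] <- 1L
      stat(y)
    })
  } else {
    set.seed(seed %% .Machine$integer.max)
    perm <- replicate(n_perm, stat(sample(labels)))
  }
  mean(perm > obs)
}

.group_subset <- function(labels, group) {
  if (is.null(group)) return(labels$sample_id)
  keep <- rep(TRUE, nrow(labels))
  if (!is.null(group[["arm"]])) keep <- keep & labels$arm == group[["arm"]]
  if (!is.null(group[["er_status"]]))
    keep <- keep & labels$er_status == group[["er_status"]]
  labels$sample_id[keep]
}

.group_string <- function(group) {
  if (is.null(group)) return("all")
  paste(c(group[["arm"]], group[["er_status"]]), collapse = "/")
}

#' Univariate gene biomarkers by concordance index
#'
#' Scores every gene's expression as a univariate predictor of response
#' within one patient group (treatment arm x ER stratum), by the C-index
#' against the binary response plus its permutation significance. Raw
#' permutation fractions and a separate Benjamini-Hochberg-adjusted column
#' are both reported, so no multiplicity claim is hidden in the raw fraction.
#' One common set of label permutations is shared across genes, which keeps
#' the permutation null exchangeable between genes and the run fast.
#'
#' @param expr expression matrix.
#' @param labels a [response_table()].
#' @param group optional list/vector with elements `arm` and/or `er_status`
#'   selecting the patient group; `NULL` uses all samples.
#' @param n_perm shared label permutations (default 1000).
#' @param seed integer seed.
#' @return a `data.frame` with columns `feature`, `cindex`, `perm_frac`,
#'   `bh_adjusted`, `n_samples`, `group`, sorted by decreasing C-index; empty
#'   (with a warning) when the group lacks a class.
#' @export
univariate_gene_biomarkers <- function(expr, labels, group = NULL,
                                       n_perm = 1000L, seed = 1L) {
  ids <- intersect(colnames(expr), .group_subset(labels, group))
  y <- labels$response[match(ids, labels$sample_id)]
  empty <- data.frame(feature = character(0L), cindex = numeric(0L),
                      perm_frac = numeric(0L), bh_adjusted = numeric(0L),
                      n_samples = integer(0L), group = character(0L),
                      stringsAsFactors = FALSE)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    warning("group ", .group_string(group),
            " lacks 2 samples in each class; skipped", call. = FALSE)
    return(empty)
  }
  x <- expr[, ids, drop = FALSE]
  n <- length(y)
  k <- sum(y == 1L)
  rk <- t(apply(x, 1L, rank))                      # genes x samples midranks
  if (nrow(x) == 1L) rk <- matrix(rank(x[1L, ]), nrow = 1L)
  ci_from_ind <- function(ind) {                   # ind: samples x m of 0/1
    (rk %*% ind - k * (k + 1) / 2) / (k * (n - k))
  }
  obs <- drop(ci_from_ind(matrix(as.numeric(y == 1L), ncol = 1L)))
  set.seed(seed %% .Machine$integer.max)
  perm_ind <- replicate(n_perm, as.numeric(sample(y) == 1L))
  perm_ci <- ci_from_ind(perm_ind)                 # genes x n_perm
  perm_frac <- rowMeans(perm_ci > obs)
  out <- data.frame(feature = rownames(x), cindex = obs,
                    perm_frac = perm_frac,
                    bh_adjusted = p.adjust(perm_frac, method = "BH"),
                    n_samples = n, group = .group_string(group),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$cindex), , drop = FALSE]
}

#' Pathway biomarkers from a delta-TSC profile
#'
#' Ranks pathways by the C-index of their delta-TSC column against the
#' binary response within a patient group, with permutation significance and
#' a Benjamini-Hochberg-adjusted column. Undefined delta entries are dropped
#' pairwise with their labels; columns that are entirely undefined are
#' excluded with a warning.
#'
#' @param profile a [delta_tsc_profile()].
#' @param labels a [response_table()].
#' @param group optional group selector, as in [univariate_gene_biomarkers()].
#' @param n_perm permutations per pathway (default 1000).
#' @param seed integer seed.
#' @return a `data.frame` with columns `feature`, `cindex`, `perm_frac`,
#'   `bh_adjusted`, `n_samples`, `group`, sorted by decreasing C-index.
#' @export
pathway_biomarkers <- function(profile, labels, group = NULL,
                               n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(profile, "delta_tsc_profile"))
  ids <- intersect(profile$sample_ids, .group_subset(labels, group))
  y <- labels$response[match(ids, labels$sample_id)]
  delta <- profile$delta[ids, , drop = FALSE]
  all_na <- apply(delta, 2L, function(col) all(is.na(col)))
  if (any(all_na))
    warning(sum(all_na), " pathway(s) with entirely undefined delta excluded",
            call. = FALSE)
  delta <- delta[, !all_na, drop = FALSE]
  rows <- lapply(seq_len(ncol(delta)), function(p) {
    col <- delta[, p]
    keep <- !is.na(col)
    ci <- concordance_index(col[keep], y[keep])
    pf <- if (is.na(ci)) NA_real_ else
      permutation_significance(col[keep], y[keep], n_perm = n_perm,
                               seed = seed + p)
    data.frame(feature = colnames(delta)[p], cindex = ci, perm_frac = pf,
               n_samples = sum(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_adjusted <- p.adjust(out$perm_frac, method = "BH")
  out$group <- .group_string(group)
  out <- out[, c("feature", "cindex", "perm_frac", "bh_adjusted",
                 "n_samples", "group")]
  out[order(-out$cindex), , drop = FALSE]
}

#' Spearman correlation of two pathway biomarker profiles
#'
#' Compares the pathway C-index profiles of two patient groups over their
#' shared pathways by Spearman rank correlation; low absolute correlation
#' indicates group-specific response mechanisms.
#'
#' @param cindex_vec_a,cindex_vec_b numeric vectors named by pathway.
#' @return Spearman rho, or `NA_real_` (with a warning) when fewer than 3
#'   pathways are shared.
#' @export
compare_biomarker_profiles <- function(cindex_vec_a, cindex_vec_b) {
  shared <- intersect(names(cindex_vec_a), names(cindex_vec_b))
  if (length(shared) < 3L) {
    warning("fewer than 3 shared pathways; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(cindex_vec_a[shared], cindex_vec_b[shared], method = "spearman")
}

#' Pairwise similarity and clustering of biomarker profiles across groups
#'
#' Builds the pairwise Spearman correlation matrix of per-group pathway
#' C-index profiles and, when at least 3 groups with complete pairwise
#' overlap are given, clusters the groups by Ward linkage on Euclidean
#' distances between the correlation-matrix rows.
#'
#' @param profiles named list of numeric vectors keyed by pathway, one per
#'   patient group.
#' @return a list with `correlation` (groups x groups Spearman matrix) and
#'   `hclust` (an `hclust` object, or `NULL` when fewer than 3 groups).
#' @export
biomarker_profile_matrix <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  g <- length(profiles)
  m <- diag(1, g)
  dimnames(m) <- list(names(profiles), names(profiles))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i < j) {
      rho <- suppressWarnings(
        compare_biomarker_profiles(profiles[[i]], profiles[[j]]))
      m[i, j] <- m[j, i] <- rho
    }
  }
  hc <- if (g >= 3L && !anyNA(m)) hclust(dist(m), method = "ward.D2") else NULL
  list(correlation = m, hclust = hc)
}
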