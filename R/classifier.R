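## Align a response table with the samples of an expression matrix and split
## into responder / non-responder identifier vectors.
.split_classes <- function(expr, labels) {
  stopifnot(inherits(labels, "response_table"))
  ids <- colnames(expr)
  miss <- setdiff(ids, labels$sample_id)
  if (length(miss))
    stop("samples missing from response table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  resp <- labels$response[match(ids, labels$sample_id)]
  list(ids = ids,
       responders = ids[resp == 1L],
       nonresponders = ids[resp == 0L],
       response = resp)
}

## Kernels for every usable pathway; sets with <2 measured genes are dropped
## with a summary warning.
.cohort_kernels <- function(expr, pathways) {
  stopifnot(inherits(pathways, "gene_sets"))
  kernels <- lapply(pathways$sets, function(g) .pathway_kernel(expr, g))
  usable <- !vapply(kernels, is.null, logical(1L))
  if (!all(usable))
    warning(sum(!usable), " pathway(s) with fewer than 2 measured genes dropped",
            call. = FALSE)
  if (!any(usable))
    stop("no pathway has at least 2 measured genes", call. = FALSE)
  kernels[usable]
}

#' Per-sample, per-pathway delta-TSC profile
#'
#' For every sample and pathway, computes the TSC of the sample against the
#' remaining responders minus the TSC against the remaining non-responders,
#' always excluding the scored sample from both reference populations
#' (full leave-one-out populations, no subsampling). A positive delta means
#' the sample's pathway co-expression pattern resembles responders more than
#' non-responders; the delta is the pathway biomarker score.
#'
#' @param expr expression matrix (genes x samples).
#' @param labels a [response_table()] covering the samples of `expr`.
#' @param pathways a [gene_sets()] collection, normally pre-filtered to a
#'   10-30 gene measured size with [filter_sets_by_size()].
#' @return an object of class `delta_tsc_profile`: a list with `delta`
#'   (samples x pathways matrix, `NA` where either TSC is undefined),
#'   `sample_ids` and `pathway_names`.
#' @export
delta_tsc_profile <- function(expr, labels, pathways) {
  cls <- .split_classes(expr, labels)
  if (length(cls$responders) < 2L)
    stop("responder class would be emptied by holdout (need >= 2 responders)",
         call. = FALSE)
  if (length(cls$nonresponders) < 2L)
    stop("non-responder class would be emptied by holdout (need >= 2 non-responders)",
         call. = FALSE)
  kernels <- .cohort_kernels(expr, pathways)
  n <- length(cls$ids)
  r_idx <- which(cls$response == 1L)
  n_idx <- which(cls$response == 0L)
  delta <- matrix(NA_real_, n, length(kernels),
                  dimnames = list(cls$ids, names(kernels)))
  for (p in seq_along(kernels)) {
    k <- kernels[[p]]
    delta[, p] <- .loo_tsc_side(k, r_idx, n) - .loo_tsc_side(k, n_idx, n)
  }
  structure(list(delta = delta, sample_ids = cls$ids,
                 pathway_names = colnames(delta)),
            class = "delta_tsc_profile")
}

## Vectorized leave-one-out TSC of every sample against class `cls_idx`
## (minus the sample itself when it belongs to the class), from one kernel.
.loo_tsc_side <- function(k, cls_idx, n) {
  kss <- diag(k)
  rs <- rowSums(k[, cls_idx, drop = FALSE])   # includes k[s,s] when s in class
  s_cc <- sum(k[cls_idx, cls_idx])
  in_cls <- seq_len(n) %in% cls_idx
  num <- rs - ifelse(in_cls, kss, 0)
  den2 <- ifelse(in_cls, s_cc - 2 * rs + kss, s_cc)
  out <- num / sqrt(kss * den2)
  out[kss <= 0 | den2 <= 0] <- NA_real_
  pmin(1, pmax(-1, out))
}

#' Responder classification rule
#'
#' A sample is called a responder when its similarity to the responders
#' exceeds its similarity to the non-responders, and a non-responder in the
#' opposite case. Ties are called non-responder (conservative toward the
#' clinically default no-pCR class, and deterministic). When exactly one side
#' is undefined the defined side wins; with both sides undefined the call is
#' undefined (`NA`).
#'
#' @param tsc_resp TSC against the responder population (may be `NA`).
#' @param tsc_nonresp TSC against the non-responder population (may be `NA`).
#' @return `1L` (responder), `0L` (non-responder) or `NA_integer_`.
#' @export
classify_rule <- function(tsc_resp, tsc_nonresp) {
  if (is.na(tsc_resp) && is.na(tsc_nonresp)) return(NA_integer_)
  if (is.na(tsc_nonresp)) return(1L)
  if (is.na(tsc_resp)) return(0L)
  if (tsc_resp > tsc_nonresp) 1L else 0L
}

#' Subsampled leave-one-out majority-vote classifier
#'
#' Each sample is set aside in turn. For each of `n_draws` repetitions,
#' `draw_size` responders and `draw_size` non-responders are drawn uniformly
#' without replacement (both excluding the held-out sample); per pathway the
#' TSC of the held-out sample against each drawn reference set is computed,
#' the median over pathways is taken separately for the responder-side and
#' non-responder-side TSC vectors (undefined entries dropped), and the two
#' medians are compared with [classify_rule()] to cast one vote. The majority
#' of votes is the predicted class; a tied vote predicts non-responder. A
#' draw in which more than half of the pathways are undefined on either side
#' abstains and is not counted.
#'
#' Reproducibility and symmetry: one global `seed` spawns a per-sample
#' substream indexed by the sample's column position, so adding a sample at
#' the end does not perturb the other samples' draws. Within a draw the two
#' classes are sampled in a canonical order (the class containing the
#' lexicographically smallest sample identifier first), so relabeling the
#' classes reuses the same draws and flips the votes. Classes smaller than
#' `draw_size` (after holdout) fall back to sampling with replacement, with a
#' loud warning.
#'
#' @inheritParams delta_tsc_profile
#' @param n_draws number of subsampled votes per sample (default 100).
#' @param draw_size reference samples drawn per class per vote (default 5).
#' @param seed integer seed governing all draws.
#' @return a `data.frame` of class `vote_prediction` with one row per sample:
#'   `sample_id`, `votes_responder`, `votes_total`, `predicted`,
#'   `vote_fraction`.
#' @export
loocv_predict <- function(expr, labels, pathways, n_draws = 100L,
                          draw_size = 5L, seed = 1L) {
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  cls <- .split_classes(expr, labels)
  if (length(cls$responders) < 2L || length(cls$nonresponders) < 2L)
    stop("both response classes need at least 2 members", call. = FALSE)
  kernels <- .cohort_kernels(expr, pathways)
  n <- length(cls$ids)
  n_path <- length(kernels)
  ## kernels flattened to an n^2 x P matrix: all draw-level sums become
  ## column sums over gathered rows.
  kk <- vapply(kernels, as.vector, numeric(n * n))
  kss <- kk[(seq_len(n) - 1L) * n + seq_len(n), , drop = FALSE]

  r_idx <- which(cls$response == 1L)
  n_idx <- which(cls$response == 0L)
  ## canonical class order for draws: class holding the smallest sample id
  first_is_resp <- min(cls$ids[r_idx]) < min(cls$ids[n_idx])
  warned <- FALSE

  side_tsc <- function(s, pop) {
    num <- colSums(kk[(pop - 1L) * n + s, , drop = FALSE])
    pairs <- as.vector(outer((pop - 1L) * n, pop, `+`))
    den2 <- colSums(kk[pairs, , drop = FALSE])
    out <- num / sqrt(kss[s, ] * den2)
    out[kss[s, ] <= 0 | den2 <= 0] <- NA_real_
    pmin(1, pmax(-1, out))
  }

  res <- data.frame(sample_id = cls$ids, votes_responder = 0L,
                    votes_total = 0L, predicted = 0L,
                    vote_fraction = NA_real_, stringsAsFactors = FALSE)
  for (s in seq_len(n)) {
    pool_r <- setdiff(r_idx, s)
    pool_n <- setdiff(n_idx, s)
    replace_r <- length(pool_r) < draw_size
    replace_n <- length(pool_n) < draw_size
    if ((replace_r || replace_n) && !warned) {
      warning("a class is smaller than draw_size after holdout; ",
              "falling back to sampling WITH replacement", call. = FALSE)
      warned <- TRUE
    }
    set.seed((seed + s) %% .Machine$integer.max)
    votes <- 0L
    total <- 0L
    for (d in seq_len(n_draws)) {
      ## sample.int guards against R's length-1 sample() surprise
      if (first_is_resp) {
        dr <- pool_r[sample.int(length(pool_r), draw_size, replace = replace_r)]
        dn <- pool_n[sample.int(length(pool_n), draw_size, replace = replace_n)]
      } else {
        dn <- pool_n[sample.int(length(pool_n), draw_size, replace = replace_n)]
        dr <- pool_r[sample.int(length(pool_r), draw_size, replace = replace_r)]
      }
      tr <- side_tsc(s, dr)
      tn <- side_tsc(s, dn)
      if (sum(is.na(tr)) > n_path / 2 || sum(is.na(tn)) > n_path / 2) next
      vote <- classify_rule(median(tr, na.rm = TRUE), median(tn, na.rm = TRUE))
      if (is.na(vote)) next
      total <- total + 1L
      votes <- votes + vote
    }
    res$votes_responder[s] <- votes
    res$votes_total[s] <- total
    res$predicted[s] <- as.integer(total > 0L && votes > total / 2)
    res$vote_fraction[s] <- if (total > 0L) votes / total else NA_real_
  }
  class(res) <- c("vote_prediction", "data.frame")
  res
}
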