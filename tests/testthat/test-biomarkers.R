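test_that("concordance index matches hand-enumerated pair counts", {
  expect_equal(concordance_index(c(0.1, 0.2, 0.9), c(0, 0, 1)), 1.0)
  expect_equal(concordance_index(c(0.9, 0.2, 0.1), c(0, 0, 1)), 0.0)
  # pairs: (2>1)=1, (3>1)=1, (2=2)=0.5, (3>2)=1 -> 3.5/4
  expect_equal(concordance_index(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  expect_identical(concordance_index(c(1, 2, 3), c(1, 1, 1)), NA_real_)
})

test_that("concordance index equals brute-force enumeration on random data", {
  set.seed(40)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    scores <- if (i %% 3 == 0) sample(1:8, n, replace = TRUE) else rnorm(n)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(concordance_index(scores, labels),
                 naive_cindex(scores, labels), tolerance = 1e-12)
  }
})

test_that("concordance index identities hold", {
  set.seed(41)
  scores <- rnorm(50)            # tie-free almost surely
  labels <- rbinom(50, 1, 0.4)
  ci <- concordance_index(scores, labels)
  expect_equal(ci + concordance_index(-scores, labels), 1, tolerance = 1e-12)
  # invariance under strictly increasing transforms
  expect_equal(concordance_index(exp(scores), labels), ci, tolerance = 1e-12)
  expect_equal(concordance_index(rank(scores), labels), ci, tolerance = 1e-12)
})

test_that("exhaustive permutation significance enumerates all labelings", {
  # n = 4, labels [0,0,1,1]: 6 distinct labelings, observed C = 1 is maximal
  expect_equal(permutation_significance(c(1, 2, 3, 4), c(0, 0, 1, 1),
                                        mode = "exhaustive"), 0)
  # degenerate scores: every C-index is 0.5, strict inequality never holds
  expect_equal(permutation_significance(rep(1, 6), c(0, 0, 0, 1, 1, 1),
                                        n_perm = 50, seed = 1), 0)
  expect_error(permutation_significance(rnorm(6), c(0, 0, 0, 1, 1, 1),
                                        n_perm = 0), "n_perm")
})

test_that("Monte-Carlo permutation significance converges to exhaustive", {
  set.seed(42)
  for (i in 1:5) {
    n <- 8
    scores <- rnorm(n)
    labels <- sample(c(rep(1, 4), rep(0, 4)))
    exact <- permutation_significance(scores, labels, mode = "exhaustive")
    mc <- permutation_significance(scores, labels, n_perm = 10000,
                                   seed = 100 + i, mode = "montecarlo")
    expect_lt(abs(mc - exact), 0.02)
  }
})

test_that("mean-shifted genes top the univariate ranking", {
  # a 2-SD mean shift at 40/class has expected C-index pnorm(2 / sqrt(2)),
  # about 0.92; require the shifted gene to rank first with a C-index
  # comfortably above the null ceiling
  top_hits <- 0L
  strong <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    set.seed(600 + r)
    expr <- rand_expr(50, 80)
    labels <- rand_labels(expr, response = rep(c(1L, 0L), each = 40))
    expr["G001", labels$response == 1L] <-
      expr["G001", labels$response == 1L] + 2  # 2-SD shift
    res <- univariate_gene_biomarkers(expr, labels, n_perm = 50,
                                      seed = 600 + r)
    if (res$feature[1L] == "G001") top_hits <- top_hits + 1L
    if (res$cindex[res$feature == "G001"] > 0.85) strong <- strong + 1L
  }
  expect_gte(top_hits, 18L)
  expect_gte(strong, 18L)
})

test_that("univariate biomarker output is well-formed", {
  expr <- rand_expr(1, 12, seed = 43)
  labels <- rand_labels(expr)
  res <- univariate_gene_biomarkers(expr, labels, n_perm = 20, seed = 2)
  expect_identical(nrow(res), 1L)
  expect_named(res, c("feature", "cindex", "perm_frac", "bh_adjusted",
                      "n_samples", "group"))

  # a group with an empty class is skipped with a warning
  one_class <- rand_labels(expr, response = rep(1L, 12))
  expect_warning(empty <- univariate_gene_biomarkers(expr, one_class),
                 "skipped")
  expect_identical(nrow(empty), 0L)
})

test_that("pathway biomarker C-index edge values are exact", {
  n <- 12
  labels <- response_table(sprintf("S%03d", 1:n), rep_len(c(1L, 0L), n),
                           rep("combination", n), rep("ER+", n))
  delta <- cbind(constant = rep(0.2, n),
                 oracle = as.numeric(rep_len(c(1L, 0L), n)),
                 noise = rnorm(n))
  rownames(delta) <- labels$sample_id
  prof <- structure(list(delta = delta, sample_ids = labels$sample_id,
                         pathway_names = colnames(delta)),
                    class = "delta_tsc_profile")
  res <- pathway_biomarkers(prof, labels, n_perm = 50, seed = 3)
  expect_equal(res$cindex[res$feature == "constant"], 0.5)
  expect_equal(res$cindex[res$feature == "oracle"], 1.0)
  expect_identical(res$feature[1L], "oracle")
})

test_that("entirely undefined pathway columns are excluded with a warning", {
  n <- 10
  labels <- response_table(sprintf("S%03d", 1:n), rep_len(c(1L, 0L), n),
                           rep("combination", n), rep("ER+", n))
  delta <- cbind(dead = rep(NA_real_, n), live = rnorm(n))
  rownames(delta) <- labels$sample_id
  prof <- structure(list(delta = delta, sample_ids = labels$sample_id,
                         pathway_names = colnames(delta)),
                    class = "delta_tsc_profile")
  expect_warning(res <- pathway_biomarkers(prof, labels, n_perm = 20, seed = 1),
                 "undefined")
  expect_identical(res$feature, "live")
})

test_that("profile comparison behaves at the fixed points", {
  v <- setNames(runif(20), paste0("P", 1:20))
  expect_equal(compare_biomarker_profiles(v, v), 1)
  rev_ranked <- setNames(-v, names(v))
  expect_equal(compare_biomarker_profiles(v, rev_ranked), -1)
  expect_warning(
    out <- compare_biomarker_profiles(v[1:2], v[1:2]), "fewer than 3")
  expect_identical(out, NA_real_)
})

test_that("independent null profiles are weakly correlated", {
  set.seed(44)
  ok <- 0L
  for (i in 1:100) {
    a <- setNames(runif(100), paste0("P", 1:100))
    b <- setNames(runif(100), paste0("P", 1:100))
    if (abs(compare_biomarker_profiles(a, b)) < 0.3) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("profile matrix clusters groups and keeps unit diagonal", {
  set.seed(45)
  base <- runif(30)
  profs <- list(g1 = setNames(base + rnorm(30, 0, 0.01), paste0("P", 1:30)),
                g2 = setNames(base + rnorm(30, 0, 0.01), paste0("P", 1:30)),
                g3 = setNames(runif(30), paste0("P", 1:30)))
  out <- biomarker_profile_matrix(profs)
  expect_equal(diag(out$correlation), c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(out$correlation, t(out$correlation))
  expect_s3_class(out$hclust, "hclust")
  # the two near-identical profiles merge first
  expect_gt(out$correlation["g1", "g2"], out$correlation["g1", "g3"])
})
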