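test_that("classification rule follows the similarity comparison", {
  expect_identical(classify_rule(0.8, 0.3), 1L)
  expect_identical(classify_rule(0.3, 0.8), 0L)
  expect_identical(classify_rule(0.5, 0.5), 0L)  # tie -> non-responder
  expect_identical(classify_rule(0.2, NA), 1L)   # defined side wins
  expect_identical(classify_rule(NA, 0.2), 0L)
  expect_identical(classify_rule(NA_real_, NA_real_), NA_integer_)
})

test_that("delta profile equals per-sample leave-one-out TSC differences", {
  expr <- rand_expr(25, 10, seed = 20)
  labels <- rand_labels(expr)
  set.seed(21)
  gs <- gene_sets(list(P1 = sample(rownames(expr), 8),
                       P2 = sample(rownames(expr), 5)))
  prof <- delta_tsc_profile(expr, labels, gs)
  resp <- labels$sample_id[labels$response == 1L]
  nonr <- labels$sample_id[labels$response == 0L]
  for (s in labels$sample_id[c(1, 4, 7)]) {
    for (p in names(gs$sets)) {
      want <- tsc_sample_vs_population(expr, s, setdiff(resp, s),
                                       gs$sets[[p]]) -
        tsc_sample_vs_population(expr, s, setdiff(nonr, s), gs$sets[[p]])
      expect_equal(prof$delta[s, p], want, tolerance = 1e-10)
    }
  }
})

test_that("mirrored twin samples get equal and opposite deltas", {
  # A == B with opposite labels, and the remaining responder/non-responder
  # reference samples mirrored (E == F), so the two holdout comparisons are
  # exact mirror images.
  set.seed(22)
  a <- rnorm(12)
  e <- rnorm(12)
  expr <- cbind(A = a, B = a, E = e, F = e)
  rownames(expr) <- sprintf("G%02d", 1:12)
  labels <- response_table(c("A", "B", "E", "F"), c(1, 0, 1, 0),
                           rep("x", 4), rep("ER+", 4))
  gs <- gene_sets(list(P = rownames(expr)))
  prof <- delta_tsc_profile(expr, labels, gs)
  expect_equal(prof$delta["A", "P"], -prof$delta["B", "P"], tolerance = 1e-12)
})

test_that("an all-zero pathway yields an undefined delta column", {
  expr <- rand_expr(20, 8, seed = 23)
  expr[1:5, ] <- 0
  labels <- rand_labels(expr)
  gs <- gene_sets(list(dead = rownames(expr)[1:5],
                       alive = rownames(expr)[6:15]))
  prof <- delta_tsc_profile(expr, labels, gs)
  expect_true(all(is.na(prof$delta[, "dead"])))
  expect_false(anyNA(prof$delta[, "alive"]))
})

test_that("holdout that would empty a class is a named hard error", {
  expr <- rand_expr(15, 5, seed = 24)
  labels <- rand_labels(expr, response = c(1L, 0L, 0L, 0L, 0L))
  gs <- gene_sets(list(P = rownames(expr)[1:10]))
  expect_error(delta_tsc_profile(expr, labels, gs), "responder")
})

test_that("injected covariance signal gives responders positive mean delta", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(
      n_per_arm = 30, arms = "combination",
      pcr_rate_by_arm = c(combination = 0.5), n_genes = 300, n_pathways = 20,
      n_signal_pathways = 3, effect_size = 3, seed = 800 + r))
    sets <- suppressMessages(
      filter_sets_by_size(co$gene_sets, 10, 30, co$expression))
    prof <- delta_tsc_profile(co$expression, co$response, sets)
    resp_ids <- co$response$sample_id[co$response$response == 1L]
    sig <- intersect(co$ground_truth$signal_pathways, prof$pathway_names)
    m <- mean(prof$delta[resp_ids, sig], na.rm = TRUE)
    if (m > 0) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("loocv predictions are deterministic and structurally sound", {
  co <- generate_cohort(cohort_config(
    n_per_arm = 24, arms = "combination", pcr_rate_by_arm = c(combination = 0.5),
    n_genes = 200, n_pathways = 15, n_signal_pathways = 2, effect_size = 1,
    seed = 30))
  sets <- suppressMessages(
    filter_sets_by_size(co$gene_sets, 10, 30, co$expression))
  p1 <- loocv_predict(co$expression, co$response, sets, n_draws = 20, seed = 7)
  p2 <- loocv_predict(co$expression, co$response, sets, n_draws = 20, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$votes_responder <= p1$votes_total))
  expect_true(all(p1$votes_total <= 20L))
  expect_identical(p1$predicted,
                   as.integer(p1$votes_responder > p1$votes_total / 2))
  expect_equal(p1$vote_fraction, p1$votes_responder / p1$votes_total)
})

test_that("swapping class labels flips every prediction", {
  co <- generate_cohort(cohort_config(
    n_per_arm = 20, arms = "combination", pcr_rate_by_arm = c(combination = 0.5),
    n_genes = 150, n_pathways = 10, n_signal_pathways = 0, effect_size = 0,
    seed = 31))
  sets <- suppressMessages(
    filter_sets_by_size(co$gene_sets, 10, 30, co$expression))
  labels <- co$response
  flipped <- labels
  flipped$response <- 1L - flipped$response
  # odd draw count so a vote tie cannot mask the flip
  p <- loocv_predict(co$expression, labels, sets, n_draws = 21, seed = 9)
  q <- loocv_predict(co$expression, flipped, sets, n_draws = 21, seed = 9)
  expect_identical(q$votes_total, p$votes_total)
  expect_identical(q$votes_responder, p$votes_total - p$votes_responder)
  expect_identical(q$predicted, 1L - p$predicted)
})

test_that("classes smaller than the draw fall back with a loud warning", {
  expr <- rand_expr(40, 8, seed = 32)
  labels <- rand_labels(expr, response = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  gs <- gene_sets(list(P = rownames(expr)[1:12]))
  expect_warning(
    p <- loocv_predict(expr, labels, gs, n_draws = 10, draw_size = 5, seed = 3),
    "WITH replacement")
  expect_identical(nrow(p), 8L)
})

test_that("draws dominated by undefined pathways abstain", {
  expr <- rand_expr(30, 10, seed = 33)
  expr[1:20, ] <- 0  # two of three pathways dead -> >50% undefined
  labels <- rand_labels(expr)
  gs <- gene_sets(list(dead1 = rownames(expr)[1:10],
                       dead2 = rownames(expr)[11:20],
                       alive = rownames(expr)[21:30]))
  p <- loocv_predict(expr, labels, gs, n_draws = 10, draw_size = 2, seed = 4)
  expect_true(all(p$votes_total == 0L))
  expect_true(all(p$predicted == 0L))
  expect_true(all(is.na(p$vote_fraction)))
})
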