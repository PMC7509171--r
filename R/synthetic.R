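#' Configuration for a synthetic neoadjuvant cohort
#'
#' Captures the generating conditions of a three-arm neoadjuvant trial
#' cohort: per-arm responder (pCR) probabilities defaulting to the trial's
#' printed rates (lapatinib 24.7%, trastuzumab 29.5%, combination 51.3%),
#' ER+/ER- strata, a dominant shared expression baseline giving very high
#' inter-sample Pearson correlation, modest class-independent co-expression
#' within every pathway, and a response-linked perturbation of the gene-gene
#' covariance of designated signal pathways.
#'
#' The generative model for gene g, sample s is
#' \deqn{x_{gs} = \mu_g + \sum_{p \ni g} u_{pg} z_{ps}
#'   + 1[p\ signal] \; e \, w^{(c_s)}_{pg} y_{ps} + \epsilon_{gs}}
#' with a fixed gene baseline \eqn{\mu_g \sim N(0, gene\_sd^2)} shared by all
#' samples, per-pathway co-expression factors \eqn{z_{ps} \sim N(0,1)} with
#' loadings \eqn{u_{pg} \sim N(0, pathway\_factor\_sd^2)}, and, on signal
#' pathways only, a second factor whose loading vector \eqn{w^{(c)}} depends
#' on the response class \eqn{c_s}, scaled by `effect_size` e. At
#' `effect_size = 0` the two classes are generated identically. The signal
#' perturbs gene-gene covariance, not gene means; `mean_shift` optionally
#' adds a responder mean shift on signal-pathway genes for testing
#' univariate gene biomarkers.
#'
#' The residual noise standard deviation is calibrated from
#' `baseline_correlation` (the target typical inter-sample Pearson
#' correlation of the signal-free cohort): with shared variance
#' `gene_sd^2` and average pathway-factor variance per gene
#' `pathway_factor_sd^2 * sum(sizes) / n_genes`, the residual variance is
#' set to `gene_sd^2 * (1 - rho) / rho` minus the factor contribution. An
#' infeasible calibration (non-positive residual variance) produces a
#' warning and is flagged in the ground truth.
#'
#' @param n_per_arm samples per treatment arm (default 50).
#' @param arms treatment arms to generate (default all three).
#' @param pcr_rate_by_arm named responder probabilities per arm.
#' @param er_pos_fraction probability of ER+ status per sample (default 0.5).
#' @param n_genes measured genes (default 1000).
#' @param n_pathways emitted gene sets (default 100).
#' @param pathway_size_range inclusive set-size range (default `c(10, 30)`).
#' @param n_signal_pathways pathways carrying response-linked covariance
#'   signal (default 10).
#' @param effect_size class-difference strength in signal-pathway covariance
#'   (default 1; 0 disables all class-linked signal).
#' @param baseline_correlation target typical inter-sample Pearson
#'   correlation (default 0.95).
#' @param gene_sd standard deviation of the shared gene baseline on the log
#'   scale (default 4).
#' @param pathway_factor_sd loading scale of the class-independent pathway
#'   co-expression factors (default 0.5).
#' @param mean_shift responder mean shift on signal-pathway genes
#'   (default 0).
#' @param exp_transform emit `2^x` abundances instead of log-scale values
#'   (default `FALSE`).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 50L,
                          arms = c("lapatinib", "trastuzumab", "combination"),
                          pcr_rate_by_arm = c(lapatinib = 0.247,
                                              trastuzumab = 0.295,
                                              combination = 0.513),
                          er_pos_fraction = 0.5,
                          n_genes = 1000L,
                          n_pathways = 100L,
                          pathway_size_range = c(10L, 30L),
                          n_signal_pathways = 10L,
                          effect_size = 1,
                          baseline_correlation = 0.95,
                          gene_sd = 4,
                          pathway_factor_sd = 0.5,
                          mean_shift = 0,
                          exp_transform = FALSE,
                          seed = 1L) {
  cfg <- list(n_per_arm = as.integer(n_per_arm),
              arms = as.character(unlist(arms)),
              pcr_rate_by_arm = unlist(pcr_rate_by_arm),  # YAML maps arrive as lists
              er_pos_fraction = er_pos_fraction,
              n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_signal_pathways = as.integer(n_signal_pathways),
              effect_size = effect_size,
              baseline_correlation = baseline_correlation,
              gene_sd = gene_sd, pathway_factor_sd = pathway_factor_sd,
              mean_shift = mean_shift, exp_transform = isTRUE(exp_transform),
              seed = as.integer(seed))
  miss <- setdiff(cfg$arms, names(cfg$pcr_rate_by_arm))
  if (length(miss))
    stop("no pCR rate configured for arm(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rates <- cfg$pcr_rate_by_arm[cfg$arms]
  if (any(rates < 0 | rates > 1) || cfg$er_pos_fraction < 0 ||
      cfg$er_pos_fraction > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (cfg$n_signal_pathways > cfg$n_pathways)
    stop("n_signal_pathways cannot exceed n_pathways", call. = FALSE)
  if (cfg$pathway_size_range[1L] < 2L ||
      cfg$pathway_size_range[2L] > cfg$n_genes ||
      cfg$pathway_size_range[1L] > cfg$pathway_size_range[2L])
    stop("pathway_size_range must lie within [2, n_genes]", call. = FALSE)
  if (cfg$effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (cfg$n_per_arm < 1L) stop("n_per_arm must be >= 1", call. = FALSE)
  if (cfg$baseline_correlation <= 0 || cfg$baseline_correlation >= 1)
    stop("baseline_correlation must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic neoadjuvant cohort
#'
#' Draws a full cohort under a [cohort_config()]: per-arm Bernoulli response
#' labels at the configured pCR rates, ER strata, an expression matrix from
#' the latent-factor model described in [cohort_config()], and the emitted
#' gene-set collection, together with the ground truth needed to test every
#' downstream stage (signal pathway names, calibration status, generating
#' parameters).
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `expression`
#'   (genes x samples matrix), `response` (a [response_table()]),
#'   `gene_sets` (a [gene_sets()] collection) and `ground_truth` (list with
#'   `signal_pathways`, `residual_sd`, `calibration_met`, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_arm * length(config$arms)
  sample_ids <- sprintf("S%04d", seq_len(n))
  arm <- rep(config$arms, each = config$n_per_arm)
  response <- rbinom(n, 1L, config$pcr_rate_by_arm[arm])
  er <- ifelse(rbinom(n, 1L, config$er_pos_fraction) == 1L, "ER+", "ER-")
  labels <- response_table(sample_ids, response, arm, er)

  g_ids <- sprintf("G%05d", seq_len(config$n_genes))
  sizes <- sample(seq(config$pathway_size_range[1L],
                      config$pathway_size_range[2L]),
                  config$n_pathways, replace = TRUE)
  p_names <- sprintf("PWY_%03d", seq_len(config$n_pathways))
  sets <- lapply(sizes, function(s) sample(g_ids, s))
  names(sets) <- p_names
  signal <- p_names[seq_len(config$n_signal_pathways)]

  ## residual-noise calibration against the target typical pair correlation
  factor_var <- config$pathway_factor_sd^2 * sum(sizes) / config$n_genes
  rho <- config$baseline_correlation
  tau2 <- config$gene_sd^2 * (1 - rho) / rho - factor_var
  calibration_met <- tau2 > 0
  if (!calibration_met) {
    warning("baseline_correlation infeasible given pathway factor variance; ",
            "residual noise floored", call. = FALSE)
    tau2 <- 0.01
  }
  tau <- sqrt(tau2)

  mu <- rnorm(config$n_genes, 0, config$gene_sd)
  x <- matrix(mu, config$n_genes, n) +
    matrix(rnorm(config$n_genes * n, 0, tau), config$n_genes, n)
  dimnames(x) <- list(g_ids, sample_ids)
  for (p in seq_len(config$n_pathways)) {
    g <- match(sets[[p]], g_ids)
    m <- length(g)
    u <- rnorm(m, 0, config$pathway_factor_sd)
    z <- rnorm(n)
    x[g, ] <- x[g, ] + outer(u, z)
    if (p <= config$n_signal_pathways && config$effect_size > 0) {
      w_resp <- rnorm(m)
      w_non <- rnorm(m)
      y <- rnorm(n)
      w <- outer(w_resp, as.numeric(response == 1L)) +
        outer(w_non, as.numeric(response == 0L))
      x[g, ] <- x[g, ] + config$effect_size * w *
        matrix(y, m, n, byrow = TRUE)
    }
  }
  if (config$mean_shift != 0 && config$n_signal_pathways > 0L) {
    sig_genes <- match(unique(unlist(sets[signal])), g_ids)
    x[sig_genes, response == 1L] <- x[sig_genes, response == 1L] +
      config$mean_shift
  }
  if (config$exp_transform) x <- 2^x

  structure(list(expression = expression_matrix(x),
                 response = labels,
                 gene_sets = gene_sets(sets,
                                       source_description = "synthetic cohort"),
                 ground_truth = list(signal_pathways = signal,
                                     residual_sd = tau,
                                     calibration_met = calibration_met,
                                     config = config)),
            class = "synthetic_cohort")
}

#' Emulation report of cohort-level properties
#'
#' Summarizes the cohort properties the generator is meant to reproduce:
#' the fraction of sample pairs with Pearson correlation above a threshold
#' (0.9 by default), per-arm responder fractions, and the pathway size
#' distribution.
#'
#' @param expr expression matrix with at least 2 samples.
#' @param response optional [response_table()] for per-arm responder
#'   fractions.
#' @param gene_sets optional [gene_sets()] collection for the size histogram.
#' @param r_threshold Pearson threshold defining a "highly correlated" pair
#'   (default 0.9).
#' @return a list of class `emulation_report` with `frac_pairs_above`,
#'   `n_pairs`, `r_threshold`, `responder_fraction_by_arm` (data.frame or
#'   `NULL`) and `pathway_sizes` (integer vector or `NULL`).
#' @export
emulation_report <- function(expr, response = NULL, gene_sets = NULL,
                             r_threshold = 0.9) {
  if (ncol(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  cc <- cor(expr)
  pairs <- cc[upper.tri(cc)]
  by_arm <- NULL
  if (!is.null(response)) {
    agg <- stats::aggregate(response ~ arm, data = response, FUN = mean)
    names(agg) <- c("arm", "responder_fraction")
    agg$n <- as.vector(table(response$arm)[agg$arm])
    by_arm <- agg
  }
  structure(list(frac_pairs_above = mean(pairs > r_threshold),
                 n_pairs = length(pairs),
                 r_threshold = r_threshold,
                 responder_fraction_by_arm = by_arm,
                 pathway_sizes = if (!is.null(gene_sets))
                   lengths(gene_sets$sets) else NULL),
            class = "emulation_report")
}

#' @export
print.emulation_report <- function(x, ...) {
  cat(sprintf("fraction of sample pairs with Pearson r > %.2f: %.3f (%d pairs)\n",
              x$r_threshold, x$frac_pairs_above, x$n_pairs))
  if (!is.null(x$responder_fraction_by_arm)) {
    cat("responder fraction by arm:\n")
    print(x$responder_fraction_by_arm, row.names = FALSE)
  }
  if (!is.null(x$pathway_sizes))
    cat("pathway sizes:", min(x$pathway_sizes), "-", max(x$pathway_sizes),
        "(n =", length(x$pathway_sizes), ")\n")
  invisible(x)
}
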