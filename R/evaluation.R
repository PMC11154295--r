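#' Precision, recall, and F1 of causal-locus recovery
#'
#' Precision is clump-level purity: the fraction of clumps whose index or
#' members include at least one causal variant. Recall is causal-variant
#' coverage: the fraction of the K causal variants appearing in any clump
#' (as index or member). F1 is their harmonic mean, 0 when both are 0. A
#' causal variant counts as recovered in both the index and member roles;
#' an index-only variant of the metrics is also reported for comparison
#' (`precision_index`, `recall_index`).
#'
#' @param clumpset a `clump_set`.
#' @param spec a `causal_spec`.
#' @return List with `precision`, `recall`, `f1`, `n_clumps`, `n_causal`,
#'   plus the index-only variants of precision and recall.
#' @export
precision_recall_f1 <- function(clumpset, spec) {
  stopifnot(inherits(clumpset, "clump_set"), inherits(spec, "causal_spec"))
  causal <- spec$entries$id
  cl <- clumpset$clumps
  n_clumps <- nrow(cl)
  if (n_clumps == 0) {
    precision <- recall <- 0
    precision_index <- recall_index <- 0
  } else {
    hit <- vapply(seq_len(n_clumps), function(i) {
      any(c(cl$index[i], cl$members[[i]]) %in% causal)
    }, logical(1))
    precision <- sum(hit) / n_clumps
    recall <- sum(causal %in% clumped_ids(clumpset)) / length(causal)
    precision_index <- sum(cl$index %in% causal) / n_clumps
    recall_index <- sum(causal %in% cl$index) / length(causal)
  }
  f1 <- function(p, r) if (p + r == 0) 0 else 2 / (1 / p + 1 / r)
  list(precision = precision, recall = recall, f1 = f1(precision, recall),
       n_clumps = n_clumps, n_causal = length(causal),
       precision_index = precision_index, recall_index = recall_index)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes number of successes (0 <= successes <= n).
#' @param n number of trials (>= 1).
#' @param confidence confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n,
            confidence > 0, confidence < 1)
  z <- stats::qnorm((1 + confidence) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Benchmark TPR/FPR from per-simulation enrichment results
#'
#' Consumes a result table from an external enrichment tool (one row per
#' simulation x gene set with its enrichment p-value) together with the
#' design of each simulation, applies a multiple-testing procedure across
#' the sets tested within each simulation, and reports the true positive
#' rate (fraction of causal-design simulations in which the target set is
#' significant) and the false positive rate (fraction of null-design
#' simulations with at least one significant set), each with a Wilson
#' score interval.
#'
#' @param results data.frame with columns `sim`, `set`, `p`.
#' @param target_set the causal (target) gene-set name.
#' @param alpha significance level, default 0.05.
#' @param multiple_testing one of "bonferroni" (default), "BH", "none".
#' @param null_sims optional character/integer vector naming the
#'   simulations that used fully random causal variants (the null design);
#'   simulations not listed are treated as causal-design. When `NULL`, all
#'   simulations are causal-design and FPR is `NA`.
#' @param confidence Wilson interval level, default 0.95.
#' @return List with `tpr`, `fpr`, counts, and `tpr_ci`/`fpr_ci`.
#' @export
tpr_fpr <- function(results, target_set, alpha = 0.05,
                    multiple_testing = c("bonferroni", "BH", "none"),
                    null_sims = NULL, confidence = 0.95) {
  stopifnot(all(c("sim", "set", "p") %in% names(results)), nrow(results) >= 1)
  multiple_testing <- match.arg(multiple_testing)
  if (!target_set %in% results$set) {
    stop("target set absent from the result table: ", target_set, call. = FALSE)
  }
  adjust <- function(p) switch(multiple_testing,
    bonferroni = stats::p.adjust(p, "bonferroni"),
    BH = stats::p.adjust(p, "BH"),
    none = p)
  sims <- split(results, results$sim)
  sig_target <- vapply(sims, function(d) {
    any(d$set == target_set & adjust(d$p) < alpha)
  }, logical(1))
  sig_any <- vapply(sims, function(d) any(adjust(d$p) < alpha), logical(1))
  is_null <- names(sims) %in% as.character(null_sims)

  n_causal <- sum(!is_null)
  tpr <- if (n_causal) sum(sig_target[!is_null]) / n_causal else NA_real_
  n_null <- sum(is_null)
  fpr <- if (n_null) sum(sig_any[is_null]) / n_null else NA_real_
  list(
    tpr = tpr,
    fpr = fpr,
    n_causal_sims = n_causal, n_null_sims = n_null,
    tpr_ci = if (n_causal) wilson_interval(sum(sig_target[!is_null]),
                                           n_causal, confidence) else NULL,
    fpr_ci = if (n_null) wilson_interval(sum(sig_any[is_null]),
                                         n_null, confidence) else NULL,
    alpha = alpha, multiple_testing = multiple_testing,
    confidence = confidence)
}

#' Grid search over phenotype-simulation parameter sets
#'
#' Runs the full simulate-associate-clump-evaluate pipeline for every
#' combination in `grid` with `n_replicates` independently seeded
#' replicates each, and returns mean precision/recall/F1 per grid point,
#' ranked by mean F1 (ties by mean recall). A failing replicate is scored
#' as all-zero metrics with a logged diagnostic rather than aborting the
#' search.
#'
#' @param grid data.frame whose rows are parameter combinations; recognised
#'   columns are `K`, `k` and the arguments of [phenotype_params()].
#' @param n_replicates replicates per grid point.
#' @param genotypes a `genotype_matrix` shared by all runs.
#' @param map nearest-gene map for the genotype variants.
#' @param pool candidate-pool variant ids.
#' @param sets gene-set collection.
#' @param set_name target gene set.
#' @param clump_parameters `clump_params` used for evaluation (default:
#'   genome-wide significance index threshold).
#' @param seed master seed; replicate seeds are derived with
#'   [derive_seeds()].
#' @return data.frame: one row per grid point with its parameters and mean
#'   metrics, sorted best-first.
#' @export
grid_search <- function(grid, n_replicates, genotypes, map, pool, sets,
                        set_name,
                        clump_parameters = clump_params(p1 = 5e-8),
                        seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, n_replicates >= 1)
  res <- grid
  res$precision <- res$recall <- res$f1 <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    row <- grid[gi, , drop = FALSE]
    K <- row$K %||% 10
    k <- row$k %||% ceiling(K / 2)
    par_args <- intersect(names(row), names(formals(phenotype_params)))
    params <- do.call(phenotype_params, as.list(row[par_args]))
    mets <- matrix(0, nrow = n_replicates, ncol = 3)
    for (r in seq_len(n_replicates)) {
      mets[r, ] <- tryCatch({
        m <- run_replicate(genotypes, map, pool, sets, set_name, K, k,
                           params, clump_parameters,
                           seed = derive_seeds(seed, sprintf("grid%d", gi), r))
        c(m$precision, m$recall, m$f1)
      }, error = function(e) {
        message(sprintf("grid point %d replicate %d failed: %s",
                        gi, r, conditionMessage(e)))
        c(0, 0, 0)
      })
    }
    res$precision[gi] <- mean(mets[, 1])
    res$recall[gi] <- mean(mets[, 2])
    res$f1[gi] <- mean(mets[, 3])
  }
  res[order(-res$f1, -res$recall), , drop = FALSE]
}

# One simulate-associate-clump-evaluate replicate on fixed genotypes.
run_replicate <- function(genotypes, map, pool, sets, set_name, K, k, params,
                          clump_parameters, seed) {
  spec <- select_from_pathway(map, pool, sets, set_name, K, k, seed = seed)
  beta <- draw_effects(K, params, seed = derive_seeds(seed, "effects", 1L))
  G <- extract_causal_genotypes(genotypes, spec)
  pheno <- simulate_quantitative(G, beta, params,
                                 seed = derive_seeds(seed, "pheno", 1L))
  stats <- assoc_quantitative(genotypes, pheno)
  cs <- clump(stats, genotypes, clump_parameters)
  precision_recall_f1(cs, spec)
}
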