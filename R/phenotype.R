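#' Phenotype simulation parameters
#'
#' The variance-partition parameterization of the simulated trait:
#' `m_beta`/`sd_beta` give the mean and standard deviation of per-variant
#' effect sizes; `h2` the proportion of phenotypic variance explained by the
#' genetic component (heritability); `hs2` the proportion of genetic
#' variance carried by the selected causal variants (the remainder comes
#' from a background polygenic score); `theta`, `p_indep`, `phi` and `alpha`
#' are multi-trait sharing parameters that must hold their inert
#' single-trait values (0, 1, 1, 0) — non-default values are rejected
#' rather than silently approximated. Defaults are the pipeline's tuned
#' default parameter set (m_beta = 0.05, sd_beta = 0.001, h2 = 0.1,
#' hs2 = 1).
#'
#' @param m_beta mean effect size.
#' @param sd_beta effect-size standard deviation (>= 0).
#' @param h2 heritability in `[0, 1]`.
#' @param hs2 proportion of genetic variance from the selected variants,
#'   in `[0, 1]`.
#' @param theta,p_indep,phi,alpha multi-trait sharing parameters; accepted
#'   for interface compatibility, validated against their single-trait
#'   defaults.
#' @param random_sign randomize the sign of each effect (default `TRUE`).
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(m_beta = 0.05, sd_beta = 0.001, h2 = 0.1,
                             hs2 = 1, theta = 0, p_indep = 1, phi = 1,
                             alpha = 0, random_sign = TRUE) {
  stopifnot(sd_beta >= 0, h2 >= 0, h2 <= 1, hs2 >= 0, hs2 <= 1,
            phi >= 0, phi <= 1)
  if (theta != 0 || p_indep != 1 || phi != 1 || alpha != 0) {
    stop("multi-trait parameters must hold their single-trait values ",
         "(theta = 0, p_indep = 1, phi = 1, alpha = 0); ",
         "multi-trait simulation is not supported", call. = FALSE)
  }
  structure(as.list(environment()), class = "phenotype_params")
}

#' Draw per-variant effect sizes
#'
#' Effect `beta_j = s_j * x_j` with `x_j ~ Normal(m_beta, sd_beta^2)` and a
#' uniform random sign `s_j` in \{-1, +1\} when `random_sign` is on.
#'
#' @param K number of causal variants.
#' @param params a `phenotype_params`.
#' @param seed optional integer seed.
#' @return Numeric effect vector of length `K`.
#' @export
draw_effects <- function(K, params = phenotype_params(), seed = NULL) {
  stopifnot(K >= 1, inherits(params, "phenotype_params"))
  with_seed_if(seed, {
    x <- stats::rnorm(K, mean = params$m_beta, sd = params$sd_beta)
    s <- if (isTRUE(params$random_sign)) {
      sample(c(-1, 1), K, replace = TRUE)
    } else rep(1, K)
  })
  s * x
}

#' Simulate a quantitative trait from causal genotypes
#'
#' The genetic score is `standardize(G) %*% beta` over the causal dosage
#' matrix, rescaled to unit empirical variance; when `hs2 < 1` a background
#' polygenic score over `background_genotypes` (i.i.d. Normal(0, 1/B)
#' effects) is mixed in with weight `sqrt(1 - hs2)` and the combination is
#' re-standardized. Observational noise is drawn Normal(0, 1),
#' orthogonalized against the genetic component, and standardized, so the
#' realized variance partition is exact: the stored genetic component
#' explains precisely `h2` of the phenotypic variance (see the methods
#' vignette for why empirical rather than expected-variance scaling is
#' used).
#'
#' @param causal_genotypes N x K `genotype_matrix` (from
#'   [extract_causal_genotypes()]).
#' @param beta effect vector of length K (from [draw_effects()]).
#' @param params a `phenotype_params`.
#' @param background_genotypes optional N x B `genotype_matrix`; required
#'   when `hs2 < 1`, ignored when `hs2 = 1`.
#' @param seed optional integer seed.
#' @return An object of class `phenotype_vector`: list with `sample_ids`,
#'   `values`, and `components` (data.frame with columns `genetic` and
#'   `noise` summing to `values`).
#' @export
simulate_quantitative <- function(causal_genotypes, beta,
                                  params = phenotype_params(),
                                  background_genotypes = NULL, seed = NULL) {
  stopifnot(inherits(causal_genotypes, "genotype_matrix"),
            inherits(params, "phenotype_params"))
  G <- causal_genotypes$dosages
  n <- nrow(G)
  if (length(beta) != ncol(G)) {
    stop("beta length must equal the number of causal variants", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 individuals", call. = FALSE)
  sds <- apply(G, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance causal variant(s): ",
         paste(causal_genotypes$variants$id[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  if (params$hs2 < 1 && is.null(background_genotypes)) {
    stop("hs2 < 1 requires background_genotypes", call. = FALSE)
  }

  Gs <- scale(G) %*% beta
  gs <- standardise_vec(drop(Gs), what = "causal genetic score")

  with_seed_if(seed, {
    if (params$hs2 < 1) {
      B <- background_genotypes$dosages
      bsd <- apply(B, 2, stats::sd)
      B <- B[, bsd > 0, drop = FALSE]
      if (!ncol(B)) stop("background genotypes are all monomorphic", call. = FALSE)
      bb <- stats::rnorm(ncol(B), 0, sqrt(1 / ncol(B)))
      gbg <- standardise_vec(drop(scale(B) %*% bb), what = "background score")
      genetic <- standardise_vec(sqrt(params$hs2) * gs +
                                   sqrt(1 - params$hs2) * gbg,
                                 what = "genetic component")
    } else {
      genetic <- gs
    }
    eps <- stats::rnorm(n)
  })
  # orthogonalize noise against the genetic component so the realized
  # variance partition is exact (var(genetic part) / var(values) == h2)
  if (params$h2 < 1) {
    eps <- eps - mean(eps)
    eps <- eps - genetic * sum(eps * genetic) / sum(genetic^2)
    eps <- standardise_vec(eps, what = "noise component")
  } else {
    eps <- rep(0, n)
  }
  g_part <- sqrt(params$h2) * genetic
  e_part <- sqrt(1 - params$h2) * eps
  structure(
    list(sample_ids = causal_genotypes$sample_ids,
         values = g_part + e_part,
         components = data.frame(genetic = g_part, noise = e_part)),
    class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("<phenotype_vector> %d individuals, var(genetic)/var(values) = %.4f\n",
              length(x$values),
              stats::var(x$components$genetic) / stats::var(x$values)))
  invisible(x)
}

#' Dichotomize a quantitative trait into cases and controls
#'
#' Liability-threshold dichotomization: the `prevalence * N` individuals
#' with the largest trait values become cases (ties broken by sample
#' order).
#'
#' @param pheno a `phenotype_vector`.
#' @param prevalence case fraction in (0, 1).
#' @param seed unused (reserved; the thresholding is deterministic).
#' @return Integer vector (1 = control, 2 = case, PLINK-style), named by
#'   sample id.
#' @export
binarize <- function(pheno, prevalence, seed = NULL) {
  stopifnot(inherits(pheno, "phenotype_vector"))
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  n <- length(pheno$values)
  n_case <- floor(prevalence * n)
  if (n_case < 1) stop("prevalence * N < 1: no cases", call. = FALSE)
  ord <- order(-pheno$values, seq_len(n))   # ties broken by sample order
  labels <- rep(1L, n)
  labels[ord[seq_len(n_case)]] <- 2L
  names(labels) <- pheno$sample_ids
  labels
}

#' Write a phenotype file (FID, IID, PHENO)
#'
#' @param pheno a `phenotype_vector`, or a named case/control vector from
#'   [binarize()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  if (inherits(pheno, "phenotype_vector")) {
    out <- data.frame(FID = pheno$sample_ids, IID = pheno$sample_ids,
                      PHENO = pheno$values)
  } else {
    out <- data.frame(FID = names(pheno), IID = names(pheno),
                      PHENO = as.integer(pheno))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
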