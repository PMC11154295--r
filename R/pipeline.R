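#' Derive a stage- and replicate-specific RNG seed
#'
#' Deterministic, collision-resistant derivation of sub-seeds from a master
#' seed, so that individual pipeline stages and replicates can be
#' reproduced in isolation. Mixing is multiplicative hashing over the
#' stage label and replicate index modulo the Mersenne prime 2^31 - 1; the
#' result is always a valid positive 32-bit integer seed.
#'
#' @param master_seed integer master seed.
#' @param stage stage label (character).
#' @param replicate replicate index (integer), default 1.
#' @return A positive integer seed below 2^31 - 1.
#' @export
derive_seeds <- function(master_seed, stage, replicate = 1L) {
  p <- 2147483647
  h <- as.numeric(master_seed) %% p
  for (cc in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + cc) %% p
  }
  h <- (h * 131 + as.numeric(replicate) + 17) %% p
  h <- (h * 48271) %% p          # final scramble (Lehmer multiplier)
  as.integer(h %% (p - 1) + 1)
}

#' Assemble and validate a pipeline run configuration
#'
#' Collects paths and stage parameters for [run_pipeline()]. Exactly one
#' causal mode must be active: a target gene set (`gene_set`) or an
#' explicit causal-id list (`causal_ids`). Referenced input files are
#' checked at validation time. Values may also be loaded from a YAML file
#' with `load_run_config()`, with later arguments overriding file values.
#'
#' @param vcf path to the phased reference panel VCF (`NULL` when
#'   `genotypes` are supplied directly to [run_pipeline()]).
#' @param annotation path to the gene annotation (GTF or BED).
#' @param gmt path to the gene-set GMT file.
#' @param keep optional sample keep-list path (one id per line).
#' @param causal_ids optional explicit causal-variant id file (one per line).
#' @param gene_set target gene-set name (pathway causal mode).
#' @param n_individuals simulated sample size N (required for the genotype
#'   stage; no silent default).
#' @param maf inclusive panel MAF filter, default 0.
#' @param causal_maf_min,causal_maf_max exclusive candidate MAF window,
#'   defaults 0.05 and 0.5.
#' @param k_total,k_pathway causal counts K and k.
#' @param switch_rate mosaic switch probability, default 0.002.
#' @param params a [phenotype_params()] object.
#' @param clump_parameters a [clump_params()] object used for locus
#'   reporting; evaluation additionally uses a genome-wide `p1`.
#' @param trait `"quant"` or `"binary"`.
#' @param prevalence case fraction for binary traits.
#' @param seed master seed.
#' @param out output prefix (directory is created).
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf = NULL, annotation = NULL, gmt = NULL, keep = NULL,
                       causal_ids = NULL, gene_set = NULL,
                       n_individuals = NULL, maf = 0,
                       causal_maf_min = 0.05, causal_maf_max = 0.5,
                       k_total = 10, k_pathway = 5, switch_rate = 0.002,
                       params = phenotype_params(),
                       clump_parameters = clump_params(),
                       trait = c("quant", "binary"), prevalence = 0.1,
                       seed = 1, out = "gwasforge_run") {
  trait <- match.arg(trait)
  if (is.null(causal_ids) == is.null(gene_set)) {
    stop("exactly one causal mode must be chosen: gene_set or causal_ids",
         call. = FALSE)
  }
  for (f in c(vcf, annotation, gmt, keep, causal_ids)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f,
                                             call. = FALSE)
  }
  stopifnot(inherits(params, "phenotype_params"),
            inherits(clump_parameters, "clump_params"),
            k_pathway <= k_total)
  fields <- names(formals(run_config))
  structure(mget(fields, envir = environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of configuration values.
#' @param ... overrides applied on top of the file values.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  if (!is.null(vals$params) && !inherits(vals$params, "phenotype_params")) {
    vals$params <- do.call(phenotype_params, vals$params)
  }
  if (!is.null(vals$clump_parameters) &&
      !inherits(vals$clump_parameters, "clump_params")) {
    vals$clump_parameters <- do.call(clump_params, vals$clump_parameters)
  }
  do.call(run_config, vals)
}

#' Run the full simulation pipeline
#'
#' Executes the three-stage workflow: (1) genotype simulation from the
#' reference panel (skipped when `genotypes` is supplied directly);
#' (2) causal-variant selection and phenotype simulation; (3) association
#' testing, clumping, evaluation against the known causal set, and
#' plotting. All artifacts are written under the `out` prefix together
#' with a JSON manifest recording parameters, derived seeds, and file
#' checksums.
#'
#' @param config a `run_config`.
#' @param genotypes optional pre-made `genotype_matrix`; bypasses the
#'   genotype stage.
#' @param write_genotypes write the (possibly large) simulated genotype VCF
#'   and dosage matrix; default `TRUE`.
#' @param make_plots render Manhattan, Q-Q and PCA plots; default `TRUE`.
#' @return Invisibly, a list with the main in-memory artifacts
#'   (`genotypes`, `spec`, `pheno`, `stats`, `clumps`, `metrics`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config, genotypes = NULL, write_genotypes = TRUE,
                         make_plots = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  out_dir <- dirname(config$out)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prefix <- config$out
  log_stage <- function(fmt, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  files <- character(0)
  seeds <- list()

  # --- stage 1: genotypes ---------------------------------------------
  if (is.null(genotypes)) {
    if (is.null(config$vcf)) stop("config$vcf is required when genotypes are not supplied",
                                  call. = FALSE)
    if (is.null(config$n_individuals)) {
      stop("n_individuals must be set explicitly (no default sample size)",
           call. = FALSE)
    }
    log_stage("loading reference panel from %s", config$vcf)
    panel <- load_panel(config$vcf)
    keep_ids <- if (!is.null(config$keep)) readLines(config$keep) else NULL
    panel <- filter_panel(panel, min_maf = config$maf, keep_ids = keep_ids)
    seeds$genotypes <- derive_seeds(config$seed, "genotypes", 1L)
    log_stage("simulating %d individuals x %d variants",
              config$n_individuals, nrow(panel$variants))
    genotypes <- simulate_genotypes(panel, config$n_individuals,
                                    switch_rate = config$switch_rate,
                                    seed = seeds$genotypes)
  } else {
    log_stage("genotype stage skipped: user-supplied genotypes (%d x %d)",
              nrow(genotypes$dosages), nrow(genotypes$variants))
  }
  if (write_genotypes) {
    write_genotypes_vcf(genotypes, paste0(prefix, ".genotypes.vcf"))
    write_dosage_matrix(genotypes, paste0(prefix, ".dosages.tsv"))
    files <- c(files, paste0(prefix, ".genotypes.vcf"),
               paste0(prefix, ".dosages.tsv"),
               paste0(prefix, ".dosages.tsv.variants.tsv"))
  }

  # --- stage 2: causal selection + phenotype --------------------------
  seeds$causal <- derive_seeds(config$seed, "causal", 1L)
  if (!is.null(config$gene_set)) {
    genes <- read_gene_intervals(config$annotation)
    sets <- read_gmt(config$gmt)
    map <- nearest_gene(genotypes$variants, genes)
    pool <- candidate_pool(genotypes, config$causal_maf_min,
                           config$causal_maf_max)
    spec <- select_from_pathway(map, pool, sets, config$gene_set,
                                K = config$k_total, k = config$k_pathway,
                                seed = seeds$causal)
  } else {
    ids <- readLines(config$causal_ids)
    spec <- select_explicit(ids, genotypes)
  }
  write_causal_spec(spec, paste0(prefix, ".causal.tsv"), genotypes)
  files <- c(files, paste0(prefix, ".causal.tsv"))

  seeds$effects <- derive_seeds(config$seed, "effects", 1L)
  seeds$pheno <- derive_seeds(config$seed, "pheno", 1L)
  beta <- draw_effects(nrow(spec$entries), config$params, seed = seeds$effects)
  causal_geno <- extract_causal_genotypes(genotypes, spec)
  background <- NULL
  if (config$params$hs2 < 1) {
    # background polygenic score: up to 1000 non-causal candidate variants
    if (is.null(config$gene_set)) {
      pool <- candidate_pool(genotypes, config$causal_maf_min,
                             config$causal_maf_max)
    }
    bg_ids <- setdiff(pool, spec$entries$id)
    seeds$background <- derive_seeds(config$seed, "background", 1L)
    bg_ids <- with_seed_if(seeds$background,
                           sample(bg_ids, min(1000L, length(bg_ids))))
    background <- subset_genotypes(genotypes, bg_ids)
  }
  log_stage("simulating phenotype for %d individuals (h2 = %g)",
            nrow(causal_geno$dosages), config$params$h2)
  pheno <- simulate_quantitative(causal_geno, beta, config$params,
                                 background_genotypes = background,
                                 seed = seeds$pheno)
  labels <- NULL
  if (config$trait == "binary") {
    labels <- binarize(pheno, config$prevalence)
    write_phenotype(labels, paste0(prefix, ".pheno.tsv"))
  } else {
    write_phenotype(pheno, paste0(prefix, ".pheno.tsv"))
  }
  files <- c(files, paste0(prefix, ".pheno.tsv"))

  # --- stage 3: association, clumping, evaluation, plots --------------
  log_stage("association scan over %d variants", nrow(genotypes$variants))
  stats <- if (config$trait == "binary") {
    assoc_binary(genotypes, labels)
  } else {
    assoc_quantitative(genotypes, pheno)
  }
  write_sumstats(stats, paste0(prefix, ".sumstats.tsv"))
  files <- c(files, paste0(prefix, ".sumstats.tsv"))

  clumps <- clump(stats, genotypes, config$clump_parameters)
  write_clumps(clumps, paste0(prefix, ".clumped.tsv"))
  files <- c(files, paste0(prefix, ".clumped.tsv"))

  eval_clumps <- clump(stats, genotypes,
                       clump_params(p1 = 5e-8, p2 = config$clump_parameters$p2,
                                    r2 = config$clump_parameters$r2,
                                    kb = config$clump_parameters$kb))
  metrics <- precision_recall_f1(eval_clumps, spec)
  jsonlite::write_json(metrics, paste0(prefix, ".metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, paste0(prefix, ".metrics.json"))

  if (make_plots) {
    plot_err <- tryCatch({
      manhattan_plot(stats, clumps, out = paste0(prefix, ".manhattan.png"))
      qq_plot(stats, out = paste0(prefix, ".qq.png"))
      pca <- pca_genotypes(genotypes)
      plot_pca(pca, out = paste0(prefix, ".pca.png"))
      files <- c(files, paste0(prefix, c(".manhattan.png", ".qq.png", ".pca.png")))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(plot_err)) {
      warning("plotting failed: ", plot_err, call. = FALSE)
    }
  }

  manifest <- list(
    created = format(Sys.time()),
    package_version = as.character(utils::packageVersion("gwasforge")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = config$seed, derived_seeds = seeds,
    parameters = config[!vapply(config, is.null, TRUE) &
                          !names(config) %in% c("params", "clump_parameters")],
    phenotype_params = unclass(config$params),
    clump_parameters = unclass(config$clump_parameters),
    metrics = metrics[c("precision", "recall", "f1", "n_clumps")],
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- paste0(prefix, ".manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_stage("done in %.1f s; manifest at %s", manifest$elapsed_sec,
            manifest_path)
  invisible(list(genotypes = genotypes, spec = spec, pheno = pheno,
                 labels = labels, stats = stats, clumps = clumps,
                 metrics = metrics, manifest_path = manifest_path))
}
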