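#' Configuration for synthetic fixtures
#'
#' Describes the synthetic reference panel and annotation used to exercise
#' the pipeline offline. The panel is built from per-block founder
#' haplotypes: each LD block carries two common founder haplotypes whose
#' mixing weight sets the block's common-variant frequency, a low-frequency
#' arm of rare variants, and per-site mutational noise. This yields strong
#' within-block and negligible between-block linkage disequilibrium and an
#' allele-frequency spectrum with both a rare and a common arm.
#'
#' @param n_diploids panel size (diploid samples); default 100 (200 haplotypes).
#' @param n_snps total number of sites generated before monomorphic sites
#'   are dropped; default 20000.
#' @param n_blocks number of LD blocks; default 400.
#' @param n_chrom number of chromosomes the blocks are spread over; default 2.
#' @param mutation_rate per-haplotype, per-site allele flip probability on
#'   common sites; default 0.003.
#' @param p_common fraction of sites that segregate between the two block
#'   founders (the common arm of the frequency spectrum); default 0.45.
#' @param n_genes number of gene intervals tiled over the variants; default 300.
#' @param n_sets number of gene sets (three of which are the calibrated
#'   small/medium/big sets of 17, 69 and 199 genes); default 10.
#' @param genes_per_set size range (min, max) for the remaining random sets.
#' @param seed integer RNG seed.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_diploids = 100, n_snps = 20000, n_blocks = 400,
                           n_chrom = 2, mutation_rate = 0.003, p_common = 0.45,
                           n_genes = 300, n_sets = 10,
                           genes_per_set = c(10, 50), seed = 1) {
  stopifnot(n_diploids >= 1, n_snps >= 1, n_blocks >= 1, n_blocks <= n_snps,
            n_chrom >= 1, n_chrom <= n_blocks,
            mutation_rate >= 0, mutation_rate < 0.5,
            p_common > 0, p_common <= 1,
            n_genes >= 1, n_sets >= 1, length(genes_per_set) == 2,
            genes_per_set[1] >= 1, genes_per_set[1] <= genes_per_set[2])
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a synthetic phased reference panel
#'
#' Builds the founder-mosaic panel described in [fixture_config()]: sites are
#' laid out in LD blocks along `n_chrom` chromosomes; within each block two
#' founder haplotypes are mixed with a block-specific weight drawn from
#' U(0.15, 0.5), so common variants in a block are in near-perfect mutual LD
#' (attenuated only by mutational noise) while variants in different blocks
#' are essentially uncorrelated. Monomorphic sites are dropped.
#'
#' @param config a `fixture_config`.
#' @param vcf_path optional path; when given, the panel is also written as a
#'   phased VCF (byte-identical for a fixed seed).
#' @param keep_path optional path for a one-ID-per-line sample list covering
#'   all panel samples.
#' @return A `haplotype_panel`.
#' @export
make_panel <- function(config, vcf_path = NULL, keep_path = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  H <- 2L * config$n_diploids
  panel <- with_seed_if(config$seed, {
    # split sites over blocks, blocks over chromosomes
    block_sizes <- tabulate(
      rep(seq_len(config$n_blocks), length.out = config$n_snps),
      nbins = config$n_blocks)
    block_chrom <- rep(seq_len(config$n_chrom), length.out = config$n_blocks)
    block_chrom <- sort(block_chrom)

    hap <- matrix(0L, nrow = H, ncol = config$n_snps)
    pos <- numeric(config$n_snps)
    chrom <- character(config$n_snps)
    at <- 0L
    cur_pos <- 0
    cur_chrom <- 0L
    for (b in seq_len(config$n_blocks)) {
      m <- block_sizes[b]
      if (m == 0L) next
      if (block_chrom[b] != cur_chrom) {
        cur_chrom <- block_chrom[b]
        cur_pos <- 0
      }
      cols <- at + seq_len(m)
      # positions: ~0.2-1.5 kb spacing within a block, 30 kb between blocks
      gaps <- sample(200:1500, m, replace = TRUE)
      gaps[1] <- gaps[1] + 30000
      pos[cols] <- cur_pos + cumsum(gaps)
      cur_pos <- pos[at + m]
      chrom[cols] <- paste0("chr", cur_chrom)

      w <- stats::runif(1, 0.15, 0.5)           # founder-2 mixing weight
      is_common <- stats::runif(m) < config$p_common
      founder2 <- ifelse(is_common, 1L, 0L)     # founders differ at common sites
      orient <- stats::runif(m) < 0.5           # which founder carries alt
      choice <- stats::rbinom(H, 1L, w)         # founder per panel haplotype
      block <- outer(choice, founder2)
      flip_orient <- which(is_common & orient)
      if (length(flip_orient)) {
        block[, flip_orient] <- 1 - block[, flip_orient]
      }
      # mutational noise on common sites
      if (config$mutation_rate > 0 && any(is_common)) {
        cc <- which(is_common)
        noise <- matrix(stats::runif(H * length(cc)) < config$mutation_rate,
                        nrow = H)
        block[, cc] <- abs(block[, cc] - noise)
      }
      # rare arm: independent low-frequency alleles
      rr <- which(!is_common)
      if (length(rr)) {
        e <- stats::runif(length(rr), 0.005, 0.045)
        block[, rr] <- matrix(
          as.integer(stats::runif(H * length(rr)) < rep(e, each = H)), nrow = H)
      }
      storage.mode(block) <- "integer"
      hap[, cols] <- block
      at <- at + m
    }

    ac <- colSums(hap)
    poly <- ac > 0L & ac < H
    hap <- hap[, poly, drop = FALSE]
    alleles <- c("A", "C", "G", "T")
    ref_i <- sample.int(4L, sum(poly), replace = TRUE)
    alt_i <- 1L + (ref_i + sample.int(3L, sum(poly), replace = TRUE) - 1L) %% 4L
    variants <- data.frame(
      chrom = chrom[poly], pos = pos[poly],
      id = sprintf("rs%05d", which(poly)),
      ref = alleles[ref_i], alt = alleles[alt_i],
      maf = fold_maf(colMeans(hap)),
      stringsAsFactors = FALSE
    )
    new_haplotype_panel(variants, hap,
                        sprintf("PNL%04d", seq_len(config$n_diploids)))
  })
  if (!is.null(vcf_path)) write_panel_vcf(panel, vcf_path)
  if (!is.null(keep_path)) writeLines(panel$sample_ids, keep_path)
  panel
}

#' Generate a synthetic gene annotation and gene-set collection
#'
#' Tiles `n_genes` non-overlapping gene intervals over the panel variants so
#' that every gene contains at least one variant (each gene covers roughly
#' the first 70% of its variant chunk, leaving intergenic gaps that exercise
#' nearest-gene distance logic), then draws `n_sets` gene sets. Three
#' calibrated sets named `SET_SMALL`, `SET_MEDIUM` and `SET_BIG` with
#' exactly 17, 69 and 199 genes are always included; remaining set sizes are
#' drawn from `genes_per_set`.
#'
#' @param config a `fixture_config`.
#' @param panel a `haplotype_panel` produced by [make_panel()].
#' @param bed_path optional path for a 6-column BED file of the genes.
#' @param gmt_path optional path for the gene sets in GMT format.
#' @return A list with elements `genes` (data.frame: gene_id, chrom, start,
#'   end, strand; 1-based inclusive coordinates) and `sets` (named list of
#'   gene-id vectors).
#' @export
make_annotation <- function(config, panel, bed_path = NULL, gmt_path = NULL) {
  stopifnot(inherits(config, "fixture_config"), inherits(panel, "haplotype_panel"))
  v <- panel$variants
  if (config$n_genes > nrow(v)) {
    stop("n_genes exceeds the number of panel variants to tile over", call. = FALSE)
  }
  calibrated <- c(SET_SMALL = 17L, SET_MEDIUM = 69L, SET_BIG = 199L)
  if (config$n_genes < max(calibrated)) {
    stop("n_genes must be >= 199 so the calibrated big set can be drawn",
         call. = FALSE)
  }
  out <- with_seed_if(config$seed + 1L, {
    lev <- chrom_levels(v$chrom)
    n_by_chrom <- table(factor(v$chrom, levels = lev))
    genes_by_chrom <- pmax(1L, round(config$n_genes * as.numeric(n_by_chrom) /
                                       nrow(v)))
    # adjust rounding drift on the largest chromosome
    genes_by_chrom[which.max(genes_by_chrom)] <-
      genes_by_chrom[which.max(genes_by_chrom)] +
      (config$n_genes - sum(genes_by_chrom))
    rows <- list()
    g <- 0L
    for (ci in seq_along(lev)) {
      p <- v$pos[v$chrom == lev[ci]]
      ng <- genes_by_chrom[ci]
      chunk <- cut(seq_along(p), breaks = ng, labels = FALSE)
      for (j in seq_len(ng)) {
        g <- g + 1L
        pp <- p[chunk == j]
        upto <- max(1L, ceiling(0.7 * length(pp)))
        rows[[g]] <- data.frame(
          gene_id = sprintf("G%04d", g), chrom = lev[ci],
          start = pp[1], end = pp[upto],
          strand = if (g %% 2L) "+" else "-",
          stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, rows)
    all_ids <- genes$gene_id
    sets <- list()
    for (i in seq_along(calibrated)) {
      sets[[names(calibrated)[i]]] <- sample(all_ids, calibrated[i])
    }
    n_extra <- max(0L, config$n_sets - length(calibrated))
    if (n_extra > 0) {
      sizes <- sample(seq(config$genes_per_set[1],
                          min(config$genes_per_set[2], length(all_ids))),
                      n_extra, replace = TRUE)
      for (i in seq_len(n_extra)) {
        sets[[sprintf("SET_%02d", i)]] <- sample(all_ids, sizes[i])
      }
    }
    list(genes = genes, sets = sets)
  })
  if (!is.null(bed_path)) {
    bed <- data.frame(out$genes$chrom, out$genes$start - 1L, out$genes$end,
                      out$genes$gene_id, 0L, out$genes$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(gmt_path)) {
    lines <- vapply(names(out$sets), function(nm) {
      paste(c(nm, "synthetic_gene_set", out$sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, gmt_path)
  }
  out
}
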