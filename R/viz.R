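#' PCA of genotype dosages with LD pruning
#'
#' LD-prunes the variants, drops monomorphic columns, column-standardizes
#' the remaining dosages, and eigendecomposes the sample covariance. The
#' first four components and their explained-variance fractions are
#' returned; `plot_pca()` renders pairwise scatterplots.
#'
#' @param genotypes a `genotype_matrix` (>= 5 samples).
#' @param window,step,r2_max LD-pruning parameters (see [ld_prune()]).
#' @param sample_labels optional grouping label per sample (for plotting).
#' @return An object of class `pca_result`: list with `coordinates`
#'   (N x 4 matrix), `explained_fraction` (length 4), `sample_labels`,
#'   and `n_variants_used`.
#' @export
pca_genotypes <- function(genotypes, window = 50, step = 5, r2_max = 0.2,
                          sample_labels = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(genotypes$dosages) < 5) stop("need at least 5 samples", call. = FALSE)
  kept <- ld_prune(genotypes, window, step, r2_max)
  X <- genotypes$dosages[, match(kept, genotypes$variants$id), drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < 2) {
    stop("fewer than 2 polymorphic variants after pruning", call. = FALSE)
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(4L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 4L) coords <- cbind(coords, matrix(0, nrow(coords), 4L - k))
  colnames(coords) <- paste0("PC", 1:4)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  expl <- c(expl, rep(0, 4))[1:4]
  structure(
    list(coordinates = coords, explained_fraction = expl,
         sample_labels = sample_labels %||% rep("all", nrow(coords)),
         n_variants_used = ncol(X)),
    class = "pca_result")
}

#' @rdname pca_genotypes
#' @param pca a `pca_result`.
#' @param out optional image path (.png or .pdf); when `NULL` the ggplot
#'   object is returned without rendering.
#' @export
plot_pca <- function(pca, out = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  d <- as.data.frame(pca$coordinates)
  d$group <- pca$sample_labels
  lab <- sprintf("PC%d (%.1f%%)", 1:4, 100 * pca$explained_fraction)
  p12 <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                         colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::theme_minimal()
  p34 <- ggplot2::ggplot(d, ggplot2::aes(.data$PC3, .data$PC4,
                                         colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(x = lab[3], y = lab[4], colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    save_plot_grid(list(p12, p34), out)
    return(invisible(out))
  }
  list(p12 = p12, p34 = p34)
}

#' Manhattan plot data and rendering
#'
#' `manhattan_data()` prepares the plotted coordinate table (cumulative
#' genome position, -log10 p, chromosome parity shading, and the highlight
#' class of each variant: `genomewide` for p below `genomewide_p`,
#' `suggestive` for p below `suggestive_p`, `none` otherwise), which is the
#' testable surface; `manhattan_plot()` renders it, annotating clump index
#' variants when a `clump_set` is given, and writes a sidecar TSV of the
#' coordinates next to the image.
#'
#' @param stats a `summary_stats` table.
#' @param suggestive_p suggestive threshold (default 1e-4).
#' @param genomewide_p genome-wide threshold (default 5e-8).
#' @return data.frame with columns `id`, `chrom`, `pos`, `cum_pos`,
#'   `neglog10p`, `shade`, `class`.
#' @export
manhattan_data <- function(stats, suggestive_p = 1e-4, genomewide_p = 5e-8) {
  stopifnot(nrow(stats) >= 1)
  lev <- chrom_levels(stats$chrom)
  offsets <- c(0, cumsum(vapply(lev, function(ch) {
    max(stats$pos[stats$chrom == ch])
  }, numeric(1))))
  ci <- match(stats$chrom, lev)
  data.frame(
    id = stats$id, chrom = stats$chrom, pos = stats$pos,
    cum_pos = stats$pos + offsets[ci],
    neglog10p = -log10(stats$p),
    shade = ci %% 2 == 0,
    class = ifelse(stats$p < genomewide_p, "genomewide",
                   ifelse(stats$p < suggestive_p, "suggestive", "none")),
    stringsAsFactors = FALSE)
}

#' @rdname manhattan_data
#' @param clumpset optional `clump_set` whose index variants are annotated.
#' @param out image path (.png or .pdf).
#' @export
manhattan_plot <- function(stats, clumpset = NULL, suggestive_p = 1e-4,
                           genomewide_p = 5e-8, out = NULL) {
  d <- manhattan_data(stats, suggestive_p, genomewide_p)
  cols <- c(none = "grey60", suggestive = "forestgreen", genomewide = "red")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$cum_pos, .data$neglog10p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class,
                                     alpha = .data$shade), size = 0.8) +
    ggplot2::scale_colour_manual(values = cols, guide = "none") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.5, `FALSE` = 0.9),
                                guide = "none") +
    ggplot2::geom_hline(yintercept = -log10(c(suggestive_p, genomewide_p)),
                        linetype = "dashed", colour = c("forestgreen", "red")) +
    ggplot2::labs(x = "cumulative position (bp)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(clumpset) && nrow(clumpset$clumps) > 0) {
    di <- d[match(clumpset$clumps$index, d$id), , drop = FALSE]
    p <- p + ggplot2::geom_point(data = di, shape = 1, size = 3,
                                 colour = "black")
  }
  if (!is.null(out)) {
    save_plot_grid(list(p), out)
    utils::write.table(d, paste0(out, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  p
}

#' Q-Q plot data and rendering
#'
#' Observed sorted -log10 p-values against the expected -log10 uniform
#' order statistics `i / (M + 1)`; the genomic inflation factor lambda is
#' annotated on the rendered plot.
#'
#' @param stats a `summary_stats` table.
#' @return data.frame with columns `expected`, `observed` (both on the
#'   -log10 scale, ascending).
#' @export
qq_data <- function(stats) {
  stopifnot(nrow(stats) >= 1)
  m <- nrow(stats)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(sort(stats$p)))[m:1, , drop = FALSE]
}

#' @rdname qq_data
#' @param out image path (.png or .pdf).
#' @export
qq_plot <- function(stats, out = NULL) {
  d <- qq_data(stats)
  lam <- genomic_inflation(stats)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::annotate("text", x = 0.5, y = max(d$observed),
                      label = sprintf("lambda == %.3f", lam), parse = TRUE,
                      hjust = 0) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    save_plot_grid(list(p), out)
    utils::write.table(d, paste0(out, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  p
}

# Render one or more ggplots side by side to PNG or PDF.
save_plot_grid <- function(plots, out) {
  ext <- tolower(tools::file_ext(out))
  w <- 6 * length(plots)
  combined <- Reduce(`+`, plots)   # patchwork composition
  tryCatch({
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    if (ext == "pdf") {
      grDevices::pdf(out, width = w, height = 5)
    } else {
      grDevices::png(out, width = 150 * w, height = 750, res = 120)
    }
  }, error = function(e) {
    stop("cannot open graphics device for ", out, ": ",
         conditionMessage(e), call. = FALSE)
  })
  on.exit(grDevices::dev.off(), add = TRUE)
  print(combined)
  invisible(out)
}
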