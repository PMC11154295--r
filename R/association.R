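#' Per-variant linear-regression association scan
#'
#' For each variant, fits the simple linear regression of the trait on
#' dosage (intercept + dosage) and reports the OLS slope, its standard
#' error, the Wald t statistic with N - 2 degrees of freedom, and the
#' two-sided p-value from the t distribution. Monomorphic variants keep
#' their row (so row order matches the genotype matrix) with the
#' convention `beta = 0`, `se = NA`, `p = 1`. The scan is vectorized in
#' column chunks via the closed-form normal equations.
#'
#' @param genotypes a `genotype_matrix`.
#' @param pheno a `phenotype_vector` (sample ids must match the genotypes).
#' @return A `summary_stats` data.frame with columns `chrom`, `pos`, `id`,
#'   `a1` (effect/alternate allele), `beta`, `se`, `stat`, `p`, `n`, and
#'   attribute `trait_type = "quantitative"`.
#' @export
assoc_quantitative <- function(genotypes, pheno) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(pheno, "phenotype_vector"))
  if (!identical(genotypes$sample_ids, pheno$sample_ids)) {
    stop("sample ids of genotypes and phenotype do not match", call. = FALSE)
  }
  y <- pheno$values
  n <- length(y)
  if (n < 3) stop("need at least 3 individuals", call. = FALSE)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  M <- ncol(genotypes$dosages)

  beta <- se <- tt <- pv <- numeric(M)
  chunks <- split(seq_len(M), ceiling(seq_len(M) / 2000))
  for (idx in chunks) {
    X <- genotypes$dosages[, idx, drop = FALSE]
    cs <- colSums(X)
    sxx <- colSums(X * X) - cs^2 / n
    sxy <- drop(crossprod(X, yc))
    mono <- sxx <= 0
    b <- ifelse(mono, 0, sxy / ifelse(mono, 1, sxx))
    sse <- pmax(syy - b^2 * sxx, 0)
    s2 <- sse / (n - 2)
    s <- ifelse(mono, NA_real_, sqrt(s2 / ifelse(mono, 1, sxx)))
    t_ <- ifelse(mono | s == 0, 0, b / s)
    p <- ifelse(mono, 1, 2 * stats::pt(abs(t_), df = n - 2, lower.tail = FALSE))
    beta[idx] <- b; se[idx] <- s; tt[idx] <- t_; pv[idx] <- p
  }
  v <- genotypes$variants
  out <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id, a1 = v$alt,
                    beta = beta, se = se, stat = tt,
                    p = pmin(pmax(pv, .Machine$double.xmin), 1), n = n,
                    stringsAsFactors = FALSE)
  attr(out, "trait_type") <- "quantitative"
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Allelic chi-squared association scan for case/control labels
#'
#' For each variant, the 1-df chi-squared test (no continuity correction)
#' on the 2x2 table of allele counts (case/control x ref/alt). The `beta`
#' column reports the log odds ratio, with the Haldane--Anscombe 0.5
#' correction applied when any cell is zero; `or` carries the odds ratio
#' itself.
#'
#' @param genotypes a `genotype_matrix`.
#' @param labels integer case/control labels (1 = control, 2 = case), named
#'   by sample id in genotype order.
#' @return A `summary_stats` data.frame (adds an `or` column);
#'   attribute `trait_type = "binary"`.
#' @export
assoc_binary <- function(genotypes, labels) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!all(labels %in% c(1L, 2L))) stop("labels must be 1 (control) or 2 (case)",
                                        call. = FALSE)
  if (length(labels) != nrow(genotypes$dosages)) {
    stop("labels must align with genotype rows", call. = FALSE)
  }
  is_case <- labels == 2L
  if (!any(is_case) || all(is_case)) {
    stop("both cases and controls are required", call. = FALSE)
  }
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  dos <- genotypes$dosages
  alt_case <- colSums(dos[is_case, , drop = FALSE])
  alt_ctrl <- colSums(dos[!is_case, , drop = FALSE])
  a <- alt_case; b <- 2 * n_case - alt_case       # case alt / ref
  c_ <- alt_ctrl; d <- 2 * n_ctrl - alt_ctrl      # control alt / ref
  tot <- a + b + c_ + d
  num <- tot * (a * d - b * c_)^2
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chisq <- ifelse(den == 0, 0, num / ifelse(den == 0, 1, den))
  p <- ifelse(den == 0, 1,
              stats::pchisq(chisq, df = 1, lower.tail = FALSE))
  zero_cell <- a == 0 | b == 0 | c_ == 0 | d == 0
  ah <- a + 0.5 * zero_cell; bh <- b + 0.5 * zero_cell
  ch <- c_ + 0.5 * zero_cell; dh <- d + 0.5 * zero_cell
  or <- (ah * dh) / (bh * ch)
  v <- genotypes$variants
  out <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id, a1 = v$alt,
                    beta = log(or), se = sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh),
                    stat = chisq, p = pmin(pmax(p, .Machine$double.xmin), 1),
                    n = length(labels), or = or, stringsAsFactors = FALSE)
  attr(out, "trait_type") <- "binary"
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median observed 1-df chi-squared statistic (recovered from
#' the p-values) divided by the median of the null chi-squared(1)
#' distribution (0.4549364...).
#'
#' @param stats a `summary_stats` table.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(stats) {
  stopifnot(nrow(stats) >= 1)
  obs <- stats::qchisq(stats$p, df = 1, lower.tail = FALSE)
  stats::median(obs) / stats::qchisq(0.5, df = 1)
}

#' Write summary statistics as a tab-separated table
#'
#' Column order is pinned: CHR, SNP, BP, A1, BETA, SE, STAT, P, NMISS
#' (binary traits append OR).
#'
#' @param stats a `summary_stats` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- data.frame(CHR = stats$chrom, SNP = stats$id, BP = stats$pos,
                    A1 = stats$a1, BETA = stats$beta, SE = stats$se,
                    STAT = stats$stat, P = stats$p, NMISS = stats$n)
  if (!is.null(stats$or)) out$OR <- stats$or
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary-statistics table written by [write_sumstats()]
#'
#' @param path path to the TSV.
#' @return A `summary_stats` data.frame.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(tab$CHR), pos = tab$BP,
                    id = as.character(tab$SNP), a1 = tab$A1, beta = tab$BETA,
                    se = tab$SE, stat = tab$STAT, p = tab$P, n = tab$NMISS,
                    stringsAsFactors = FALSE)
  if (!is.null(tab$OR)) {
    out$or <- tab$OR
    attr(out, "trait_type") <- "binary"
  } else {
    attr(out, "trait_type") <- "quantitative"
  }
  class(out) <- c("summary_stats", "data.frame")
  out
}
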