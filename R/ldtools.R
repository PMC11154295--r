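#' Pairwise linkage disequilibrium (r-squared) between two variants
#'
#' The squared Pearson correlation of the two dosage columns (genotypic
#' r-squared, as computed by standard tooling on unphased genotype data).
#'
#' @param genotypes a `genotype_matrix`.
#' @param id_a,id_b variant ids.
#' @return Scalar r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(genotypes, id_a, id_b) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  i <- match(c(id_a, id_b), genotypes$variants$id)
  if (anyNA(i)) stop("variant id not found", call. = FALSE)
  x <- genotypes$dosages[, i[1]]
  y <- genotypes$dosages[, i[2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("LD is undefined for monomorphic variants", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Clumping parameters
#'
#' Thresholds of the greedy clumping algorithm: `p1` for index variants,
#' `p2` for clump members, `r2` for LD with the index, and `kb` for the
#' window half-width. The defaults (1e-4, 1e-2, 0.5, 250) are the standard
#' published clumping defaults; the causal-recovery evaluation path
#' overrides `p1` to genome-wide significance (5e-8) so that clumps mean
#' genome-wide-significant loci.
#'
#' @param p1 index-variant p-value threshold (exclusive: p < p1).
#' @param p2 member p-value threshold (exclusive).
#' @param r2 minimum r-squared with the index (inclusive).
#' @param kb window half-width in kilobases.
#' @return An object of class `clump_params`.
#' @export
clump_params <- function(p1 = 1e-4, p2 = 1e-2, r2 = 0.5, kb = 250) {
  stopifnot(p1 > 0, p1 <= 1, p2 > 0, p2 <= 1, r2 >= 0, r2 <= 1, kb > 0)
  structure(list(p1 = p1, p2 = p2, r2 = r2, kb = kb), class = "clump_params")
}

#' Greedy LD clumping of summary statistics
#'
#' Sorts variants with `p < p1` by ascending p (ties broken by chromosome
#' then position); repeatedly takes the best unassigned variant as a clump
#' index and assigns to it, as members, every still-unassigned variant with
#' `p < p2` on the same chromosome, within `kb` kilobases, and with
#' r-squared at least `r2` to the index. Every variant belongs to at most
#' one clump; inter-chromosomal clumping never occurs.
#'
#' @param stats a `summary_stats` table.
#' @param genotypes the `genotype_matrix` the statistics were computed on
#'   (LD is measured on these dosages).
#' @param params a `clump_params`.
#' @return An object of class `clump_set`: list with `clumps` (data.frame
#'   `index`, `chrom`, `pos`, `p`, `n_members`, `members` where `members`
#'   is a list-column of member id vectors) and `params`.
#' @export
clump <- function(stats, genotypes, params = clump_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(params, "clump_params"))
  si <- match(stats$id, genotypes$variants$id)
  if (anyNA(si)) stop("summary statistics contain variants absent from genotypes",
                      call. = FALSE)
  lev <- chrom_levels(stats$chrom)
  ord_key <- order(stats$p, match(stats$chrom, lev), stats$pos)
  cand <- ord_key[stats$p[ord_key] < params$p1]

  assigned <- rep(FALSE, nrow(stats))
  member_ok <- stats$p < params$p2
  rows <- list()
  members <- list()
  nclump <- 0L
  for (i in cand) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    near <- which(!assigned & member_ok &
                    stats$chrom == stats$chrom[i] &
                    abs(stats$pos - stats$pos[i]) <= params$kb * 1000)
    mem <- character(0)
    if (length(near)) {
      x <- genotypes$dosages[, si[i]]
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      Y <- genotypes$dosages[, si[near], drop = FALSE]
      yc <- sweep(Y, 2, colMeans(Y))
      r2 <- drop(crossprod(yc, xc))^2 / (sxx * colSums(yc^2))
      r2[!is.finite(r2)] <- 0
      take <- near[r2 >= params$r2]
      assigned[take] <- TRUE
      mem <- stats$id[take]
    }
    nclump <- nclump + 1L
    rows[[nclump]] <- data.frame(index = stats$id[i], chrom = stats$chrom[i],
                                 pos = stats$pos[i], p = stats$p[i],
                                 n_members = length(mem),
                                 stringsAsFactors = FALSE)
    members[[nclump]] <- mem
  }
  clumps <- if (nclump) do.call(rbind, rows) else
    data.frame(index = character(0), chrom = character(0), pos = numeric(0),
               p = numeric(0), n_members = integer(0))
  clumps$members <- members
  structure(list(clumps = clumps, params = params), class = "clump_set")
}

#' @export
print.clump_set <- function(x, ...) {
  cat(sprintf("<clump_set> %d clump(s) at p1 < %g, r2 >= %g, %g kb\n",
              nrow(x$clumps), x$params$p1, x$params$r2, x$params$kb))
  invisible(x)
}

#' All variant ids covered by a clump set (indexes and members)
#'
#' @param clumpset a `clump_set`.
#' @return Character vector of variant ids.
#' @export
clumped_ids <- function(clumpset) {
  unique(c(clumpset$clumps$index, unlist(clumpset$clumps$members)))
}

#' Write a clump report (CHR, SNP, BP, P, TOTAL, SP2)
#'
#' @param clumpset a `clump_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clumps <- function(clumpset, path) {
  cl <- clumpset$clumps
  sp2 <- vapply(cl$members, function(m) {
    if (length(m)) paste(m, collapse = ",") else "NONE"
  }, character(1))
  out <- data.frame(CHR = cl$chrom, SNP = cl$index, BP = cl$pos, P = cl$p,
                    TOTAL = cl$n_members, SP2 = sp2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sliding-window LD pruning
#'
#' Within each window of `window` consecutive variants (per chromosome),
#' while any retained pair has r-squared above `r2_max`, the member of the
#' currently worst (highest r-squared) pair with the smaller sample MAF is
#' removed (ties: the later position). The window then slides by `step`
#' variants. Deterministic.
#'
#' @param genotypes a `genotype_matrix`.
#' @param window window size in variants (>= 2).
#' @param step slide in variants (1 <= step <= window).
#' @param r2_max r-squared ceiling above which one of a pair is removed.
#' @return Character vector of retained variant ids (original order).
#' @export
ld_prune <- function(genotypes, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            window >= 2, step >= 1, step <= window)
  v <- genotypes$variants
  maf <- sample_maf(genotypes)
  keep <- rep(TRUE, nrow(v))
  for (ch in chrom_levels(v$chrom)) {
    vi <- which(v$chrom == ch)
    if (length(vi) < 2) next
    starts <- seq(1L, length(vi), by = step)
    for (s in starts) {
      win <- vi[s:min(s + window - 1L, length(vi))]
      win <- win[keep[win]]
      poly <- win[apply(genotypes$dosages[, win, drop = FALSE], 2,
                        function(x) stats::sd(x) > 0)]
      if (length(poly) < 2) next
      repeat {
        C2 <- stats::cor(genotypes$dosages[, poly, drop = FALSE])^2
        diag(C2) <- 0
        worst <- which(C2 == max(C2), arr.ind = TRUE)[1, ]
        if (C2[worst[1], worst[2]] <= r2_max) break
        pair <- poly[worst]
        # drop the smaller-MAF member; tie -> later position
        drop_i <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
          else if (maf[pair[2]] < maf[pair[1]]) pair[2]
          else pair[which.max(v$pos[pair])]
        keep[drop_i] <- FALSE
        poly <- setdiff(poly, drop_i)
        if (length(poly) < 2) break
      }
    }
  }
  v$id[keep]
}
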