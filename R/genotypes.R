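#' Genotype matrix objects
#'
#' A `genotype_matrix` holds an N x M dosage matrix with entries in
#' \{0, 1, 2\} (count of the alternate allele), the matching variant metadata
#' table, and simulated individual labels.
#'
#' @param variants variant metadata data.frame (see [new_haplotype_panel()]).
#' @param dosages integer N x M matrix with entries in \{0, 1, 2\}.
#' @param sample_ids N individual labels.
#' @return An object of class `genotype_matrix`.
#' @keywords internal
new_genotype_matrix <- function(variants, dosages, sample_ids) {
  check_variants(variants)
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants)) {
    stop("dosage columns must align with variant rows", call. = FALSE)
  }
  if (nrow(dosages) != length(sample_ids)) {
    stop("dosage rows must align with sample ids", call. = FALSE)
  }
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in {0, 1, 2}", call. = FALSE)
  rownames(variants) <- NULL
  colnames(dosages) <- variants$id
  structure(
    list(variants = variants, dosages = dosages,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), nrow(x$variants),
              length(chrom_levels(x$variants$chrom))))
  invisible(x)
}

# Sample minor-allele frequencies of a genotype matrix (folded to <= 0.5).
sample_maf <- function(genotypes) fold_maf(colMeans(genotypes$dosages) / 2)

#' Simulate genotypes as haplotype mosaics of a reference panel
#'
#' Each simulated haplotype starts from a uniformly chosen panel haplotype
#' and, between consecutive variants, switches to a new uniformly chosen
#' panel haplotype with probability `switch_rate`; the copying process
#' restarts (a forced switch) at every chromosome boundary. Two independent
#' mosaic haplotypes are summed into a dosage per individual. This preserves
#' local linkage disequilibrium of the panel while generating an arbitrary
#' number of individuals, and matches panel allele frequencies in
#' expectation at every variant.
#'
#' @param panel a `haplotype_panel`.
#' @param n_individuals number of diploid individuals to simulate.
#' @param switch_rate per-variant-interval probability of switching template
#'   haplotype, in `[0, 1]`. Default 0.002.
#' @param seed optional integer seed; the result is bit-identical for a
#'   given seed.
#' @return A `genotype_matrix` with `n_individuals` rows; variant metadata
#'   carries the *sample* MAF of the simulated dosages.
#' @export
simulate_genotypes <- function(panel, n_individuals, switch_rate = 0.002,
                               seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$variants) == 0) stop("empty panel", call. = FALSE)
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  if (switch_rate < 0 || switch_rate > 1) {
    stop("switch_rate must lie in [0, 1]", call. = FALSE)
  }
  P <- panel$haplotypes
  H <- nrow(P)
  M <- ncol(P)
  # forced-switch intervals: the interval preceding each new chromosome
  chrom <- panel$variants$chrom
  forced <- if (M > 1) which(chrom[-1] != chrom[-M]) else integer(0)
  col_off <- (seq_len(M) - 1) * H

  draw_hap <- function() {
    nsw <- stats::rbinom(1L, max(M - 1L, 0L), switch_rate)
    sw <- if (nsw > 0) sort(unique(c(sample.int(M - 1L, nsw), forced))) else forced
    nseg <- length(sw) + 1L
    src <- rep(sample.int(H, nseg, replace = TRUE), times = diff(c(0L, sw, M)))
    P[col_off + src]
  }

  with_seed_if(seed, {
    # fill M x N transpose column-wise (contiguous), transpose once at the end
    tdos <- matrix(0L, nrow = M, ncol = n_individuals)
    for (i in seq_len(n_individuals)) {
      tdos[, i] <- draw_hap() + draw_hap()
    }
  })
  dos <- t(tdos)
  variants <- panel$variants
  variants$maf <- fold_maf(colMeans(dos) / 2)
  new_genotype_matrix(variants, dos,
                      sprintf("SIM%05d", seq_len(n_individuals)))
}

#' Merge per-chromosome genotype matrices
#'
#' Column-binds genotype matrices that share the same individuals but cover
#' disjoint chromosome sets (the per-chromosome processing path), then
#' re-sorts variants by chromosome and position. Chromosome order in the
#' merged matrix is canonical (numeric-aware label sort), so the result does
#' not depend on the order in which parts are supplied.
#'
#' @param parts list of `genotype_matrix` objects.
#' @return A single merged `genotype_matrix`.
#' @export
merge_genotypes <- function(parts) {
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, TRUE, "genotype_matrix")))
  if (length(parts) == 1) return(parts[[1]])
  ids <- parts[[1]]$sample_ids
  for (p in parts[-1]) {
    if (!identical(p$sample_ids, ids)) {
      stop("sample ids differ between parts", call. = FALSE)
    }
  }
  chrom_sets <- lapply(parts, function(p) chrom_levels(p$variants$chrom))
  all_chrom <- unlist(chrom_sets)
  if (anyDuplicated(all_chrom)) {
    stop("parts must cover disjoint chromosome sets", call. = FALSE)
  }
  var_ids <- unlist(lapply(parts, function(p) p$variants$id))
  if (anyDuplicated(var_ids)) {
    stop("duplicate variant id across parts: ",
         paste(utils::head(unique(var_ids[duplicated(var_ids)]), 5),
               collapse = ", "), call. = FALSE)
  }
  variants <- do.call(rbind, lapply(parts, function(p) p$variants))
  dosages <- do.call(cbind, lapply(parts, function(p) p$dosages))
  # canonical chromosome order: numeric-aware, input-order independent
  lab <- chrom_levels(variants$chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", lab)))
  lev <- lab[order(is.na(num), num, lab)]
  ord <- order(match(variants$chrom, lev), variants$pos)
  new_genotype_matrix(variants[ord, , drop = FALSE],
                      dosages[, ord, drop = FALSE], ids)
}

#' Write simulated genotypes to disk
#'
#' `write_genotypes_vcf()` writes an unphased VCF (dosage 0/1/2 rendered as
#' `0/0`, `0/1`, `1/1`). `write_dosage_matrix()` writes a tab-separated
#' N x M dosage table (rows = individuals) plus a `<path>.variants.tsv`
#' sidecar with columns CHROM, POS, ID, REF, ALT, MAF.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(codes[t(genotypes$dosages) + 1L], nrow = nrow(v))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom_levels(v$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  )
  body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), v$id,
                v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
write_dosage_matrix <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- as.data.frame(genotypes$dosages)
  dos <- cbind(IID = genotypes$sample_ids, dos)
  utils::write.table(dos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- genotypes$variants
  side <- data.frame(CHROM = v$chrom, POS = v$pos, ID = v$id, REF = v$ref,
                     ALT = v$alt, MAF = v$maf)
  utils::write.table(side, paste0(path, ".variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a subset of variants as a new genotype matrix
#'
#' @param genotypes a `genotype_matrix`.
#' @param ids variant ids to keep, in the requested order.
#' @return A `genotype_matrix` with columns in the order of `ids`.
#' @keywords internal
subset_genotypes <- function(genotypes, ids) {
  idx <- match(ids, genotypes$variants$id)
  if (anyNA(idx)) {
    stop("variant id(s) absent from genotypes: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  v <- genotypes$variants[idx, , drop = FALSE]
  rownames(v) <- NULL
  out <- list(variants = v,
              dosages = genotypes$dosages[, idx, drop = FALSE],
              sample_ids = genotypes$sample_ids)
  colnames(out$dosages) <- v$id
  class(out) <- "genotype_matrix"
  out
}

#' Read a dosage matrix written by [write_dosage_matrix()]
#'
#' @param path path to the dosage TSV (its `<path>.variants.tsv` sidecar
#'   must sit next to it).
#' @return A `genotype_matrix`.
#' @export
read_dosage_matrix <- function(path) {
  side_path <- paste0(path, ".variants.tsv")
  if (!file.exists(path)) stop("dosage matrix not found: ", path, call. = FALSE)
  if (!file.exists(side_path)) {
    stop("variant sidecar not found: ", side_path, call. = FALSE)
  }
  dos <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  side <- utils::read.table(side_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  ids <- dos$IID
  dos$IID <- NULL
  variants <- data.frame(chrom = as.character(side$CHROM), pos = side$POS,
                         id = as.character(side$ID), ref = side$REF,
                         alt = side$ALT, maf = side$MAF,
                         stringsAsFactors = FALSE)
  m <- as.matrix(dos)
  storage.mode(m) <- "integer"
  new_genotype_matrix(variants, m, ids)
}
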