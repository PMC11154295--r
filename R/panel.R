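#' Haplotype panel objects
#'
#' A `haplotype_panel` holds a phased reference panel: a variant metadata
#' table (one row per biallelic SNP, sorted by chromosome then position), an
#' H x M binary haplotype matrix (two rows per diploid sample), and the
#' diploid sample identifiers. It is the raw material from which simulated
#' genotypes are resampled.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `maf`.
#' @param haplotypes integer matrix of 0/1 alleles, H rows (haplotypes) by
#'   M columns (variants); rows `2i - 1` and `2i` belong to sample `i`.
#' @param sample_ids character vector of H/2 diploid sample labels.
#' @return An object of class `haplotype_panel`.
#' @keywords internal
new_haplotype_panel <- function(variants, haplotypes, sample_ids) {
  check_variants(variants)
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L) {
    stop("haplotype count must be even (two per diploid sample)", call. = FALSE)
  }
  if (ncol(haplotypes) != nrow(variants)) {
    stop("haplotype columns must align with variant rows", call. = FALSE)
  }
  if (length(sample_ids) * 2L != nrow(haplotypes)) {
    stop("need exactly two haplotypes per sample id", call. = FALSE)
  }
  # enforce (chrom, pos) ordering with strictly increasing positions per chrom
  ord <- order_variants(variants)
  variants <- variants[ord, , drop = FALSE]
  haplotypes <- haplotypes[, ord, drop = FALSE]
  rownames(variants) <- NULL
  same_chrom <- variants$chrom[-1] == variants$chrom[-nrow(variants)]
  if (nrow(variants) > 1 &&
      any(same_chrom & diff(variants$pos) <= 0)) {
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  structure(
    list(variants = variants,
         haplotypes = haplotypes,
         sample_ids = as.character(sample_ids)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes (%d diploids) x %d variants on %d chromosome(s)\n",
              nrow(x$haplotypes), length(x$sample_ids), nrow(x$variants),
              length(chrom_levels(x$variants$chrom))))
  invisible(x)
}

#' Load a phased reference panel from a VCF file
#'
#' Reads phased genotypes (GT fields) from a VCF and returns a
#' [new_haplotype_panel()] object. Only biallelic SNP records in which every
#' sample carries a phased, non-missing genotype are used; all other records
#' (multiallelic, indel, unphased, or missing) are skipped and counted in a
#' message. Minor-allele frequencies are computed from the panel haplotypes.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @return A `haplotype_panel`.
#' @export
load_panel <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no genotype columns", call. = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  phased_ok <- gt %in% c("0|0", "0|1", "1|0", "1|1")
  usable <- snp & (rowSums(matrix(phased_ok, nrow = nrow(gt))) == ncol(gt))
  n_skipped <- sum(!usable)
  if (n_skipped > 0) {
    message(sprintf("load_panel: skipped %d record(s) (multiallelic, indel, unphased or missing GT)",
                    n_skipped))
  }
  if (!any(usable)) stop("no usable phased biallelic SNP records in ", vcf_path,
                         call. = FALSE)

  gt <- gt[usable, , drop = FALSE]
  n_samp <- ncol(gt)
  m <- nrow(gt)
  # haplotypes: rows 2i-1, 2i are the two phased alleles of sample i
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = m)
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = m)
  hap <- matrix(0L, nrow = 2L * n_samp, ncol = m)
  hap[seq(1L, 2L * n_samp, by = 2L), ] <- t(h1)
  hap[seq(2L, 2L * n_samp, by = 2L), ] <- t(h2)

  variants <- data.frame(
    chrom = as.character(fix[usable, "CHROM"]),
    pos = as.numeric(fix[usable, "POS"]),
    id = as.character(fix[usable, "ID"]),
    ref = ref[usable],
    alt = alt[usable],
    stringsAsFactors = FALSE
  )
  no_id <- is.na(variants$id) | variants$id == "."
  if (any(no_id)) {
    variants$id[no_id] <- paste0(variants$chrom[no_id], "_", variants$pos[no_id])
  }
  variants$maf <- fold_maf(colMeans(hap))
  new_haplotype_panel(variants, hap, colnames(gt))
}

#' Filter a haplotype panel by minor-allele frequency and sample list
#'
#' Removes variants with panel MAF below `min_maf` (the threshold is
#' inclusive: variants with `maf >= min_maf` are retained, mirroring the
#' usual interpretation of a `--maf` cutoff). When `keep_ids` is given, only
#' the listed diploid samples are retained and MAF is recomputed on the
#' retained haplotypes before the MAF filter is applied.
#'
#' @param panel a `haplotype_panel`.
#' @param min_maf minimum minor-allele frequency in `[0, 0.5)`.
#' @param keep_ids optional character vector of sample ids to retain.
#' @return The filtered `haplotype_panel`.
#' @export
filter_panel <- function(panel, min_maf = 0, keep_ids = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must lie in [0, 0.5)", call. = FALSE)
  variants <- panel$variants
  hap <- panel$haplotypes
  samples <- panel$sample_ids

  if (!is.null(keep_ids)) {
    keep <- samples %in% keep_ids
    if (!any(keep)) {
      stop("keep_ids shares no samples with the panel", call. = FALSE)
    }
    idx <- which(keep)
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap <- hap[rows, , drop = FALSE]
    samples <- samples[idx]
    variants$maf <- fold_maf(colMeans(hap))
  }
  keep_var <- variants$maf >= min_maf
  new_haplotype_panel(variants[keep_var, , drop = FALSE],
                      hap[, keep_var, drop = FALSE], samples)
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel a `haplotype_panel`.
#' @param path output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  v <- panel$variants
  hap <- panel$haplotypes
  n_samp <- length(panel$sample_ids)
  i1 <- seq(1L, 2L * n_samp, by = 2L)
  # GT strings per variant x sample
  gt <- matrix(paste0(t(hap[i1, , drop = FALSE]), "|",
                      t(hap[i1 + 1L, , drop = FALSE])),
               nrow = nrow(v))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom_levels(v$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), v$id,
                v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
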