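#' Read gene intervals from a GTF or BED file
#'
#' GTF input (`.gtf`/`.gff`/`.gff3`) is parsed with \pkg{rtracklayer}; only
#' records with feature type `gene` and a `gene_id` attribute are used. BED
#' input (0-based half-open, at least 4 columns: chrom, start, end, name,
#' optionally score and strand) is converted to the package's internal
#' 1-based inclusive coordinates on read.
#'
#' @param path annotation file path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gtf", "gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF/GFF requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path)
    meta <- as.data.frame(gr)
    if ("type" %in% names(meta)) {
      meta <- meta[as.character(meta$type) == "gene", , drop = FALSE]
    }
    if (!nrow(meta)) stop("no 'gene' records in ", path, call. = FALSE)
    if (!"gene_id" %in% names(meta)) {
      stop("GTF lacks a gene_id attribute", call. = FALSE)
    }
    genes <- data.frame(
      gene_id = as.character(meta$gene_id),
      chrom = as.character(meta$seqnames),
      start = meta$start, end = meta$end,
      strand = as.character(meta$strand),
      stringsAsFactors = FALSE)
  } else {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4) stop("BED file needs >= 4 columns", call. = FALSE)
    genes <- data.frame(
      gene_id = as.character(bed[[4]]),
      chrom = as.character(bed[[1]]),
      start = bed[[2]] + 1L,             # 0-based half-open -> 1-based inclusive
      end = bed[[3]],
      strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+",
      stringsAsFactors = FALSE)
  }
  if (any(genes$start > genes$end)) {
    stop("gene interval with start > end in ", path, call. = FALSE)
  }
  genes
}

#' Map each variant to its nearest gene
#'
#' Distance is 0 for a variant lying inside a gene interval, otherwise the
#' base-pair gap to the nearer interval boundary (strand is ignored). Ties
#' are broken deterministically: the gene with the smaller start coordinate
#' wins, then the lexicographically smaller `gene_id`. Variants on a
#' chromosome without genes are flagged unmapped (`NA` gene, logged).
#'
#' @param variants variant metadata data.frame (columns `chrom`, `pos`, `id`).
#' @param genes gene interval data.frame as from [read_gene_intervals()].
#' @return data.frame `id`, `gene_id`, `distance` aligned with `variants`.
#' @export
nearest_gene <- function(variants, genes) {
  stopifnot(all(c("chrom", "pos", "id") %in% names(variants)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  out <- data.frame(id = variants$id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  n_unmapped <- 0L
  for (ch in chrom_levels(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) {
      n_unmapped <- n_unmapped + length(vi)
      next
    }
    # deterministic tie-break: order genes by (start, gene_id); the first
    # minimum along that order wins
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    # chunked distance matrix: variants x genes
    for (block in split(vi, ceiling(seq_along(vi) / 5000))) {
      p <- variants$pos[block]
      d <- pmax(outer(g$start, p, function(s, q) s - q),
                outer(g$end, p, function(e, q) q - e), 0)
      best <- max.col(-t(d), ties.method = "first")
      out$gene_id[block] <- g$gene_id[best]
      out$distance[block] <- d[cbind(best, seq_along(p))]
    }
  }
  if (n_unmapped > 0) {
    message(sprintf("nearest_gene: %d variant(s) on chromosomes without genes left unmapped",
                    n_unmapped))
  }
  out
}

#' Causal-candidate pool by sample MAF window
#'
#' Returns the ids of variants whose *sample* minor-allele frequency lies
#' strictly inside `(min_maf, max_maf)`. The bounds are exclusive — the
#' candidate window for causal variants is distinct from (and stricter
#' than) the inclusive panel-level MAF filter of [filter_panel()].
#'
#' @param genotypes a `genotype_matrix`.
#' @param min_maf lower bound (exclusive), default 0.05.
#' @param max_maf upper bound (exclusive), default 0.5.
#' @return Character vector of variant ids.
#' @export
candidate_pool <- function(genotypes, min_maf = 0.05, max_maf = 0.5) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!(min_maf >= 0 && min_maf < max_maf && max_maf <= 0.5)) {
    stop("need 0 <= min_maf < max_maf <= 0.5", call. = FALSE)
  }
  maf <- sample_maf(genotypes)
  keep <- maf > min_maf & maf < max_maf
  if (!any(keep)) {
    qs <- stats::quantile(maf, c(0, 0.25, 0.5, 0.75, 1))
    stop(sprintf(
      "empty causal-candidate pool in MAF window (%g, %g); sample MAF quantiles: %s",
      min_maf, max_maf, paste(sprintf("%.4f", qs), collapse = ", ")),
      call. = FALSE)
  }
  genotypes$variants$id[keep]
}

#' Read a gene-set collection in GMT format
#'
#' Each tab-separated line holds a set name, a description (discarded), and
#' one or more member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene ids per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields (name, description, gene...)",
                 short[1]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  sets
}
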