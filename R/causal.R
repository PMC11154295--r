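#' Causal-variant specifications
#'
#' A `causal_spec` records the K selected causal variants with per-variant
#' provenance: `pathway` (anchored to a gene of the target set through the
#' nearest-gene map), `random` (drawn off-set), or `explicit` (user-listed).
#'
#' @param entries data.frame with columns `id`, `origin`, `gene_id`.
#' @param target_set gene-set name or `NULL`.
#' @keywords internal
new_causal_spec <- function(entries, target_set = NULL) {
  stopifnot(all(c("id", "origin", "gene_id") %in% names(entries)),
            all(entries$origin %in% c("pathway", "random", "explicit")))
  if (anyDuplicated(entries$id)) {
    stop("duplicate variant id in causal spec", call. = FALSE)
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, target_set = target_set),
            class = "causal_spec")
}

#' @export
print.causal_spec <- function(x, ...) {
  tab <- table(x$entries$origin)
  cat(sprintf("<causal_spec> %d causal variants (%s)%s\n",
              nrow(x$entries),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              if (is.null(x$target_set)) "" else
                paste0(" anchored to ", x$target_set)))
  invisible(x)
}

#' Select causal variants anchored to a gene set
#'
#' Implements the pathway-anchored sampling design: (a) sample
#' `min(k, n')` genes uniformly without replacement from the `n'` genes of
#' the target set that have at least one candidate-pool variant mapped to
#' them; (b) pick one pool variant uniformly per selected gene; when
#' `n' < k`, assignment continues in round-robin cycles (a fresh uniform
#' gene permutation per cycle) so per-gene causal counts differ by at most
#' one; (c) add `K - k` variants drawn uniformly from pool variants whose
#' nearest gene is *not* in the set. Deterministic for a given seed.
#'
#' @param map nearest-gene map from [nearest_gene()].
#' @param pool candidate variant ids from [candidate_pool()].
#' @param sets named list of gene sets from [read_gmt()].
#' @param set_name name of the target set within `sets`.
#' @param K total number of causal variants.
#' @param k number of causal variants anchored in the target set (`k <= K`).
#' @param seed optional integer seed.
#' @return A `causal_spec` with exactly `k` pathway-origin and `K - k`
#'   random-origin entries.
#' @export
select_from_pathway <- function(map, pool, sets, set_name, K, k, seed = NULL) {
  stopifnot(k >= 0, K >= 1, k <= K, length(pool) >= 1)
  if (!set_name %in% names(sets)) {
    stop("gene set not found: ", set_name, call. = FALSE)
  }
  set_genes <- sets[[set_name]]
  m <- map[match(pool, map$id), , drop = FALSE]
  if (anyNA(m$id)) stop("candidate pool contains variants absent from the nearest-gene map",
                        call. = FALSE)
  in_set <- !is.na(m$gene_id) & m$gene_id %in% set_genes
  on_ids <- m$id[in_set]
  on_genes <- m$gene_id[in_set]
  off_ids <- m$id[!in_set]
  if (length(on_ids) < k) {
    stop(sprintf("only %d pool variant(s) map to genes of '%s'; need k = %d",
                 length(on_ids), set_name, k), call. = FALSE)
  }
  if (length(off_ids) < K - k) {
    stop(sprintf("only %d off-set pool variant(s) available; need K - k = %d",
                 length(off_ids), K - k), call. = FALSE)
  }
  with_seed_if(seed, {
    chosen_id <- character(0)
    chosen_gene <- character(0)
    eligible <- unique(on_genes)
    while (length(chosen_id) < k) {
      for (g in sample(eligible)) {      # fresh uniform permutation per cycle
        if (length(chosen_id) >= k) break
        avail <- on_ids[on_genes == g & !(on_ids %in% chosen_id)]
        if (length(avail)) {
          chosen_id <- c(chosen_id, avail[sample.int(length(avail), 1L)])
          chosen_gene <- c(chosen_gene, g)
        }
      }
    }
    rand_id <- off_ids[sample.int(length(off_ids), K - k)]
  })
  entries <- data.frame(
    id = c(chosen_id, rand_id),
    origin = rep(c("pathway", "random"), c(k, K - k)),
    gene_id = c(chosen_gene, m$gene_id[match(rand_id, m$id)]),
    stringsAsFactors = FALSE)
  new_causal_spec(entries, target_set = set_name)
}

#' Select explicitly listed causal variants
#'
#' Intersects a user-provided variant-id list with the variants present in
#' the genotype data, preserving input order. Absent ids are reported in a
#' warning; an empty intersection is fatal.
#'
#' @param ids character vector of variant ids.
#' @param genotypes a `genotype_matrix`.
#' @return A `causal_spec` with origin `explicit`.
#' @export
select_explicit <- function(ids, genotypes) {
  stopifnot(length(ids) >= 1, inherits(genotypes, "genotype_matrix"))
  ids <- unique(ids)
  present <- ids %in% genotypes$variants$id
  if (!any(present)) {
    stop("none of the provided causal variant ids are present in the genotypes",
         call. = FALSE)
  }
  if (any(!present)) {
    warning("causal variant id(s) absent from genotypes and dropped: ",
            paste(ids[!present], collapse = ", "), call. = FALSE)
  }
  entries <- data.frame(id = ids[present], origin = "explicit",
                        gene_id = NA_character_, stringsAsFactors = FALSE)
  new_causal_spec(entries)
}

#' Extract causal-variant genotypes
#'
#' Projects the genotype matrix onto the causal variants, preserving spec
#' order (columns follow the order of `spec$entries`).
#'
#' @param genotypes a `genotype_matrix`.
#' @param spec a `causal_spec`.
#' @return An N x K `genotype_matrix`.
#' @export
extract_causal_genotypes <- function(genotypes, spec) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(spec, "causal_spec"))
  subset_genotypes(genotypes, spec$entries$id)
}

#' Serialize a causal spec as TSV
#'
#' Columns: ID, ORIGIN, GENE, CHROM, POS, MAF (coordinate and frequency
#' columns are filled from `genotypes` when supplied).
#'
#' @param spec a `causal_spec`.
#' @param path output path.
#' @param genotypes optional `genotype_matrix` for coordinates and MAF.
#' @return `path`, invisibly.
#' @export
write_causal_spec <- function(spec, path, genotypes = NULL) {
  e <- spec$entries
  out <- data.frame(ID = e$id, ORIGIN = e$origin, GENE = e$gene_id,
                    CHROM = NA, POS = NA, MAF = NA)
  if (!is.null(genotypes)) {
    i <- match(e$id, genotypes$variants$id)
    out$CHROM <- genotypes$variants$chrom[i]
    out$POS <- genotypes$variants$pos[i]
    out$MAF <- sample_maf(genotypes)[i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
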