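# Internal helpers shared across modules.

# Fold an allele frequency onto the minor-allele scale [0, 0.5].
fold_maf <- function(freq) pmin(freq, 1 - freq)

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# a NULL seed uses (and advances) the caller's RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Centre and scale a vector to zero mean and unit *sample* variance.
# Zero-variance input is an error unless `allow_zero` (then returns zeros).
standardise_vec <- function(x, allow_zero = FALSE, what = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_zero) return(rep(0, length(x)))
    stop(sprintf("cannot standardise %s: zero variance", what), call. = FALSE)
  }
  (x - mean(x)) / s
}

# Stable chromosome ordering: first appearance in `chrom` wins.
chrom_levels <- function(chrom) unique(as.character(chrom))

# Order variant indices by (chromosome first-appearance, position).
order_variants <- function(variants) {
  lev <- chrom_levels(variants$chrom)
  order(match(variants$chrom, lev), variants$pos)
}

# Validate a variant metadata data.frame (chrom, pos, id, ref, alt, maf).
check_variants <- function(variants) {
  need <- c("chrom", "pos", "id", "ref", "alt", "maf")
  missing <- setdiff(need, names(variants))
  if (length(missing)) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant ids: ",
         paste(utils::head(unique(variants$id[duplicated(variants$id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1", call. = FALSE)
  invisible(variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
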