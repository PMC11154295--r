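# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; nothing is read from disk unless a test writes it first.

# Wrap an arbitrary dosage matrix (entries 0/1/2) as a genotype_matrix.
geno_from_matrix <- function(dos, chrom = NULL, pos = NULL, ids = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  variants <- data.frame(
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% seq(1000, by = 1000, length.out = m),
    id = ids %||% sprintf("v%03d", seq_len(m)),
    ref = "A", alt = "G",
    maf = gwasforge:::fold_maf(colMeans(dos) / 2),
    stringsAsFactors = FALSE)
  gwasforge:::new_genotype_matrix(variants, dos,
                                  sprintf("I%04d", seq_len(nrow(dos))))
}

# Wrap a phenotype vector for association tests.
pheno_from_values <- function(values, ids) {
  structure(list(sample_ids = ids, values = values,
                 components = data.frame(genetic = 0 * values,
                                         noise = values)),
            class = "phenotype_vector")
}

# Small deterministic haplotype panel built directly (no founder structure),
# for brute-force oracles.
tiny_panel <- function(n_diploids = 10, m = 30, seed = 11, n_chrom = 2) {
  withr::with_seed(seed, {
    H <- 2 * n_diploids
    hap <- matrix(rbinom(H * m, 1, runif(m, 0.1, 0.9)[rep(seq_len(m), each = H)]),
                  nrow = H)
    poly <- colSums(hap) > 0 & colSums(hap) < H
    hap <- hap[, poly, drop = FALSE]
    mm <- ncol(hap)
    chrom <- paste0("chr", rep(seq_len(n_chrom), length.out = mm))
    chrom <- sort(chrom)
    pos <- unlist(lapply(split(seq_len(mm), chrom), function(i) {
      seq(500, by = 700, length.out = length(i))
    }), use.names = FALSE)
    variants <- data.frame(chrom = chrom, pos = pos,
                           id = sprintf("t%03d", seq_len(mm)),
                           ref = "A", alt = "C",
                           maf = gwasforge:::fold_maf(colMeans(hap)),
                           stringsAsFactors = FALSE)
    gwasforge:::new_haplotype_panel(variants, hap,
                                    sprintf("P%03d", seq_len(n_diploids)))
  })
}

# Small block-structured fixture shared by LD-dependent tests.
small_fixture <- function(seed = 5) {
  cfg <- fixture_config(n_diploids = 50, n_snps = 1200, n_blocks = 30,
                        n_chrom = 2, n_genes = 210, n_sets = 5,
                        genes_per_set = c(5, 20), seed = seed)
  panel <- make_panel(cfg)
  ann <- make_annotation(cfg, panel)
  list(cfg = cfg, panel = panel, ann = ann)
}

# Hand-written 4-sample, 4-record VCF: 3 phased biallelic SNPs plus one
# unphased record that load_panel must skip.
write_toy_vcf <- function(path, unphased_record = TRUE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:4)), collapse = "\t"),
    "chr1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0|0\t0|1\t1|0\t1|1",
    "chr1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0|1\t0|0\t0|0\t0|1",
    "chr1\t300\trsC\tG\tA\t.\tPASS\t.\tGT\t1|1\t0|1\t0|0\t0|0")
  if (unphased_record) {
    lines <- c(lines, "chr1\t400\trsD\tT\tC\t.\tPASS\t.\tGT\t0/1\t0|0\t0|0\t0|0")
  }
  writeLines(lines, path)
  path
}
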