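test_that("load_panel ingests phased biallelic SNPs and skips unphased records", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, unphased_record = TRUE)
  expect_message(panel <- load_panel(vcf), "skipped 1 record")
  expect_s3_class(panel, "haplotype_panel")
  expect_equal(nrow(panel$haplotypes), 8)       # H = 2 x 4 samples
  expect_equal(nrow(panel$variants), 3)         # rsD dropped
  expect_false("rsD" %in% panel$variants$id)
  # rsA alleles: 0|0 0|1 1|0 1|1 -> 4 alt of 8
  expect_equal(panel$variants$maf[panel$variants$id == "rsA"], 0.5)
  # rsB alleles: 0|1 0|0 0|0 0|1 -> 2 alt of 8
  expect_equal(panel$variants$maf[panel$variants$id == "rsB"], 2 / 8)
})

test_that("panel MAF equals brute-force allele counts from the VCF text", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  cfg <- fixture_config(n_diploids = 100, n_snps = 500, n_blocks = 10,
                        seed = 3)
  make_panel(cfg, vcf_path = vcf)
  panel <- load_panel(vcf)
  # brute force: count '1' alleles in the GT fields of the raw text
  body <- grep("^#", readLines(vcf), value = TRUE, invert = TRUE)
  gt_fields <- lapply(strsplit(body, "\t"), function(f) f[-(1:9)])
  counts <- vapply(gt_fields, function(g) {
    sum(unlist(strsplit(g, "|", fixed = TRUE)) == "1")
  }, numeric(1))
  maf_brute <- pmin(counts / 200, 1 - counts / 200)
  expect_equal(panel$variants$maf, maf_brute, tolerance = 1e-12)
})

test_that("filter_panel applies an inclusive MAF cutoff and keep-lists", {
  hap <- cbind(c(rep(1L, 2), rep(0L, 98)),   # maf 0.02
               c(rep(1L, 5), rep(0L, 95)),   # maf 0.05
               c(rep(1L, 30), rep(0L, 70)))  # maf 0.30
  variants <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
                         id = c("lo", "edge", "hi"), ref = "A", alt = "G",
                         maf = colMeans(hap))
  panel <- gwasforge:::new_haplotype_panel(variants, hap,
                                           sprintf("S%02d", 1:50))
  filt <- filter_panel(panel, min_maf = 0.05)
  expect_setequal(filt$variants$id, c("edge", "hi"))   # threshold inclusive

  same <- filter_panel(panel, min_maf = 0, keep_ids = panel$sample_ids)
  expect_identical(same$haplotypes, panel$haplotypes)

  half <- filter_panel(panel, keep_ids = panel$sample_ids[1:25])
  expect_equal(nrow(half$haplotypes), 50)
  brute <- colMeans(panel$haplotypes[1:50, , drop = FALSE])
  expect_equal(half$variants$maf,
               pmin(brute, 1 - brute), tolerance = 1e-12)
  expect_error(filter_panel(panel, keep_ids = c("nobody", "here")),
               "no samples")
})

test_that("mosaic simulation degenerates correctly and respects the panel", {
  # two identical haplotypes -> every dosage row is twice that haplotype
  hap <- rbind(c(1L, 0L, 1L, 0L), c(1L, 0L, 1L, 0L))
  variants <- data.frame(chrom = "chr1", pos = 1:4 * 100,
                         id = paste0("s", 1:4), ref = "A", alt = "G",
                         maf = colMeans(hap))
  panel <- gwasforge:::new_haplotype_panel(variants, hap, "only")
  g <- simulate_genotypes(panel, 5, switch_rate = 0.5, seed = 1)
  expect_equal(unname(g$dosages),
               matrix(rep(c(2L, 0L, 2L, 0L), each = 5), nrow = 5))

  # switch_rate = 0: every simulated haplotype is a panel haplotype verbatim
  panel2 <- tiny_panel(n_diploids = 8, m = 25, seed = 2)
  g2 <- simulate_genotypes(panel2, 40, switch_rate = 0, seed = 3)
  pool <- apply(panel2$haplotypes, 1, paste, collapse = "")
  # recover the two haplotypes per individual per chromosome is not unique;
  # instead check per chromosome that each dosage row is the sum of two
  # panel haplotypes restricted to that chromosome
  for (ch in unique(panel2$variants$chrom)) {
    cols <- panel2$variants$chrom == ch
    sub_pool <- panel2$haplotypes[, cols, drop = FALSE]
    sums <- outer(seq_len(nrow(sub_pool)), seq_len(nrow(sub_pool)),
                  Vectorize(function(i, j) {
                    paste(sub_pool[i, ] + sub_pool[j, ], collapse = "")
                  }))
    observed <- apply(g2$dosages[, cols, drop = FALSE], 1, paste, collapse = "")
    expect_true(all(observed %in% sums))
  }
})

test_that("simulated allele frequencies concentrate around panel frequencies", {
  panel <- make_panel(fixture_config(n_diploids = 60, n_snps = 400,
                                     n_blocks = 10, seed = 8))
  g <- simulate_genotypes(panel, 10000, seed = 9)
  p_panel <- colMeans(panel$haplotypes)
  p_sim <- colMeans(g$dosages) / 2
  se <- sqrt(p_panel * (1 - p_panel) / (2 * 10000))
  within3 <- abs(p_sim - p_panel) <= 3 * se
  expect_gte(mean(within3), 0.99)
})

test_that("same seed gives bit-identical genotypes; switch rate decays LD", {
  panel <- make_panel(fixture_config(n_diploids = 40, n_snps = 300,
                                     n_blocks = 15, n_chrom = 1, seed = 4))
  a <- simulate_genotypes(panel, 50, seed = 123)
  b <- simulate_genotypes(panel, 50, seed = 123)
  expect_identical(a$dosages, b$dosages)

  adj_r2 <- function(g) {
    d <- g$dosages
    sds <- apply(d, 2, sd)
    keep <- which(sds[-1] > 0 & sds[-length(sds)] > 0)
    mean(vapply(keep, function(j) cor(d[, j], d[, j + 1])^2, numeric(1)))
  }
  r2s <- vapply(c(0, 0.05, 0.5), function(sr) {
    adj_r2(simulate_genotypes(panel, 3000, switch_rate = sr, seed = 77))
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))   # r2 strictly decreasing in switch rate
})

test_that("merge_genotypes concatenates chromosomes order-independently", {
  g1 <- geno_from_matrix(matrix(rbinom(20 * 5, 2, 0.3), 20),
                         chrom = rep("chr1", 5))
  g2 <- geno_from_matrix(matrix(rbinom(20 * 7, 2, 0.3), 20),
                         chrom = rep("chr2", 7),
                         ids = sprintf("w%03d", 1:7))
  fwd <- merge_genotypes(list(g1, g2))
  expect_equal(nrow(fwd$variants), 12)
  expect_equal(chrom_levels <- unique(fwd$variants$chrom), c("chr1", "chr2"))
  rev_ <- merge_genotypes(list(g2, g1))
  expect_identical(fwd$dosages, rev_$dosages)
  expect_identical(fwd$variants, rev_$variants)

  dup <- geno_from_matrix(matrix(rbinom(20 * 2, 2, 0.3), 20),
                          chrom = rep("chr3", 2), ids = c("v001", "x2"))
  expect_error(merge_genotypes(list(g1, dup)), "duplicate variant id")
  bad_samples <- geno_from_matrix(matrix(rbinom(19 * 2, 2, 0.3), 19),
                                  chrom = rep("chr4", 2),
                                  ids = c("y1", "y2"))
  expect_error(merge_genotypes(list(g1, bad_samples)), "sample ids differ")
})

test_that("genotype writers round-trip through their readers", {
  g <- geno_from_matrix(matrix(rbinom(15 * 8, 2, 0.4), 15))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_matrix(g, tsv)
  back <- read_dosage_matrix(tsv)
  expect_equal(back$dosages, g$dosages, ignore_attr = TRUE)
  expect_equal(back$variants$id, g$variants$id)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, vcf)
  lines <- readLines(vcf)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  expect_length(body, 8)
  gt1 <- strsplit(body[1], "\t")[[1]][-(1:9)]
  expect_equal(match(gt1, c("0/0", "0/1", "1/1")) - 1L,
               unname(g$dosages[, 1]))
})
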