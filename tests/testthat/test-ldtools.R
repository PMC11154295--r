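test_that("ld_r2 is squared Pearson correlation and sign-invariant", {
  g <- geno_from_matrix(cbind(c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 1),
                              c(2, 2, 2, 2)),
                        ids = c("a", "b", "a2", "mono"))
  expect_equal(ld_r2(g, "a", "a2"), 1)
  expect_equal(ld_r2(g, "a", "b"), 1)     # perfect negative correlation
  expect_error(ld_r2(g, "a", "mono"), "monomorphic")

  withr::with_seed(61, dos <- matrix(rbinom(50 * 2, 2, 0.4), nrow = 50))
  g2 <- geno_from_matrix(dos, ids = c("x", "y"))
  x <- dos[, 1]; y <- dos[, 2]
  brute <- (sum((x - mean(x)) * (y - mean(y))) /
              sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(ld_r2(g2, "x", "y"), brute, tolerance = 1e-12)
})

# Construct a 5-SNP toy where SNP2 is in high LD with SNP1 within the window
# and SNP4 is independent; hand-traced greedy expectation:
# clumps = {SNP1: members SNP2}, {SNP4: members none}.
toy_clump_data <- function() {
  withr::with_seed(62, {
    n <- 400
    base <- rbinom(n, 1, 0.5) + rbinom(n, 1, 0.5)
    flip <- rbinom(n, 1, 0.05)
    snp2 <- ifelse(flip == 1, 2 - base, base)     # r2 ~ 0.8 with snp1
    dos <- cbind(base, snp2,
                 rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rbinom(n, 2, 0.3))
  })
  g <- geno_from_matrix(dos, pos = c(1e5, 1.5e5, 2e5, 6e5, 9e5),
                        ids = paste0("SNP", 1:5))
  stats <- data.frame(chrom = "chr1", pos = g$variants$pos,
                      id = g$variants$id,
                      p = c(1e-10, 1e-9, 0.2, 1e-6, 0.5))
  list(g = g, stats = stats)
}

test_that("clump reproduces the hand-traced greedy execution", {
  toy <- toy_clump_data()
  stopifnot(ld_r2(toy$g, "SNP1", "SNP2") >= 0.5)
  cs <- clump(toy$stats, toy$g, clump_params(p1 = 1e-4, p2 = 1e-2,
                                             r2 = 0.5, kb = 250))
  expect_equal(cs$clumps$index, c("SNP1", "SNP4"))
  expect_identical(cs$clumps$members[[1]], "SNP2")
  expect_identical(cs$clumps$members[[2]], character(0))

  # no index candidates -> empty clump set
  none <- toy$stats; none$p <- pmax(none$p, 0.5)
  expect_equal(nrow(clump(none, toy$g, clump_params())$clumps), 0)
})

test_that("perfect mutual LD within one window collapses to a single clump", {
  base <- rep(c(0L, 1L, 2L, 1L), 50)
  dos <- cbind(base, base, base, 2L - base)
  g <- geno_from_matrix(dos, pos = c(1000, 2000, 3000, 4000),
                        ids = paste0("s", 1:4))
  stats <- data.frame(chrom = "chr1", pos = g$variants$pos,
                      id = g$variants$id, p = c(1e-9, 1e-8, 5e-3, 1e-7))
  cs <- clump(stats, g, clump_params(p1 = 1e-4, p2 = 1e-2, r2 = 0.5, kb = 250))
  expect_equal(nrow(cs$clumps), 1)
  expect_equal(cs$clumps$index, "s1")
  expect_setequal(cs$clumps$members[[1]], c("s2", "s3", "s4"))
})

test_that("clump output partitions variants and replays greedily", {
  fix <- small_fixture(seed = 63)
  g <- simulate_genotypes(fix$panel, 800, seed = 64)
  pool <- candidate_pool(g)
  spec <- select_explicit(sample(pool, 6), g)
  ph <- simulate_quantitative(extract_causal_genotypes(g, spec),
                              draw_effects(6, seed = 65),
                              phenotype_params(h2 = 0.3), seed = 66)
  st <- assoc_quantitative(g, ph)
  params <- clump_params(p1 = 1e-4)
  cs <- clump(st, g, params)
  cl <- cs$clumps
  all_assigned <- c(cl$index, unlist(cl$members))
  expect_false(anyDuplicated(all_assigned) > 0)   # at most one clump each
  expect_true(all(cl$p < params$p1))
  # replay audit: each index is the minimum-p unassigned variant at its step
  assigned <- character(0)
  cand <- st[st$p < params$p1, ]
  cand <- cand[order(cand$p, cand$chrom, cand$pos), ]
  for (i in seq_len(nrow(cl))) {
    remaining <- cand$id[!(cand$id %in% assigned)]
    expect_identical(cl$index[i], remaining[1])
    assigned <- c(assigned, cl$index[i], cl$members[[i]])
  }
  # member constraints: window, chromosome, r2
  for (i in seq_len(nrow(cl))) {
    for (m in cl$members[[i]]) {
      mi <- match(m, st$id)
      expect_identical(st$chrom[mi], cl$chrom[i])
      expect_lte(abs(st$pos[mi] - cl$pos[i]), params$kb * 1000)
      expect_gte(ld_r2(g, m, cl$index[i]), params$r2)
      expect_lt(st$p[mi], params$p2)
    }
  }
  # raising p1 never decreases the clump count
  looser <- clump(st, g, clump_params(p1 = 1e-2))
  expect_gte(nrow(looser$clumps), nrow(cl))
})

test_that("ld_prune removes duplicates and leaves independent sets alone", {
  base <- rep(c(0L, 1L, 2L, 0L, 2L), 30)
  g_dup <- geno_from_matrix(cbind(base, base), ids = c("d1", "d2"))
  expect_length(ld_prune(g_dup, window = 2, step = 1, r2_max = 0.8), 1)

  withr::with_seed(67, ind <- matrix(rbinom(200 * 10, 2, 0.4), nrow = 200))
  g_ind <- geno_from_matrix(ind)
  expect_length(ld_prune(g_ind, window = 10, step = 2, r2_max = 0.95), 10)
})

test_that("ld_prune post-condition holds: no surviving in-window pair above r2_max", {
  fix <- small_fixture(seed = 68)
  g <- simulate_genotypes(fix$panel, 300, seed = 69)
  sub_ids <- g$variants$id[g$variants$chrom == "chr1"][1:100]
  g100 <- gwasforge:::subset_genotypes(g, sub_ids)
  kept <- ld_prune(g100, window = 50, step = 5, r2_max = 0.2)
  expect_lt(length(kept), 100)
  kept_idx <- match(kept, g100$variants$id)
  for (a in seq_along(kept_idx)) {
    for (b in seq_len(a - 1)) {
      # pairs this close in index order are guaranteed to share a window
      # (window 50, step 5)
      if (kept_idx[a] - kept_idx[b] <= 45) {
        xa <- g100$dosages[, kept_idx[a]]
        xb <- g100$dosages[, kept_idx[b]]
        if (sd(xa) > 0 && sd(xb) > 0) {
          expect_lte(cor(xa, xb)^2, 0.2 + 1e-12)
        }
      }
    }
  }
})
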