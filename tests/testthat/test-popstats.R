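two_pop_assign <- function(nA, nB) {
  pop_assignment(c(sprintf("A%03d", 1:nA), sprintf("B%03d", 1:nB)),
                 rep(c("A", "B"), c(nA, nB)))
}

test_that("Weir-Cockerham Fst is one on fixed differences and near zero without", {
  nA <- 20; nB <- 20
  g <- cbind(matrix(0L, 50, nA), matrix(1L, 50, nB))
  colnames(g) <- names(two_pop_assign(nA, nB))
  v <- toy_variants(g)
  expect_equal(wc_fst_global(v, two_pop_assign(nA, nB), "A", "B"), 1)
  sim <- simulate_island_sites(40, 40, 10000, fst = 0, seed = 17)
  f0 <- wc_fst_global(sim$variants, sim$pops, "A", "B")
  expect_lt(abs(f0), 0.01)
})

test_that("windows honour the strict segregating-site threshold", {
  mk <- function(nsites) {
    set.seed(3)
    g <- matrix(rbinom(nsites * 20, 1, 0.5), nsites, 20)
    colnames(g) <- names(two_pop_assign(10, 10))
    toy_variants(g, pos = seq_len(nsites) * 100L)
  }
  pops <- two_pop_assign(10, 10)
  w30 <- wc_fst_windows(mk(30), pops, "A", "B", window_bp = 1e6,
                        step_bp = 1e6, min_seg = 30)
  expect_true(is.na(w30$fst[1]))
  w31 <- wc_fst_windows(mk(31), pops, "A", "B", window_bp = 1e6,
                        step_bp = 1e6, min_seg = 30)
  expect_false(is.na(w31$fst[1]))
  expect_equal(w31$n_sites[1], 31)
})

test_that("Fst rises monotonically with planted differentiation", {
  fs <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  est <- vapply(seq_along(fs), function(i) {
    sim <- simulate_island_sites(30, 30, 3000, fst = fs[i], seed = 100 + i)
    wc_fst_global(sim$variants, sim$pops, "A", "B")
  }, 0)
  expect_true(all(diff(est) > 0))
  expect_gt(cor(est, fs, method = "spearman"), 0.9)
  expect_true(all(est > -0.01 & est <= 1))
})

test_that("population-specific SNP classification follows the draws", {
  nA <- 55; nB <- 55
  pops <- two_pop_assign(nA, nB)
  set.seed(11)
  g <- matrix(0L, 3, nA + nB, dimnames = list(NULL, names(pops)))
  g[1, 1:30] <- 1L                      # polymorphic only in A, common
  g[2, 1] <- 1L                         # polymorphic only in A, rare
  g[3, c(1:40, nA + (1:40))] <- 1L      # polymorphic in both
  v <- toy_variants(g)
  res <- pop_specific_snps(v, pops, sample_n = 50, reps = 10, seed = 19)
  a <- res$per_replicate[res$per_replicate$pop == "A", ]
  # site 3 never counts; site 1 counts for A in every replicate
  expect_true(all(a$rare + a$common <= 2))
  expect_true(all(a$common >= 1))
  b <- res$per_replicate[res$per_replicate$pop == "B", ]
  expect_true(all(b$rare + b$common == 0))
  # MAF exactly at the split classifies as rare: 1 of 20 drawn lines
  pops20 <- two_pop_assign(20, 20)
  g2 <- matrix(0L, 1, 40, dimnames = list(NULL, names(pops20)))
  g2[1, 1] <- 1L
  res2 <- pop_specific_snps(toy_variants(g2), pops20, sample_n = 20,
                            reps = 3, seed = 23)
  a2 <- res2$per_replicate[res2$per_replicate$pop == "A", ]
  expect_true(all(a2$rare == 1))        # MAF = 0.05 exactly -> rare
  expect_true(all(a2$common == 0))
  expect_error(pop_specific_snps(v, pops, sample_n = 100, seed = 1),
               "sample_n")
})

test_that("adjacent r2 matches planted correlation structure", {
  set.seed(29)
  x <- rbinom(200, 1, 0.5)
  g <- cbind(x, x, rbinom(200, 1, 0.5))
  colnames(g) <- sprintf("s%03d", 1:3)
  v <- toy_variants(t(g))
  expect_error(ld_r2_adjacent(subset_variants(v, c(2, 1, 3)), k = 2), "sorted")
  pairs <- ld_r2_adjacent(v, k = 2)
  expect_equal(pairs$r2[pairs$pos1 == 1000 & pairs$pos2 == 2000], 1)
  # independent SNPs: mean r2 near 1/n
  set.seed(31)
  gi <- matrix(rbinom(300 * 200, 1, 0.5), 300, 200,
               dimnames = list(NULL, sprintf("s%03d", 1:200)))
  p2 <- ld_r2_adjacent(toy_variants(gi), k = 3)
  expect_equal(mean(p2$r2), 1 / 200, tolerance = 0.35)
  # k larger than remaining SNPs truncates silently
  p3 <- ld_r2_adjacent(v, k = 50)
  expect_equal(nrow(p3), 3L)
})

test_that("LD decay distance inverts a planted exponential curve", {
  d <- rep(seq(5, 600, by = 5), each = 4)
  pairs <- data.frame(chrom = "chr1", pos1 = 1L, pos2 = 1L + d,
                      distance_bp = d, r2 = exp(-d / 100))
  res <- ld_decay_distance(pairs, r2_cut = 0.1, dist_bin_bp = 50)
  expect_false(res$censored)
  expect_equal(res$decay_bp, 100 * log(10), tolerance = 0.2)
  # all-high r2 is right-censored
  res1 <- ld_decay_distance(transform(pairs, r2 = 1), r2_cut = 0.1)
  expect_true(res1$censored)
  expect_true(is.na(res1$decay_bp))
  # degenerate cutoff 1.0 returns the first bin
  res2 <- ld_decay_distance(pairs, r2_cut = 1.0, dist_bin_bp = 50)
  expect_equal(res2$decay_bp, mean(d[d < 50]))
  expect_error(ld_decay_distance(pairs[0, ]), "empty")
  expect_true(all(c("q25", "median", "q75") %in% names(res$r2_bins)))
})

test_that("LD pruning respects the window and threshold", {
  set.seed(37)
  x <- rbinom(100, 1, 0.5)
  y <- rbinom(100, 1, 0.5)
  g <- rbind(x, x, y)
  colnames(g) <- sprintf("s%03d", 1:100)
  # perfect copies 1 kb apart: second removed
  v <- variant_set(rep("chr1", 3), c(1000L, 2000L, 3000L), g)
  pv <- ld_prune(v, r2_thresh = 0.2, window_bp = 5e5)
  expect_equal(pv$pos, c(1000L, 3000L))
  # same copies 600 kb apart: both kept
  v2 <- variant_set(rep("chr1", 2), c(1000L, 601000L), rbind(x, x))
  expect_equal(ld_prune(v2)$pos, c(1000L, 601000L))
  # independent SNPs: identity
  g3 <- matrix(rbinom(5 * 100, 1, 0.5), 5, 100,
               dimnames = list(NULL, sprintf("s%03d", 1:100)))
  v3 <- toy_variants(g3)
  expect_equal(ld_prune(v3)$pos, v3$pos)
})

test_that("kinship filtering removes one member of each close pair", {
  set.seed(41)
  base <- rbinom(400, 1, 0.5)
  g <- cbind(dup1 = base, dup2 = base,
             far = rbinom(400, 1, 0.5), far2 = rbinom(400, 1, 0.5))
  v <- variant_set(rep("chr1", 400), seq_len(400) * 100L, g)
  K <- kinship_matrix(v)
  expect_equal(K["dup1", "dup2"], 1)
  expect_true(isSymmetric(K))
  expect_equal(unname(diag(K)), rep(1, 4))
  kept <- kinship_filter(v, threshold = 0.5, seed = 43)
  expect_length(kept, 3L)
  expect_equal(sum(c("dup1", "dup2") %in% kept), 1L)
  # unrelated panel is untouched
  g2 <- matrix(rbinom(400 * 4, 1, 0.5), 400, 4,
               dimnames = list(NULL, paste0("u", 1:4)))
  v2 <- variant_set(rep("chr1", 400), seq_len(400) * 100L, g2)
  expect_length(kinship_filter(v2, seed = 1), 4L)
  # trio of mutual relatives (plus unrelated background so the panel stays
  # polymorphic): removal proceeds until clean, deterministically
  g3 <- cbind(a = base, b = base, c = base,
              u1 = rbinom(400, 1, 0.5), u2 = rbinom(400, 1, 0.5))
  v3 <- variant_set(rep("chr1", 400), seq_len(400) * 100L, g3)
  k1 <- kinship_filter(v3, seed = 47)
  k2 <- kinship_filter(v3, seed = 47)
  expect_identical(k1, k2)
  expect_length(k1, 3L)                 # one survivor of the trio + u1, u2
  expect_equal(sum(c("a", "b", "c") %in% k1), 1L)
})
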