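small_cfg <- function(seed = 301, ...) {
  sim_config(params = scaled_params("split1", nu1 = 1, nu2 = 0.3,
                                    tau = 0.1, M = 1),
             n_snps = 20000, n1 = 20, n2 = 20,
             chrom_lengths = c(chr1 = 60e6, chr2 = 60e6),
             mc_replicates = 5000, seed = seed, ...)
}

test_that("simulated genotypes reproduce the generating spectrum", {
  cfg <- small_cfg()
  sim <- simulate_genotypes(cfg)
  v <- sim$variants
  expect_equal(n_variants(v), cfg$n_snps)
  # spacing guarantee
  for (ch in unique(v$chrom))
    expect_true(all(diff(v$pos[v$chrom == ch]) >= 2000))
  # chi-square goodness of fit of site configurations against the
  # generating multinomial (cells pooled below expectation 5)
  probs <- unclass(sim$expected_sfs)
  probs[is.na(probs)] <- 0
  probs <- probs / sum(probs)
  obs <- table(factor(paste(sim$truth$count_pop1, sim$truth$count_pop2),
                      levels = paste(rep(0:20, 21), rep(0:20, each = 21))))
  exp_cnt <- as.vector(probs) * cfg$n_snps
  big <- exp_cnt >= 5
  o <- c(as.vector(obs)[big], sum(obs[!big]))
  e <- c(exp_cnt[big], sum(exp_cnt[!big]))
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  p <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
  # genotype matrix is consistent with the recorded truth configurations
  expect_equal(rowSums(v$geno[, 1:20]), sim$truth$count_pop1)
  expect_equal(rowSums(v$geno[, 21:40]), sim$truth$count_pop2)
})

test_that("a neutral one-population panel shows the folded neutral shape", {
  cfg <- sim_config(params = scaled_params("neutral"), n_snps = 30000,
                    n1 = 20, n2 = 0, chrom_lengths = c(chr1 = 80e6),
                    mc_replicates = 1e5, seed = 313)
  sim <- simulate_genotypes(cfg)
  cnt <- pmin(sim$truth$count_pop1, 20 - sim$truth$count_pop1)
  obs <- tabulate(cnt, nbins = 10)
  shape <- 1 / (1:10) + 1 / (20 - (1:10))
  shape[10] <- 1 / 10                      # self-conjugate class
  expect_gt(cor(obs, shape), 0.99)
  chis <- sum((obs - shape / sum(shape) * sum(obs))^2 /
                (shape / sum(shape) * sum(obs)))
  expect_gt(pchisq(chis, 9, lower.tail = FALSE), 0.001)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg()
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_genotypes(cfg, out_dir = d1)
  s2 <- simulate_genotypes(cfg, out_dir = d2)
  expect_identical(readLines(s1$vcf_path), readLines(s2$vcf_path))
  m1 <- simulate_map(cfg); m2 <- simulate_map(cfg)
  expect_identical(m1, m2)
  ib1 <- simulate_ibd(cfg, c("a", "b", "c"), m1)
  ib2 <- simulate_ibd(cfg, c("a", "b", "c"), m2)
  expect_identical(ib1, ib2)
  # and the emitted VCF round-trips through the loader
  v <- load_variants(s1$vcf_path)
  expect_equal(n_variants(v), cfg$n_snps)
  expect_equal(v$pos, s1$variants$pos)
  expect_equal(unname(v$geno), unname(s1$variants$geno))
  expect_equal(v$ann, s1$variants$ann)
})

test_that("simulated maps are strictly monotone and exact without jitter", {
  cfg <- small_cfg(map_jitter = 0, cM_per_Mb = 1)
  map <- simulate_map(cfg)
  expect_equal(as.numeric(interpolate_cM(map, "chr1", 5e5)), 0.5)
  cfgj <- small_cfg(map_jitter = 5)
  mj <- simulate_map(cfgj)
  for (ch in unique(mj$chrom)) {
    m <- mj[mj$chrom == ch, ]
    expect_true(all(diff(m$pos_cM) > 0))
    expect_true(all(diff(m$pos_bp) > 0))
  }
})

test_that("IBD generator honours rate, length and hotspot settings", {
  big_map <- genetic_map(data.frame(chrom = "chr1",
                                    pos_bp = seq(0, 1000e6, by = 1e6),
                                    pos_cM = seq(0, 1000, by = 1)))
  # rate 0: empty output
  cfg0 <- small_cfg(ibd_rate = 0)
  expect_equal(nrow(simulate_ibd(cfg0, c("a", "b"), big_map)), 0L)
  # exponential mean within 3 standard errors at ~1e4 segments
  cfg1 <- sim_config(params = scaled_params("neutral"), n_snps = 10,
                     n1 = 2, n2 = 0, chrom_lengths = c(chr1 = 1000e6),
                     ibd_rate = 220, ibd_mean_cM = 5, seed = 331)
  seg <- simulate_ibd(cfg1, sprintf("s%02d", 1:10), big_map)
  expect_gt(nrow(seg), 8000)
  keep <- seg$end_cM < 999              # drop end-truncated tracts
  expect_lt(abs(mean(seg$length_cM[keep]) - 5) /
              (5 / sqrt(sum(keep))), 3.5)
  # enrichment 1: occupancy uniform across windows (chi-square)
  tr <- hotspot_occurrence(seg, big_map, pairs = 45)
  cnt <- tr$count[!tr$partial]
  stat <- sum((cnt - mean(cnt))^2 / mean(cnt))
  expect_gt(pchisq(stat, length(cnt) - 1, lower.tail = FALSE), 0.001)
  # planted hotspot attracts segments
  cfg2 <- sim_config(params = scaled_params("neutral"), n_snps = 10,
                     n1 = 2, n2 = 0, chrom_lengths = c(chr1 = 1000e6),
                     ibd_rate = 40, ibd_mean_cM = 5,
                     hotspots = data.frame(chrom = "chr1", start_cM = 200,
                                           end_cM = 210),
                     hotspot_enrichment = 8, seed = 337)
  seg2 <- simulate_ibd(cfg2, sprintf("s%02d", 1:10), big_map)
  tr2 <- hotspot_occurrence(seg2, big_map, pairs = 45)
  hot <- tr2$count[tr2$start_cM == 200]
  expect_gt(hot, 2 * stats::median(tr2$count))
  # hotspot outside the map errors
  cfg3 <- small_cfg(hotspots = data.frame(chrom = "chr1", start_cM = 1e4,
                                          end_cM = 1e4 + 10))
  expect_error(simulate_ibd(cfg3, c("a", "b"), big_map), "outside the")
})

test_that("repeated detector runs are noisy copies of one truth set", {
  big_map <- genetic_map(data.frame(chrom = "chr1",
                                    pos_bp = seq(0, 100e6, by = 1e6),
                                    pos_cM = seq(0, 100, by = 1)))
  cfg <- sim_config(params = scaled_params("neutral"), n_snps = 10,
                    n1 = 2, n2 = 0, chrom_lengths = c(chr1 = 100e6),
                    ibd_rate = 4, ibd_mean_cM = 5, seed = 347)
  rr <- simulate_ibd_runs(cfg, sprintf("s%02d", 1:8), big_map, n_runs = 5,
                          jitter_cM = 0.2, drop_rate = 0.1)
  expect_length(rr$runs, 5L)
  nseg <- vapply(rr$runs, nrow, 0L)
  expect_true(all(nseg <= nrow(rr$truth)))
  expect_gt(mean(nseg), 0.7 * nrow(rr$truth))
  # endpoints stay within the jitter of the truth: the majority consensus
  # of the runs recovers tracts near the truth tracts
  cons <- consensus_ibd(rr$runs)
  expect_gt(nrow(cons), 0L)
  cons_cm <- ibd_add_cM(cons, big_map)
  truth_mid <- (rr$truth$start_cM + rr$truth$end_cM) / 2
  covered <- vapply(seq_len(nrow(cons_cm)), function(i)
    any(rr$truth$chrom == cons_cm$chrom[i] &
          truth_mid > cons_cm$start_cM[i] - 1 &
          truth_mid < cons_cm$end_cM[i] + 1), TRUE)
  expect_true(all(covered))
  # determinism
  rr2 <- simulate_ibd_runs(cfg, sprintf("s%02d", 1:8), big_map, n_runs = 5,
                           jitter_cM = 0.2, drop_rate = 0.1)
  expect_identical(rr$runs, rr2$runs)
})

test_that("infeasible spacing requests fail loudly", {
  cfg <- sim_config(params = scaled_params("neutral"), n_snps = 10000,
                    n1 = 4, n2 = 0, chrom_lengths = c(chr1 = 1e6),
                    mc_replicates = 200, seed = 1)
  expect_error(simulate_genotypes(cfg), "incompatible with spacing")
})
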