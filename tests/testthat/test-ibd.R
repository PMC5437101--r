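toy_map <- function(cm_per_mb = 1) {
  genetic_map(data.frame(chrom = "chr1",
                         pos_bp = seq(0, 50e6, by = 1e6),
                         pos_cM = seq(0, 50e6, by = 1e6) / 1e6 * cm_per_mb))
}

seg_df <- function(a, b, start_cM, end_cM, chrom = "chr1") {
  data.frame(sampleA = a, sampleB = b, chrom = chrom,
             start_cM = start_cM, end_cM = end_cM)
}

test_that("map interpolation is exact at anchors and monotone between them", {
  map <- genetic_map(data.frame(chrom = "chr1", pos_bp = c(0, 1e6),
                                pos_cM = c(0, 1)))
  mid <- interpolate_cM(map, "chr1", 5e5)
  expect_equal(as.numeric(mid), 0.5)
  expect_false(attr(mid, "extrapolated"))
  expect_equal(as.numeric(interpolate_cM(map, "chr1", c(0, 1e6))), c(0, 1))
  pos <- sort(runif(50, 0, 1e6))
  cm <- as.numeric(interpolate_cM(map, "chr1", pos))
  expect_true(all(diff(cm) >= 0))
  # outside the anchors: terminal-slope extension, flagged
  out <- interpolate_cM(map, "chr1", 2e6)
  expect_equal(as.numeric(out), 2)
  expect_true(attr(out, "extrapolated"))
  expect_error(interpolate_cM(map, "chr9", 1), "unknown chromosome")
  # inverse interpolation round-trips
  expect_equal(interpolate_bp(map, "chr1", 0.25), 2.5e5)
})

test_that("genetic maps reject non-monotone anchors", {
  expect_error(genetic_map(data.frame(chrom = "chr1", pos_bp = c(0, 10, 5),
                                      pos_cM = c(0, 1, 2))), "increasing")
  expect_error(genetic_map(data.frame(chrom = "chr1", pos_bp = 0, pos_cM = 0)),
               ">= 2")
})

test_that("consensus keeps majority-covered bases only", {
  base <- data.frame(sampleA = "x", sampleB = "y", chrom = "chr1",
                     start_bp = 1e6, end_bp = 2e6, score = 1e-9)
  # identical in all 10 runs: unchanged
  c10 <- consensus_ibd(replicate(10, base, simplify = FALSE))
  expect_equal(nrow(c10), 1L)
  expect_equal(c(c10$start_bp, c10$end_bp), c(1e6, 2e6))
  # present in 1 of 10: absent
  empty <- base[0, ]
  c1 <- consensus_ibd(c(list(base), replicate(9, empty, simplify = FALSE)))
  expect_equal(nrow(c1), 0L)
  # half-overlapping segments, each seen in 5 of 10 runs: only their
  # intersection reaches majority coverage (5 + 5 runs)
  left <- transform(base, start_bp = 1e6, end_bp = 3e6)
  right <- transform(base, start_bp = 2e6, end_bp = 4e6)
  runs <- c(replicate(5, left, simplify = FALSE),
            replicate(5, right, simplify = FALSE))
  cc <- consensus_ibd(runs)
  expect_equal(nrow(cc), 1L)
  expect_equal(c(cc$start_bp, cc$end_bp), c(2e6, 3e6))
  # k identical copies act as the identity for any k
  for (k in c(1, 3, 7)) {
    ck <- consensus_ibd(replicate(k, rbind(left, right), simplify = FALSE))
    expect_equal(min(ck$start_bp), 1e6)
    expect_equal(max(ck$end_bp), 4e6)
  }
  expect_error(consensus_ibd(list(base, transform(base, sampleA = "p",
                                                  sampleB = "q"))),
               "different sample sets")
})

test_that("consensus coverage never exceeds any single run (brute force)", {
  set.seed(53)
  mk_run <- function() {
    n <- sample(1:4, 1)
    s <- sort(sample(1:90, n)) * 1e5
    data.frame(sampleA = "x", sampleB = "y", chrom = "chr1",
               start_bp = s, end_bp = s + sample(5:30, n) * 1e5,
               score = 1e-9)
  }
  for (rep in 1:5) {
    runs <- replicate(5, mk_run(), simplify = FALSE)
    cc <- consensus_ibd(runs)
    cons_len <- sum(cc$end_bp - cc$start_bp)
    per_run <- vapply(runs, function(r) {
      ir <- IRanges::reduce(IRanges::IRanges(r$start_bp, r$end_bp - 1))
      sum(IRanges::width(ir))
    }, 0)
    # each consensus base is covered by >= 3 of the 5 runs, so the total
    # consensus length is bounded by the pooled coverage over the threshold
    expect_lte(cons_len, sum(per_run) / 3)
    # brute-force coverage check on a grid: majority inside, minority outside
    grid <- seq(0.5e5, 120e6, by = 1e5)
    covn <- vapply(grid, function(p) sum(vapply(runs, function(r)
      any(r$start_bp <= p & r$end_bp > p), TRUE)), 0)
    inside <- vapply(grid, function(p)
      nrow(cc) > 0 && any(cc$start_bp <= p & cc$end_bp > p), TRUE)
    expect_true(all(covn[inside] >= 3))
    expect_true(all(covn[!inside] < 3))
  }
})

test_that("length filtering and long-tract classification use strict bounds", {
  segs <- ibd_add_cM(data.frame(sampleA = "x", sampleB = "y", chrom = "chr1",
                                start_bp = c(0, 0, 0), score = 1,
                                end_bp = c(0.8e6, 1.0e6, 7.5e6)),
                     toy_map())
  f <- filter_short(segs, 1.0)
  expect_equal(f$end_bp, c(1.0e6, 7.5e6))   # 0.8 cM dropped, exactly 1.0 kept
  expect_equal(nrow(filter_short(segs[0, ], 1)), 0L)
  expect_error(filter_short(data.frame(start_bp = 1)), "cM coordinates")
  cl <- classify_long(ibd_add_cM(data.frame(
    sampleA = "x", sampleB = "y", chrom = "chr1", score = 1,
    start_bp = 0, end_bp = c(7.5e6, 6.9e6, 7.0e6)), toy_map()), 7.0)
  expect_equal(cl$long, c(TRUE, FALSE, FALSE))  # exactly 7.0 is short
})

test_that("pair sharing totals and cross-population means add up", {
  pops <- pop_assignment(c("t1", "t2", "n1"), c("TS", "TS", "NSS"))
  segs <- ibd_add_cM(data.frame(sampleA = c("t1", "t1"), sampleB = c("n1", "n1"),
                                chrom = "chr1", start_bp = c(0, 10e6),
                                end_bp = c(7e6, 13e6), score = 1), toy_map())
  sh <- pair_sharing(segs, pops)
  expect_equal(sh$per_pair$total_cM, 10)
  expect_equal(sh$per_pair$mean_cM, 5)
  cross <- sh$pop_means[sh$pop_means$popA != sh$pop_means$popB, ]
  expect_equal(cross$n_pairs, 2)        # t1-n1 and t2-n1, zero pair included
  expect_equal(cross$mean_total_cM, 5)  # 10 cM over 2 possible pairs
  # doubling the segment list doubles totals exactly
  sh2 <- pair_sharing(rbind(segs, segs), pops)
  expect_equal(sh2$per_pair$total_cM, 20)
  # no segments: all-zero means
  sh0 <- pair_sharing(segs[0, ], pops)
  expect_true(all(sh0$pop_means$mean_total_cM == 0))
})

test_that("hotspot occurrence counts spanning segments per window", {
  map <- toy_map()                       # 50 cM -> windows [0,10), ... [40,50]
  segs <- seg_df("a", "b", 12, 17)
  tr <- hotspot_occurrence(segs, map, pairs = 2)
  expect_equal(nrow(tr), 5L)
  expect_equal(tr$occurrence, c(0, 0.5, 0, 0, 0))
  # a segment spanning two windows counts once in each
  tr2 <- hotspot_occurrence(seg_df("a", "b", 8, 12), map, pairs = 2)
  expect_equal(tr2$count, c(1, 1, 0, 0, 0))
  # no segments: all-zero track; order invariance; additivity
  tr0 <- hotspot_occurrence(segs[0, ], map, pairs = 2)
  expect_true(all(tr0$occurrence == 0))
  many <- rbind(seg_df("a", "b", 2, 4), seg_df("a", "c", 33, 35),
                seg_df("b", "c", 8, 22))
  expect_equal(hotspot_occurrence(many, map, pairs = 3)$count,
               hotspot_occurrence(many[c(3, 1, 2), ], map, pairs = 3)$count)
  expect_equal(hotspot_occurrence(many, map, pairs = 3)$count,
               hotspot_occurrence(many[1:2, ], map, pairs = 3)$count +
                 hotspot_occurrence(many[3, ], map, pairs = 3)$count)
  expect_error(hotspot_occurrence(segs, map, pairs = 0), "pairs")
})

test_that("overlap permutation test behaves at the extremes and under planting", {
  map <- toy_map()
  set.seed(59)
  segs <- do.call(rbind, lapply(1:40, function(i) {
    s <- runif(1, 0, 45); seg_df("a", paste0("b", i), s, s + runif(1, 1, 4))
  }))
  tr <- hotspot_occurrence(segs, map, pairs = 40)
  # regions covering everything: overlap 1, p = 1
  all_r <- data.frame(chrom = "chr1", start = 0, end = 50e6)
  r1 <- overlap_permutation_test(tr, all_r, map, top_q = 0.6, n_perm = 99,
                                 seed = 1)
  expect_equal(r1$overlap_fraction, 1)
  expect_equal(r1$p_value, 1)
  # regions covering nothing: overlap 0, p = 1
  r0 <- overlap_permutation_test(tr, all_r[0, ], map, top_q = 0.6,
                                 n_perm = 99, seed = 1)
  expect_equal(r0$overlap_fraction, 0)
  expect_equal(r0$p_value, 1)
  # planted enrichment: the top windows are constructed inside the regions
  big_map <- genetic_map(data.frame(chrom = "chr1",
                                    pos_bp = seq(0, 200e6, by = 1e6),
                                    pos_cM = seq(0, 200, by = 1)))
  set.seed(67)
  bg <- do.call(rbind, lapply(1:60, function(i) {
    s <- runif(1, 0, 195); seg_df("a", paste0("x", i), s, s + 2)
  }))
  hot <- do.call(rbind, lapply(1:120, function(i) {
    s <- runif(1, 100, 158); seg_df("a", paste0("h", i), s, s + 2)
  }))
  tr2 <- hotspot_occurrence(rbind(bg, hot), big_map, pairs = 200)
  reg <- data.frame(chrom = "chr1", start = 100e6, end = 160e6)
  rp <- overlap_permutation_test(tr2, reg, big_map, top_q = 0.75,
                                 n_perm = 999, seed = 3)
  expect_equal(rp$overlap_fraction, 1)
  expect_lte(rp$p_value, 0.05)
  expect_error(overlap_permutation_test(tr[0, ], reg, map, seed = 1), "empty")
})

test_that("permutation p-values are super-uniform under uniform placement", {
  map <- toy_map()
  reg <- data.frame(chrom = "chr1", start = c(5e6, 30e6), end = c(8e6, 36e6))
  set.seed(61)
  ps <- vapply(1:200, function(b) {
    segs <- do.call(rbind, lapply(1:12, function(i) {
      s <- runif(1, 0, 48)
      seg_df("a", paste0("b", i), s, s + runif(1, 0.5, 2))
    }))
    tr <- hotspot_occurrence(segs, map, pairs = 12)
    overlap_permutation_test(tr, reg, map, top_q = 0.6, n_perm = 99,
                             seed = 1000 + b)$p_value
  }, 0)
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
})

test_that("IBD tables round-trip through the fastIBD-style TSV", {
  seg <- data.frame(sampleA = c("x", "y"), sampleB = c("y", "z"),
                    chrom = "chr1", start_bp = c(1e6, 2e6),
                    end_bp = c(3e6, 2.5e6), score = c(1e-9, 1e-10))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(seg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  r <- read_ibd(path)
  expect_equal(r$start_bp, seg$start_bp)
  expect_equal(r$score, seg$score)
  bad <- transform(seg, end_bp = start_bp)
  utils::write.table(bad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_ibd(path), "start < end")
})
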