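write_toy_vcf <- function(lines, samples = c("s1", "s2", "s3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               "##INFO=<ID=ANN,Number=1,Type=String,Description=\"x\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               lines), path)
  path
}

test_that("VCF loading keeps biallelic SNPs and codes inbred lines haploid", {
  p <- write_toy_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\tANN=synonymous\tGT\t0/0\t1/1\t0/0",
    "chr1\t200\t.\tG\tC\t.\tPASS\tANN=other\tGT\t0/0\t./.\t1/1",
    "chr1\t300\t.\tA\tG\t.\tPASS\tANN=synonymous\tGT\t0/1\t1/1\t0/0",
    "chr1\t400\t.\tA\tT,G\t.\tPASS\tANN=other\tGT\t0/0\t1/1\t2/2"))
  v <- load_variants(p)
  expect_equal(n_variants(v), 3L)               # multi-allelic dropped
  expect_equal(v$n_skipped_multiallelic, 1L)
  expect_equal(v$pos, c(100L, 200L, 300L))
  expect_equal(v$ann, c("synonymous", "other", "synonymous"))
  # missing GT stays NA but the record is kept; heterozygote becomes NA
  expect_equal(unname(v$geno[2, ]), c(0L, NA, 1L))
  expect_equal(unname(v$geno[3, ]), c(NA, 1L, 0L))
})

test_that("synonymous filtering preserves order and demands annotations", {
  g <- matrix(0L, 8, 3)
  ann <- c("synonymous", "other", "synonymous", "synonymous", "other",
           "other", "synonymous", "synonymous")
  v <- toy_variants(g, ann = ann)
  f <- filter_synonymous(v)
  expect_equal(n_variants(f), 5L)
  expect_equal(f$pos, v$pos[ann == "synonymous"])
  v_unk <- toy_variants(g)
  expect_error(filter_synonymous(v_unk), "unknown")
  v_empty <- subset_variants(v, integer(0))
  expect_equal(n_variants(filter_synonymous(v_empty)), 0L)
})

test_that("region exclusion follows 0-based half-open boundary semantics", {
  v <- toy_variants(matrix(0L, 3, 2), pos = c(100L, 101L, 200L))
  # [99, 100) removes 1-based position 100 only
  r <- data.frame(chrom = "chr1", start = 99L, end = 100L)
  expect_equal(exclude_regions(v, r)$pos, c(101L, 200L))
  # position just past the half-open end is retained
  r2 <- data.frame(chrom = "chr1", start = 90L, end = 100L)
  expect_equal(exclude_regions(v, r2)$pos, c(101L, 200L))
  # empty region set is the identity
  expect_equal(exclude_regions(v, r[0, ])$pos, v$pos)
  expect_warning(exclude_regions(v, data.frame(chrom = "chrX", start = 1L,
                                               end = 10L)), "ignored")
})

test_that("distance thinning is greedy, safe, and replicate-reproducible", {
  v <- toy_variants(matrix(0L, 3, 2), pos = c(1L, 1501L, 2501L))
  t1 <- thin_variants(v, min_bp = 2000, reps = 1, seed = 1, order = "sweep")
  expect_equal(t1[[1]]$pos, c(1L, 2501L))
  # every retained pair in every replicate is >= min_bp apart
  set.seed(5)
  pos <- sort(sample.int(50000L, 60))
  v2 <- toy_variants(matrix(0L, 60, 2), pos = pos)
  reps <- thin_variants(v2, min_bp = 2000, reps = 10, seed = 9)
  for (r in reps) expect_true(all(diff(r$pos) >= 2000))
  # bit-identical under the same (seed, index); replicates differ
  reps2 <- thin_variants(v2, min_bp = 2000, reps = 10, seed = 9)
  expect_identical(lapply(reps, `[[`, "pos"), lapply(reps2, `[[`, "pos"))
  expect_gt(length(unique(vapply(reps, function(r)
    paste(r$pos, collapse = ","), ""))), 1L)
  # single SNP always retained
  v3 <- toy_variants(matrix(0L, 1, 2), pos = 5L)
  expect_equal(thin_variants(v3, reps = 2, seed = 1)[[1]]$pos, 5L)
  expect_error(thin_variants(subset_variants(v2, c(2, 1)), seed = 1), "sorted")
})

test_that("the genotype-to-SFS chain projects and masks correctly", {
  # 1 site: 1/60 derived in pop1, 0/60 in pop2 -> unit mass at (1, 0)
  g <- matrix(c(1L, rep(0L, 119)), nrow = 1)
  colnames(g) <- c(sprintf("a%02d", 1:60), sprintf("b%02d", 1:60))
  v <- variant_set("chr1", 100L, g)
  pops <- pop_assignment(colnames(g), rep(c("TS", "NSS"), each = 60))
  s <- joint_sfs_from_genotypes(v, pops, pop_pair = c("TS", "NSS"),
                                proj = c(60, 60), polarization = "unfolded")
  expect_equal(unclass(s)[2, 1], 1)
  expect_equal(sfs_total(s), 1)
  # monomorphic site contributes nothing (mass lands in the masked corner)
  g0 <- matrix(0L, 1, 120, dimnames = list(NULL, colnames(g)))
  s0 <- joint_sfs_from_genotypes(variant_set("chr1", 100L, g0), pops,
                                 pop_pair = c("TS", "NSS"), proj = c(60, 60),
                                 polarization = "unfolded")
  expect_equal(sfs_total(s0), 0)
  # 4 haplotypes with 1 derived projected to 2: mass 0.5 at count 0 and 1
  g4 <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L), nrow = 1)
  colnames(g4) <- c(paste0("a", 1:4), paste0("b", 1:4))
  p4 <- pop_assignment(colnames(g4), rep(c("TS", "NSS"), each = 4))
  s4 <- joint_sfs_from_genotypes(variant_set("chr1", 5L, g4), p4,
                                 pop_pair = c("TS", "NSS"), proj = c(2, 2),
                                 polarization = "unfolded")
  m4 <- unclass(s4); m4[is.na(m4)] <- 0
  # hypergeometric weights per population are (1/2, 1/2, 0)
  expect_equal(sum(m4[2, ]), 0.5)         # pop1 count 1 keeps weight 1/2
  expect_equal(m4[2, 1], 0.25)            # (1, 0) cell
  expect_equal(sfs_total(s4), 0.75)       # (0, 0) quarter is corner-masked
  # sites with too much missingness are dropped and counted
  gm <- matrix(c(1L, NA, 0L, 0L, 0L, 0L, 0L, 0L), nrow = 1)
  colnames(gm) <- colnames(g4)
  sm <- joint_sfs_from_genotypes(variant_set("chr1", 5L, gm), p4,
                                 pop_pair = c("TS", "NSS"), proj = c(4, 4),
                                 polarization = "unfolded")
  expect_equal(attr(sm, "dropped_sites"), 1L)
  expect_equal(sfs_total(sm), 0)
})

test_that("the full chain is deterministic given the seed", {
  sim <- simulate_genotypes(sim_config(
    params = scaled_params("split1", nu1 = 1, nu2 = 0.3, tau = 0.1, M = 1),
    n_snps = 500, n1 = 12, n2 = 12,
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    mc_replicates = 2000, seed = 123))
  run_once <- function() {
    v <- filter_synonymous(sim$variants)
    v <- exclude_regions(v, sim$regions)
    th <- thin_variants(v, min_bp = 2000, reps = 2, seed = 77)
    joint_sfs_from_genotypes(th[[1]], sim$pops, pop_pair = c("TS", "NSS"),
                             proj = c(8, 8))
  }
  a <- run_once(); b <- run_once()
  expect_identical(unclass(a), unclass(b))
})
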