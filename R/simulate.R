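#' Synthetic-study configuration
#'
#' Bundles every knob of the generators. Defaults describe the study
#' conditions the pipeline targets: two inbred-line panels (tropical and
#' temperate) of 80 lines each, the two-bottleneck split demography at its
#' reference parameter values, a ten-chromosome genome scaled to desk size
#' (30 Mb per chromosome) with a maize-like 0.8 cM/Mb baseline map, a
#' quarter of SNPs synonymous, about 5% of the genome inside
#' "selected-region" intervals, and pairwise IBD with exponential tract
#' lengths of mean 3 cM at 2 segments per pair.
#'
#' @param params [scaled_params()] of the generating model (theta ignored;
#'   site counts are set by \code{n_snps})
#' @param n_snps number of SNP sites to emit
#' @param n1,n2 lines (haplotypes) per population; n2 = 0 for one-deme
#'   models
#' @param chrom_lengths named vector of chromosome lengths, bp
#' @param cM_per_Mb baseline recombination density
#' @param map_jitter gamma shape of the positive jitter on per-Mb map
#'   increments (larger is smoother); 0 disables jitter
#' @param frac_synonymous fraction of sites labeled synonymous
#' @param sel_region_frac fraction of each chromosome covered by emitted
#'   selected-region intervals
#' @param ibd_rate mean IBD segments per sample pair
#' @param ibd_mean_cM mean exponential tract length, cM
#' @param hotspots data.frame (chrom, start_cM, end_cM) of enriched
#'   windows, or NULL
#' @param hotspot_enrichment placement-weight multiplier inside hotspots
#' @param mc_replicates genealogy replicates used to compute the generating
#'   expected SFS
#' @param seed mandatory integer seed
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(params = split5_reference_fit()$scaled,
                       n_snps = 20000, n1 = 80, n2 = 80,
                       chrom_lengths = stats::setNames(rep(30e6, 10),
                                                       paste0("chr", 1:10)),
                       cM_per_Mb = 0.8, map_jitter = 20,
                       frac_synonymous = 0.25, sel_region_frac = 0.05,
                       ibd_rate = 2, ibd_mean_cM = 3,
                       hotspots = NULL, hotspot_enrichment = 5,
                       mc_replicates = 20000, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_snps >= 1, n1 >= 1, n2 >= 0, all(chrom_lengths > 0),
            cM_per_Mb > 0, ibd_rate >= 0, ibd_mean_cM > 0,
            hotspot_enrichment > 0)
  structure(list(params = params, n_snps = as.integer(n_snps),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 chrom_lengths = chrom_lengths, cM_per_Mb = cM_per_Mb,
                 map_jitter = map_jitter,
                 frac_synonymous = frac_synonymous,
                 sel_region_frac = sel_region_frac,
                 ibd_rate = ibd_rate, ibd_mean_cM = ibd_mean_cM,
                 hotspots = hotspots,
                 hotspot_enrichment = hotspot_enrichment,
                 mc_replicates = as.integer(mc_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# positions with guaranteed >= min_bp spacing: slack distributed uniformly
spaced_positions <- function(n, chrom_len, min_bp) {
  if (n == 0L) return(integer(0))
  slack <- chrom_len - n * min_bp
  if (slack < 0) stop("requested SNP count incompatible with spacing and chromosome length")
  cuts <- sort(stats::runif(n, 0, slack))
  as.integer(floor(cuts) + min_bp * seq_len(n))
}

#' Simulate unlinked genotypes from a model's expected joint SFS
#'
#' Site configurations (i, j) are drawn multinomially from the normalized
#' expected joint spectrum of the configured model at the panel sample
#' sizes; carriers are assigned uniformly at random within each population,
#' consistent with the configuration. Positions are uniform with a
#' guaranteed minimum spacing of 2 kb (sites are unlinked by construction).
#' A fraction of sites is labeled non-synonymous, and selected-region BED
#' intervals are emitted (sites are placed without regard to them) so that
#' the filtering stages have work to do.
#'
#' @param cfg [sim_config()]
#' @param out_dir optional directory; when given, a VCF
#'   (\code{panel.vcf}), BED (\code{selected_regions.bed}), population file
#'   (\code{pops.tsv}) and truth table (\code{truth.tsv}) are written
#' @return list: \code{variants} (\code{variant_set}), \code{pops},
#'   \code{regions}, \code{truth} (per-site configuration data.frame),
#'   \code{expected_sfs}, and file paths when written
#' @export
simulate_genotypes <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  sfs <- model_spectrum(cfg$params, cfg$n1, cfg$n2, theta = 1,
                        cfg = coalescent_config(cfg$mc_replicates,
                                                seed = cfg$seed))
  set.seed(cfg$seed + 1L)
  m <- unclass(sfs)
  m[is.na(m)] <- 0
  cells <- which(m > 0, arr.ind = TRUE)
  probs <- m[m > 0]
  draw <- stats::rmultinom(1, cfg$n_snps, probs)[, 1]
  i_cnt <- rep(cells[, 1] - 1L, draw)
  j_cnt <- rep(cells[, 2] - 1L, draw)
  ord <- sample.int(length(i_cnt))                 # shuffle site order
  i_cnt <- i_cnt[ord]; j_cnt <- j_cnt[ord]

  # per-chromosome site counts proportional to length
  ns <- length(i_cnt)
  chrom_of <- sample(names(cfg$chrom_lengths), ns, replace = TRUE,
                     prob = cfg$chrom_lengths)
  chrom_of <- sort(chrom_of)
  pos <- integer(ns)
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    pos[idx] <- spaced_positions(length(idx), cfg$chrom_lengths[[ch]], 2000L)
  }

  samples <- c(sprintf("TS%03d", seq_len(cfg$n1)),
               if (cfg$n2 > 0) sprintf("NSS%03d", seq_len(cfg$n2)))
  geno <- matrix(0L, ns, cfg$n1 + cfg$n2, dimnames = list(NULL, samples))
  for (s in seq_len(ns)) {
    if (i_cnt[s] > 0) geno[s, sample.int(cfg$n1, i_cnt[s])] <- 1L
    if (j_cnt[s] > 0) geno[s, cfg$n1 + sample.int(cfg$n2, j_cnt[s])] <- 1L
  }
  ann <- ifelse(stats::runif(ns) < cfg$frac_synonymous, "synonymous", "other")
  v <- variant_set(chrom_of, pos, geno, ann = ann)
  pops <- pop_assignment(samples, c(rep("TS", cfg$n1), rep("NSS", cfg$n2)))

  regions <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    width <- round(cfg$sel_region_frac * len / 2)
    if (width < 1) return(NULL)
    s1 <- round(stats::runif(1, 0, len / 2 - width))
    s2 <- round(stats::runif(1, len / 2, len - width))
    data.frame(chrom = ch, start = c(s1, s2), end = c(s1, s2) + width)
  }))
  truth <- data.frame(chrom = v$chrom, pos = v$pos,
                      count_pop1 = i_cnt, count_pop2 = j_cnt, ann = ann)
  out <- list(variants = v, pops = pops, regions = regions, truth = truth,
              expected_sfs = sfs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$vcf_path <- file.path(out_dir, "panel.vcf")
    write_sim_vcf(v, out$vcf_path)
    out$bed_path <- file.path(out_dir, "selected_regions.bed")
    utils::write.table(regions, out$bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out$pops_path <- file.path(out_dir, "pops.tsv")
    utils::write.table(data.frame(names(pops), unname(pops)), out$pops_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    out$truth_path <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, out$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Write a variant set as an uncompressed VCF v4.2
#'
#' Inbred lines are written as homozygous diploid GT calls (0/0, 1/1, or
#' ./. for missing); the annotation class goes into the \code{ANN} INFO
#' key.
#'
#' @param v \code{variant_set}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_sim_vcf <- function(v, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(v$chrom)),
               "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation class\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", v$samples), collapse = "\t")), con)
  gt <- matrix("./.", n_variants(v), ncol(v$geno))
  gt[v$geno == 0L] <- "0/0"
  gt[v$geno == 1L] <- "1/1"
  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                 paste0("ANN=", v$ann), "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a jittered genetic map
#'
#' Anchors every megabase (plus the chromosome end); cM increments are the
#' baseline density times a positive gamma jitter, so the map is strictly
#' increasing in both coordinates.
#'
#' @param cfg [sim_config()]
#' @param out_path optional TSV path
#' @return \code{genetic_map}
#' @export
simulate_map <- function(cfg, out_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 2L)
  rows <- lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    bp <- unique(c(seq(0, len, by = 1e6), len))
    inc_mb <- diff(bp) / 1e6
    jit <- if (cfg$map_jitter > 0)
      stats::rgamma(length(inc_mb), shape = cfg$map_jitter,
                    rate = cfg$map_jitter) else rep(1, length(inc_mb))
    data.frame(chrom = ch, pos_bp = bp,
               pos_cM = c(0, cumsum(cfg$cM_per_Mb * inc_mb * jit)))
  })
  map <- genetic_map(do.call(rbind, rows))
  if (!is.null(out_path))
    utils::write.table(map, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  map
}

#' Simulate pairwise IBD segments with optional planted hotspots
#'
#' Per sample pair the segment count is Poisson(\code{ibd_rate}); each
#' segment picks a chromosome proportional to genetic length, an
#' exponential length (mean \code{ibd_mean_cM}), and a start position from
#' a piecewise-constant density that up-weights hotspot windows by the
#' enrichment factor; segments are truncated at chromosome ends and mapped
#' to bp by inverse interpolation.
#'
#' @param cfg [sim_config()]
#' @param samples character vector of sample names
#' @param map \code{genetic_map}
#' @param out_path optional TSV path (fastIBD-style, no header)
#' @return segment data.frame with bp and cM coordinates
#' @export
simulate_ibd <- function(cfg, samples, map, out_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 3L)
  chroms <- unique(map$chrom)
  clen <- vapply(chroms, function(ch) max(map$pos_cM[map$chrom == ch]), 0)
  if (!is.null(cfg$hotspots))
    for (w in seq_len(nrow(cfg$hotspots))) {
      ch <- cfg$hotspots$chrom[w]
      if (!ch %in% chroms || cfg$hotspots$end_cM[w] > clen[[ch]])
        stop("hotspot window outside the genetic map")
    }
  pairs <- utils::combn(samples, 2)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    nseg <- stats::rpois(1, cfg$ibd_rate)
    if (nseg == 0) next
    for (s in seq_len(nseg)) {
      ch <- sample(chroms, 1, prob = clen)
      len <- stats::rexp(1, 1 / cfg$ibd_mean_cM)
      start <- sample_start_cM(cfg, ch, clen[[ch]])
      end <- min(start + len, clen[[ch]])
      if (end <= start) next
      rows[[length(rows) + 1L]] <- data.frame(
        sampleA = pairs[1, p], sampleB = pairs[2, p], chrom = ch,
        start_cM = start, end_cM = end,
        score = 10^stats::runif(1, -10, -8))
    }
  }
  seg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sampleA = character(0), sampleB = character(0),
               chrom = character(0), start_cM = numeric(0),
               end_cM = numeric(0), score = numeric(0))
  if (nrow(seg)) {
    seg$start_bp <- NA_real_; seg$end_bp <- NA_real_
    for (ch in unique(seg$chrom)) {
      i <- seg$chrom == ch
      seg$start_bp[i] <- round(interpolate_bp(map, ch, seg$start_cM[i]))
      seg$end_bp[i] <- round(interpolate_bp(map, ch, seg$end_cM[i]))
    }
    seg$length_cM <- seg$end_cM - seg$start_cM
  } else {
    seg$start_bp <- numeric(0); seg$end_bp <- numeric(0)
    seg$length_cM <- numeric(0)
  }
  if (!is.null(out_path))
    utils::write.table(seg[, c("sampleA", "sampleB", "chrom",
                               "start_bp", "end_bp", "score"), drop = FALSE],
                       out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  seg
}

#' Simulate repeated detector runs over one IBD truth set
#'
#' Emulates multiple runs of an IBD detector on the same data: a single
#' truth segment set is drawn with [simulate_ibd()], and each run reports a
#' noisy version of it - every segment is dropped independently with
#' probability \code{drop_rate} and its endpoints jittered by up to
#' \code{jitter_cM}, truncated to the chromosome and to positive length.
#'
#' @param cfg [sim_config()]
#' @param samples character vector of sample names
#' @param map \code{genetic_map}
#' @param n_runs number of runs to emit
#' @param jitter_cM maximum absolute endpoint perturbation, cM
#' @param drop_rate per-run probability that a segment goes undetected
#' @param out_paths optional character vector of TSV paths, length n_runs
#' @return list: \code{truth} (the generating segments), \code{runs}
#'   (list of per-run segment data.frames)
#' @export
simulate_ibd_runs <- function(cfg, samples, map, n_runs = 10,
                              jitter_cM = 0.2, drop_rate = 0.1,
                              out_paths = NULL) {
  truth <- simulate_ibd(cfg, samples, map)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 4L)
  clen <- vapply(unique(map$chrom), function(ch)
    max(map$pos_cM[map$chrom == ch]), 0)
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    r <- truth[stats::runif(nrow(truth)) >= drop_rate, , drop = FALSE]
    if (nrow(r)) {
      top <- clen[r$chrom]
      r$start_cM <- pmax(0, r$start_cM +
                           stats::runif(nrow(r), -jitter_cM, jitter_cM))
      r$end_cM <- pmin(top, pmax(r$start_cM + 0.05, r$end_cM +
                                   stats::runif(nrow(r), -jitter_cM, jitter_cM)))
      for (ch in unique(r$chrom)) {
        i <- r$chrom == ch
        r$start_bp[i] <- round(interpolate_bp(map, ch, r$start_cM[i]))
        r$end_bp[i] <- round(interpolate_bp(map, ch, r$end_cM[i]))
      }
      r <- r[r$end_bp > r$start_bp, , drop = FALSE]
      r$length_cM <- r$end_cM - r$start_cM
    }
    rownames(r) <- NULL
    runs[[k]] <- r
    if (!is.null(out_paths))
      utils::write.table(r[, c("sampleA", "sampleB", "chrom",
                               "start_bp", "end_bp", "score"), drop = FALSE],
                         out_paths[k], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  }
  list(truth = truth, runs = runs)
}

# start position from the hotspot-weighted piecewise-constant density
sample_start_cM <- function(cfg, ch, chrom_len) {
  hs <- cfg$hotspots
  if (is.null(hs) || !any(hs$chrom == ch))
    return(stats::runif(1, 0, chrom_len))
  hs <- hs[hs$chrom == ch, , drop = FALSE]
  brk <- sort(unique(c(0, hs$start_cM, hs$end_cM, chrom_len)))
  w <- diff(brk)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  inhot <- vapply(mid, function(x) any(x >= hs$start_cM & x < hs$end_cM), TRUE)
  w <- w * ifelse(inhot, cfg$hotspot_enrichment, 1)
  seg <- sample.int(length(w), 1, prob = w)
  stats::runif(1, brk[seg], brk[seg + 1])
}

#' Simulate a haplotype-block panel with planted LD
#'
#' Samples copy one of a few founder haplotypes per block with per-site
#' noise flips, so r-squared is high within blocks and near the
#' independence floor across blocks; used to exercise the LD statistics.
#'
#' @param n_samples lines in the panel
#' @param n_snps sites
#' @param n_founders founder haplotypes per block
#' @param block_len sites per block
#' @param noise_rate per-site copy-error probability
#' @param spacing_bp distance between adjacent sites
#' @param seed integer seed
#' @param chrom chromosome name
#' @return \code{variant_set}
#' @export
simulate_ld_panel <- function(n_samples = 100, n_snps = 200, n_founders = 4,
                              block_len = 20, noise_rate = 0.02,
                              spacing_bp = 100, seed, chrom = "chr1") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- matrix(0L, n_snps, n_samples)
  n_blocks <- ceiling(n_snps / block_len)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_len + 1L):min(b * block_len, n_snps)
    founders <- matrix(stats::rbinom(length(idx) * n_founders, 1, 0.5),
                       length(idx), n_founders)
    pick <- sample.int(n_founders, n_samples, replace = TRUE)
    g[idx, ] <- founders[, pick]
  }
  flip <- matrix(stats::runif(length(g)) < noise_rate, nrow(g), ncol(g))
  g[flip] <- 1L - g[flip]
  variant_set(rep(chrom, n_snps), seq_len(n_snps) * spacing_bp, g)
}

#' Simulate independent sites under an island model with target Fst
#'
#' Ancestral frequencies are uniform on (0.1, 0.9); population frequencies
#' are Beta-distributed around them with variance parameter F (the
#' Balding-Nichols model), so the expected Weir-Cockerham Fst is close to
#' F. Used to check the monotonicity of the Fst estimator.
#'
#' @param nA,nB haploid samples per population
#' @param n_sites number of independent sites
#' @param fst target differentiation in [0, 1)
#' @param seed integer seed
#' @return list: \code{variants} (\code{variant_set}), \code{pops}
#' @export
simulate_island_sites <- function(nA, nB, n_sites, fst, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- stats::runif(n_sites, 0.1, 0.9)
  draw_p <- function(p) {
    if (fst <= 0) return(p)
    stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  }
  pA <- draw_p(p); pB <- draw_p(p)
  gA <- matrix(stats::rbinom(n_sites * nA, 1, rep(pA, nA)), n_sites, nA)
  gB <- matrix(stats::rbinom(n_sites * nB, 1, rep(pB, nB)), n_sites, nB)
  g <- cbind(gA, gB)
  colnames(g) <- c(sprintf("A%03d", 1:nA), sprintf("B%03d", 1:nB))
  v <- variant_set(rep("chr1", n_sites), seq_len(n_sites) * 2000L, g)
  list(variants = v,
       pops = pop_assignment(colnames(g), c(rep("A", nA), rep("B", nB))))
}
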