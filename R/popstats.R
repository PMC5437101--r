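#' Windowed Weir-Cockerham Fst for haploid-coded inbred samples
#'
#' Per segregating site the Weir-Cockerham variance components are computed
#' for haploid samples (the individual-within component is structurally
#' zero for inbred lines): with population allele frequencies p_i from n_i
#' non-missing haplotypes, MSP = sum n_i (p_i - pbar)^2 / (r-1),
#' MSG = sum n_i p_i (1-p_i) / sum (n_i - 1),
#' nc = (sum n_i - sum n_i^2 / sum n_i) / (r-1),
#' a = (MSP - MSG)/nc (among populations) and b = MSG (within). Windows use
#' the ratio-of-sums estimator Fst = sum(a) / sum(a+b) over their
#' segregating sites and are reported as undefined unless they hold more
#' than \code{min_seg} segregating sites.
#'
#' @param v \code{variant_set}
#' @param pops [pop_assignment()]
#' @param popA,popB the two population labels
#' @param window_bp,step_bp sliding-window size and step, bp
#' @param min_seg windows need strictly more than this many segregating
#'   sites
#' @return data.frame (chrom, start, end 1-based inclusive, n_sites, fst);
#'   class \code{window_track}
#' @export
wc_fst_windows <- function(v, pops, popA, popB,
                           window_bp = 1e6, step_bp = 2e5, min_seg = 30) {
  comp <- wc_site_components(v, pops, popA, popB)
  out <- list()
  for (ch in unique(v$chrom)) {
    on_ch <- v$chrom == ch
    maxp <- max(v$pos[on_ch])
    starts0 <- seq(0L, max(0L, maxp - 1L), by = as.integer(step_bp))
    for (w0 in starts0) {
      w1 <- w0 + window_bp
      sel <- on_ch & v$pos > w0 & v$pos <= w1 & comp$seg
      nseg <- sum(sel)
      fst <- if (nseg > min_seg) {
        denom <- sum(comp$a[sel] + comp$b[sel])
        if (denom > 0) sum(comp$a[sel]) / denom else NA_real_
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = w0 + 1L, end = w1, n_sites = nseg, fst = fst)
      if (w1 >= maxp) break
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("window_track", "data.frame")
  res
}

# per-site Weir-Cockerham components a, b plus a segregating flag
wc_site_components <- function(v, pops, popA, popB) {
  sA <- intersect(names(pops)[pops == popA], v$samples)
  sB <- intersect(names(pops)[pops == popB], v$samples)
  if (length(sA) < 2L || length(sB) < 2L)
    stop("both populations need >= 2 samples")
  gA <- v$geno[, sA, drop = FALSE]
  gB <- v$geno[, sB, drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))
  cA <- rowSums(gA == 1L, na.rm = TRUE); cB <- rowSums(gB == 1L, na.rm = TRUE)
  ok <- nA >= 2L & nB >= 2L
  pA <- ifelse(nA > 0, cA / nA, NA)
  pB <- ifelse(nB > 0, cB / nB, NA)
  ntot <- nA + nB
  pbar <- (cA + cB) / ntot
  seg <- ok & (cA + cB) > 0L & (cA + cB) < ntot
  MSP <- nA * (pA - pbar)^2 + nB * (pB - pbar)^2          # r - 1 = 1
  MSG <- (nA * pA * (1 - pA) + nB * pB * (1 - pB)) / (ntot - 2)
  nc <- ntot - (nA^2 + nB^2) / ntot
  a <- (MSP - MSG) / nc
  b <- MSG
  a[!seg] <- 0; b[!seg] <- 0
  list(a = a, b = b, seg = seg)
}

#' Genome-wide ratio-of-sums Weir-Cockerham Fst
#' @inheritParams wc_fst_windows
#' @return scalar Fst over all segregating sites
#' @export
wc_fst_global <- function(v, pops, popA, popB) {
  comp <- wc_site_components(v, pops, popA, popB)
  sum(comp$a[comp$seg]) / sum(comp$a[comp$seg] + comp$b[comp$seg])
}

#' Population-specific SNP counts from repeated subsampling
#'
#' Per replicate, \code{sample_n} lines are drawn from every population; a
#' SNP is population-specific when it is polymorphic in exactly one
#' population's draw, and is classed by its minor-allele frequency in that
#' draw (rare: MAF <= maf_split; common otherwise).
#'
#' @param v \code{variant_set}
#' @param pops [pop_assignment()]
#' @param sample_n lines drawn per population
#' @param reps number of replicate draws
#' @param maf_split rare/common MAF boundary (<= is rare)
#' @param seed integer seed
#' @return list: \code{per_replicate} data.frame (replicate, pop, rare,
#'   common), \code{summary} data.frame with mean counts, the
#'   rare:common ratio, and the mean fraction of SNPs that are
#'   population-specific
#' @export
pop_specific_snps <- function(v, pops, sample_n = 50, reps = 10,
                              maf_split = 0.05, seed) {
  labs <- unique(unname(pops))
  members <- lapply(labs, function(l) intersect(names(pops)[pops == l], v$samples))
  names(members) <- labs
  if (any(lengths(members) < sample_n))
    stop("every population needs at least sample_n members")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  frac_specific <- numeric(reps)
  for (r in seq_len(reps)) {
    draw <- lapply(members, function(mm) sample(mm, sample_n))
    poly <- vapply(labs, function(l) {
      g <- v$geno[, draw[[l]], drop = FALSE]
      cnt <- rowSums(g == 1L, na.rm = TRUE)
      n <- rowSums(!is.na(g))
      cnt > 0L & cnt < n
    }, logical(n_variants(v)))
    if (!is.matrix(poly)) poly <- matrix(poly, nrow = 1,
                                         dimnames = list(NULL, labs))
    nspec <- rowSums(poly) == 1L
    frac_specific[r] <- mean(nspec)
    for (l in labs) {
      idx <- which(nspec & poly[, l])
      g <- v$geno[idx, draw[[l]], drop = FALSE]
      cnt <- rowSums(g == 1L, na.rm = TRUE)
      n <- rowSums(!is.na(g))
      maf <- pmin(cnt / n, 1 - cnt / n)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, pop = l,
        rare = sum(maf <= maf_split), common = sum(maf > maf_split))
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(labs, function(l) {
    d <- per[per$pop == l, ]
    data.frame(pop = l, mean_rare = mean(d$rare), mean_common = mean(d$common),
               rare_common_ratio = mean(d$rare) / mean(d$common))
  }))
  list(per_replicate = per, summary = agg,
       mean_frac_specific = mean(frac_specific))
}

#' r-squared between each SNP and its next k neighbours
#'
#' Composite allele-frequency correlation on haploid-coded genotypes with
#' pairwise-complete samples; pairs where either SNP is monomorphic in the
#' complete subset are skipped.
#'
#' @param v \code{variant_set} sorted by (chrom, pos)
#' @param k number of downstream neighbours per SNP
#' @return data.frame (chrom, pos1, pos2, distance_bp, r2)
#' @export
ld_r2_adjacent <- function(v, k = 10) {
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_along(o))) stop("variants must be sorted by (chrom, pos)")
  rows <- vector("list", 0)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    for (ii in seq_along(idx)) {
      for (jj in seq_len(min(k, length(idx) - ii))) {
        a <- idx[ii]; b <- idx[ii + jj]
        r2 <- r2_pair(v$geno[a, ], v$geno[b, ])
        if (is.na(r2)) next
        rows[[length(rows) + 1L]] <- c(a, b)
        attr(rows[[length(rows)]], "r2") <- r2
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), pos1 = integer(0),
                      pos2 = integer(0), distance_bp = integer(0),
                      r2 = numeric(0)))
  ab <- do.call(rbind, rows)
  r2 <- vapply(rows, attr, 0, "r2")
  data.frame(chrom = v$chrom[ab[, 1]],
             pos1 = v$pos[ab[, 1]], pos2 = v$pos[ab[, 2]],
             distance_bp = v$pos[ab[, 2]] - v$pos[ab[, 1]], r2 = r2)
}

r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD decay distance and per-bin summaries
#'
#' Pairs are grouped into distance-ordered bins; the decay distance is the
#' mean pairwise distance in the first bin whose mean r-squared falls to or
#' below \code{r2_cut} (right-censored when no bin reaches it). For the
#' boxplot view, pairs are also grouped into r-squared categories with
#' per-category distance quartiles.
#'
#' @param pairs data.frame from [ld_r2_adjacent()]
#' @param r2_cut stable-r2 cutoff
#' @param dist_bin_bp distance bin width, bp
#' @param r2_breaks breakpoints for the r-squared categories
#' @return list: \code{decay_bp}, \code{censored}, \code{distance_bins},
#'   \code{r2_bins}
#' @export
ld_decay_distance <- function(pairs, r2_cut = 0.1, dist_bin_bp = 100,
                              r2_breaks = seq(0, 1, by = 0.1)) {
  if (nrow(pairs) == 0L) stop("empty pair table")
  bin <- floor(pairs$distance_bp / dist_bin_bp)
  means <- tapply(pairs$r2, bin, mean)
  dmeans <- tapply(pairs$distance_bp, bin, mean)
  ord <- order(as.numeric(names(means)))
  means <- means[ord]; dmeans <- dmeans[ord]
  hit <- which(means <= r2_cut)
  decay <- if (length(hit)) unname(dmeans[hit[1]]) else NA_real_
  dist_bins <- data.frame(bin_start_bp = as.numeric(names(means)) * dist_bin_bp,
                          mean_distance_bp = as.numeric(dmeans),
                          mean_r2 = as.numeric(means))
  cats <- cut(pairs$r2, breaks = r2_breaks, include.lowest = TRUE)
  qs <- tapply(pairs$distance_bp, cats, function(d)
    stats::quantile(d, c(0.25, 0.5, 0.75)))
  keep <- !vapply(qs, is.null, TRUE)
  r2_bins <- data.frame(r2_bin = names(qs)[keep],
                        q25 = vapply(qs[keep], `[[`, 0, 1),
                        median = vapply(qs[keep], `[[`, 0, 2),
                        q75 = vapply(qs[keep], `[[`, 0, 3))
  list(decay_bp = decay, censored = !length(hit),
       distance_bins = dist_bins, r2_bins = r2_bins)
}

#' Greedy LD pruning
#'
#' Left-to-right scan per chromosome: a SNP is removed when its r-squared
#' with any retained SNP within \code{window_bp} upstream exceeds
#' \code{r2_thresh}.
#'
#' @param v \code{variant_set} sorted by (chrom, pos)
#' @param r2_thresh removal threshold (strictly greater than)
#' @param window_bp upstream window, bp
#' @return pruned \code{variant_set}
#' @export
ld_prune <- function(v, r2_thresh = 0.2, window_bp = 5e5) {
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_along(o))) stop("variants must be sorted by (chrom, pos)")
  keep <- logical(n_variants(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    kept <- integer(0)
    for (s in idx) {
      near <- kept[v$pos[s] - v$pos[kept] <= window_bp]
      drop <- FALSE
      for (t in rev(near)) {
        r2 <- r2_pair(v$geno[s, ], v$geno[t, ])
        if (!is.na(r2) && r2 > r2_thresh) { drop <- TRUE; break }
      }
      if (!drop) { keep[s] <- TRUE; kept <- c(kept, s) }
    }
  }
  subset_variants(v, keep)
}

#' Identity-by-state kinship matrix for haploid-coded samples
#'
#' Method-of-moments estimator from allele sharing: for each pair the
#' observed fraction of identical sites is centered by its panmictic
#' expectation from the panel allele frequencies,
#' k = (IBS_obs - IBS_exp) / (1 - IBS_exp) over pairwise-complete sites, so
#' unrelated samples score near 0 and duplicates score 1. Diagonal is 1.
#'
#' @param v \code{variant_set}
#' @return symmetric samples x samples matrix (values near [0, 1],
#'   small negatives possible by sampling noise)
#' @export
kinship_matrix <- function(v) {
  g <- v$geno
  n <- ncol(g)
  p <- rowMeans(g, na.rm = TRUE)
  exp_match <- 1 - 2 * p * (1 - p)
  K <- matrix(1, n, n, dimnames = list(v$samples, v$samples))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    ok <- !is.na(g[, a]) & !is.na(g[, b]) & p > 0 & p < 1
    K[a, b] <- K[b, a] <- if (any(ok)) {
      obs <- mean(g[ok, a] == g[ok, b])
      em <- mean(exp_match[ok])
      (obs - em) / (1 - em)
    } else NA_real_
  }
  K
}

#' Remove one of each over-related sample pair
#'
#' Iteratively, while any retained pair has kinship above the threshold,
#' one member of the first such pair (in sample order) is removed at
#' random; the retained set therefore has no pair above the threshold and
#' is deterministic given the seed.
#'
#' @param v \code{variant_set}
#' @param threshold kinship cutoff (strictly greater than triggers removal)
#' @param seed integer seed
#' @return character vector of retained sample names, with attribute
#'   \code{removed}
#' @export
kinship_filter <- function(v, threshold = 0.5, seed) {
  K <- kinship_matrix(v)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- colnames(K)
  repeat {
    Ks <- K[keep, keep, drop = FALSE]
    Ks[lower.tri(Ks, diag = TRUE)] <- NA
    bad <- which(Ks > threshold, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    pair <- keep[bad[1, ]]
    keep <- setdiff(keep, sample(pair, 1))
  }
  structure(keep, removed = setdiff(colnames(K), keep))
}
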