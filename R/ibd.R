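#' Genetic map with linear interpolation between anchors
#'
#' @param map data.frame with columns chrom, pos_bp, pos_cM; both
#'   coordinates must be strictly increasing within a chromosome and every
#'   chromosome needs at least two anchors
#' @return validated map, class \code{genetic_map}
#' @export
genetic_map <- function(map) {
  stopifnot(all(c("chrom", "pos_bp", "pos_cM") %in% names(map)))
  map <- map[order(map$chrom, map$pos_bp), ]
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (nrow(m) < 2L) stop("each chromosome needs >= 2 map anchors")
    if (any(diff(m$pos_bp) <= 0) || any(diff(m$pos_cM) <= 0))
      stop("map coordinates must be strictly increasing within a chromosome")
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Read a genetic map TSV (chrom, pos_bp, pos_cM)
#' @param path TSV path, no header
#' @return \code{genetic_map}
#' @export
read_genetic_map <- function(path) {
  genetic_map(utils::read.table(path, sep = "\t", header = FALSE,
                                col.names = c("chrom", "pos_bp", "pos_cM")))
}

#' Interpolate genetic position (cM) from physical position (bp)
#'
#' Piecewise-linear between anchors; positions outside the anchored range
#' are extended linearly with the terminal segment's slope and flagged via
#' the \code{extrapolated} attribute.
#'
#' @param map \code{genetic_map}
#' @param chrom chromosome name
#' @param pos_bp numeric vector of physical positions
#' @return numeric cM positions with logical attribute \code{extrapolated}
#' @export
interpolate_cM <- function(map, chrom, pos_bp) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0L) stop(sprintf("unknown chromosome '%s'", chrom))
  out <- stats::approx(m$pos_bp, m$pos_cM, xout = pos_bp, rule = 2)$y
  lo <- pos_bp < m$pos_bp[1]; hi <- pos_bp > m$pos_bp[nrow(m)]
  if (any(lo)) {
    sl <- (m$pos_cM[2] - m$pos_cM[1]) / (m$pos_bp[2] - m$pos_bp[1])
    out[lo] <- m$pos_cM[1] + (pos_bp[lo] - m$pos_bp[1]) * sl
  }
  if (any(hi)) {
    k <- nrow(m)
    sl <- (m$pos_cM[k] - m$pos_cM[k - 1]) / (m$pos_bp[k] - m$pos_bp[k - 1])
    out[hi] <- m$pos_cM[k] + (pos_bp[hi] - m$pos_bp[k]) * sl
  }
  attr(out, "extrapolated") <- lo | hi
  out
}

#' Inverse map interpolation: cM to bp
#' @inheritParams interpolate_cM
#' @param pos_cM numeric vector of genetic positions
#' @return numeric bp positions
#' @export
interpolate_bp <- function(map, chrom, pos_cM) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0L) stop(sprintf("unknown chromosome '%s'", chrom))
  stats::approx(m$pos_cM, m$pos_bp, xout = pos_cM, rule = 2)$y
}

#' Read an IBD segment table
#'
#' TSV columns: sampleA, sampleB, chrom, start_bp, end_bp, score (fastIBD
#' style, no header).
#'
#' @param path TSV path
#' @return data.frame of segments
#' @export
read_ibd <- function(path) {
  seg <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sampleA", "sampleB", "chrom",
                                         "start_bp", "end_bp", "score"),
                           colClasses = c("character", "character", "character",
                                          "numeric", "numeric", "numeric"))
  if (any(seg$end_bp <= seg$start_bp)) stop("segments must have start < end")
  if (any(seg$sampleA == seg$sampleB)) stop("segments must join distinct samples")
  seg
}

#' Attach genetic coordinates to segments
#' @param segments data.frame as from [read_ibd()]
#' @param map \code{genetic_map}
#' @return segments with added start_cM, end_cM, length_cM
#' @export
ibd_add_cM <- function(segments, map) {
  segments$start_cM <- NA_real_
  segments$end_cM <- NA_real_
  for (ch in unique(segments$chrom)) {
    i <- segments$chrom == ch
    segments$start_cM[i] <- as.numeric(interpolate_cM(map, ch, segments$start_bp[i]))
    segments$end_cM[i] <- as.numeric(interpolate_cM(map, ch, segments$end_bp[i]))
  }
  segments$length_cM <- segments$end_cM - segments$start_cM
  segments
}

# canonical pair id, order-free
pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Majority-vote consensus of IBD segments across runs
#'
#' For every sample pair and chromosome, a base-pair position belongs to the
#' consensus when it is covered by a segment in more than half of the runs
#' (> 5 of 10 by default); maximal covered intervals are emitted.
#'
#' @param runs list of segment data.frames over an identical sample universe
#' @param min_runs minimum coverage count; default \code{floor(n/2) + 1}
#' @return consensus segment data.frame (score dropped)
#' @export
consensus_ibd <- function(runs, min_runs = NULL) {
  n <- length(runs)
  if (n == 0L) stop("no runs supplied")
  uni <- lapply(runs, function(r) sort(unique(c(r$sampleA, r$sampleB))))
  nonempty <- uni[lengths(uni) > 0]
  if (length(nonempty) > 1L)
    for (a in seq_len(length(nonempty) - 1L))
      if (!length(intersect(nonempty[[a]], nonempty[[a + 1L]])))
        stop("runs cover different sample sets")
  if (is.null(min_runs)) min_runs <- floor(n / 2) + 1L
  all_seg <- do.call(rbind, lapply(seq_along(runs), function(k) {
    r <- runs[[k]][, c("sampleA", "sampleB", "chrom", "start_bp", "end_bp")]
    r$run <- rep(k, nrow(r))
    r
  }))
  if (is.null(all_seg) || nrow(all_seg) == 0L)
    return(data.frame(sampleA = character(0), sampleB = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0)))
  all_seg$pid <- pair_id(all_seg$sampleA, all_seg$sampleB)
  groups <- split(seq_len(nrow(all_seg)),
                  paste(all_seg$pid, all_seg$chrom, sep = "@"))
  out_a <- character(0); out_b <- character(0); out_ch <- character(0)
  out_s <- numeric(0); out_e <- numeric(0)
  for (key in names(groups)) {
    idx <- groups[[key]]
    # a run may report overlapping segments; merge per run so each run
    # counts at most once per bp, then sweep the +-1 coverage events
    pos <- numeric(0); d <- integer(0)
    for (k in unique(all_seg$run[idx])) {
      ki <- idx[all_seg$run[idx] == k]
      s <- all_seg$start_bp[ki]; e <- all_seg$end_bp[ki]
      o <- order(s)
      s <- s[o]; e <- cummax(e[o])
      new_run <- c(TRUE, s[-1] > e[-length(e)])
      grp <- cumsum(new_run)
      ms <- tapply(s, grp, min); me <- tapply(e, grp, max)
      pos <- c(pos, ms, me)
      d <- c(d, rep(1L, length(ms)), rep(-1L, length(me)))
    }
    o <- order(pos, -d)
    cov <- cumsum(d[o])
    pos <- pos[o]
    above <- cov >= min_runs
    rises <- which(above & !c(FALSE, above[-length(above)]))
    drops <- which(!above & c(FALSE, above[-length(above)]))
    if (!length(rises)) next
    # collapse zero-length alternations at tied positions
    ss <- pos[rises]; ee <- pos[drops]
    keep <- ee > ss
    ss <- ss[keep]; ee <- ee[keep]
    if (!length(ss)) next
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    ab <- strsplit(parts[1], "|", fixed = TRUE)[[1]]
    out_a <- c(out_a, rep(ab[1], length(ss)))
    out_b <- c(out_b, rep(ab[2], length(ss)))
    out_ch <- c(out_ch, rep(parts[2], length(ss)))
    out_s <- c(out_s, ss); out_e <- c(out_e, ee)
  }
  data.frame(sampleA = out_a, sampleB = out_b, chrom = out_ch,
             start_bp = out_s, end_bp = out_e)
}

#' Drop IBD segments shorter than a genetic length
#' @param segments data.frame with cM coordinates (see [ibd_add_cM()])
#' @param min_cM strict lower bound: segments with length < min_cM are
#'   removed, a segment of exactly min_cM is retained
#' @return filtered segments
#' @export
filter_short <- function(segments, min_cM = 1.0) {
  if (!all(c("start_cM", "end_cM") %in% names(segments)))
    stop("segments lack cM coordinates; run ibd_add_cM() first")
  segments[(segments$end_cM - segments$start_cM) >= min_cM, , drop = FALSE]
}

#' Per-pair IBD sharing totals and cross-population means
#'
#' @param segments data.frame with cM coordinates
#' @param pops [pop_assignment()]
#' @return list: \code{per_pair} (sampleA, sampleB, popA, popB, total_cM,
#'   mean_cM, n_segments) for pairs with sharing, and \code{pop_means}, the
#'   mean per-pair total over all possible pairs (zero-sharing pairs
#'   included) for every population pair
#' @export
pair_sharing <- function(segments, pops) {
  if (nrow(segments) == 0L) {
    labs <- sort(unique(unname(pops)))
    means <- list()
    for (i in seq_along(labs)) for (j in i:length(labs)) {
      na <- sum(pops == labs[i]); nb <- sum(pops == labs[j])
      npairs <- if (i == j) choose(na, 2) else na * nb
      if (npairs == 0) next
      means[[length(means) + 1L]] <- data.frame(
        popA = labs[i], popB = labs[j], n_pairs = npairs, mean_total_cM = 0)
    }
    return(list(per_pair = data.frame(sampleA = character(0),
                                      sampleB = character(0),
                                      popA = character(0), popB = character(0),
                                      total_cM = numeric(0),
                                      mean_cM = numeric(0),
                                      n_segments = numeric(0)),
                pop_means = do.call(rbind, means)))
  }
  segments$length_cM <- segments$end_cM - segments$start_cM
  pid <- pair_id(segments$sampleA, segments$sampleB)
  tot <- tapply(segments$length_cM, pid, sum)
  cnt <- tapply(segments$length_cM, pid, length)
  ab <- do.call(rbind, strsplit(names(tot), "|", fixed = TRUE))
  per <- data.frame(sampleA = ab[, 1], sampleB = ab[, 2],
                    popA = unname(pops[ab[, 1]]), popB = unname(pops[ab[, 2]]),
                    total_cM = as.numeric(tot),
                    mean_cM = as.numeric(tot) / as.numeric(cnt),
                    n_segments = as.numeric(cnt))
  rownames(per) <- NULL
  labs <- sort(unique(unname(pops)))
  means <- list()
  for (i in seq_along(labs)) for (j in i:length(labs)) {
    la <- labs[i]; lb <- labs[j]
    na <- sum(pops == la); nb <- sum(pops == lb)
    npairs <- if (la == lb) choose(na, 2) else na * nb
    if (npairs == 0) next
    sel <- (per$popA == la & per$popB == lb) | (per$popA == lb & per$popB == la)
    means[[length(means) + 1L]] <- data.frame(
      popA = la, popB = lb, n_pairs = npairs,
      mean_total_cM = sum(per$total_cM[sel]) / npairs)
  }
  list(per_pair = per, pop_means = do.call(rbind, means))
}

#' Label long IBD tracts
#' @param segments data.frame with cM coordinates
#' @param thr_cM threshold: long means length strictly greater than thr_cM
#' @return segments with added logical column \code{long}
#' @export
classify_long <- function(segments, thr_cM = 7.0) {
  segments$length_cM <- segments$end_cM - segments$start_cM
  segments$long <- segments$length_cM > thr_cM
  segments
}

#' IBD occurrence in non-overlapping genetic-map windows
#'
#' Windows tile each chromosome from 0 cM in steps of \code{window_cM}
#' (the terminal partial window is retained and flagged). A segment counts
#' once in every window its cM interval overlaps; occurrence is the
#' spanning count divided by the number of possible sample pairs.
#'
#' @param segments data.frame with cM coordinates
#' @param map \code{genetic_map}
#' @param pairs number of possible sample pairs (C(n,2) within a
#'   population, n1*n2 across)
#' @param window_cM window width
#' @return data.frame (chrom, start_cM, end_cM, partial, count, occurrence),
#'   class \code{hotspot_track}
#' @export
hotspot_occurrence <- function(segments, map, pairs, window_cM = 10.0) {
  if (pairs <= 0) stop("pairs must be > 0")
  if (nrow(map) == 0L) stop("empty genetic map")
  out <- list()
  for (ch in unique(map$chrom)) {
    top <- max(map$pos_cM[map$chrom == ch])
    starts <- seq(0, top, by = window_cM)
    starts <- starts[starts < top]
    if (!length(starts)) starts <- 0
    ends <- pmin(starts + window_cM, top)
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    cnt <- vapply(seq_along(starts), function(w)
      sum(seg$start_cM < ends[w] & seg$end_cM > starts[w]), 0)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start_cM = starts, end_cM = ends,
      partial = ends - starts < window_cM,
      count = cnt, occurrence = cnt / pairs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hotspot_track", "data.frame")
  res
}

#' Permutation test for overlap of IBD hotspots with candidate regions
#'
#' The observed statistic is the fraction of top-occurrence windows (the
#' upper \code{1 - top_q} quantile by occurrence, ties broken by genomic
#' order) that overlap any candidate region; the null redraws an equal
#' number of windows uniformly without replacement, and
#' p = (1 + #(null >= observed)) / (1 + n_perm).
#'
#' @param track \code{hotspot_track} from [hotspot_occurrence()]
#' @param regions data.frame chrom/start/end (bp, 0-based half-open)
#' @param map \code{genetic_map} to place windows on the physical axis
#' @param top_q occurrence quantile defining the hotspot set
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list: \code{overlap_fraction}, \code{p_value}, \code{n_top},
#'   \code{window_overlaps} (logical per window)
#' @export
overlap_permutation_test <- function(track, regions, map, top_q = 0.95,
                                     n_perm = 999, seed) {
  nw <- nrow(track)
  if (nw == 0L) stop("empty hotspot track")
  k <- ceiling((1 - top_q) * nw)
  if (k < 1L || k > nw) stop("fewer windows than the top-quantile count")
  # windows to physical space, then flag region overlap
  hit <- logical(nw)
  if (nrow(regions) > 0) {
    for (w in seq_len(nw)) {
      ch <- track$chrom[w]
      b0 <- interpolate_bp(map, ch, track$start_cM[w])
      b1 <- interpolate_bp(map, ch, track$end_cM[w])
      r <- regions[regions$chrom == ch, , drop = FALSE]
      hit[w] <- any(r$start + 1 <= b1 & r$end >= b0)
    }
  }
  ord <- order(-track$occurrence, track$chrom, track$start_cM)
  top <- ord[seq_len(k)]
  obs <- mean(hit[top])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- replicate(n_perm, mean(hit[sample.int(nw, k)]))
  list(overlap_fraction = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       n_top = k, window_overlaps = hit)
}
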