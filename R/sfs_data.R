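#' Variant set: biallelic SNPs with haploid-coded inbred genotypes
#'
#' Loads a VCF of biallelic SNPs. Inbred lines are coded as one haplotype
#' per line: homozygous diploid calls collapse to 0 (ref) or 1 (alt), and
#' heterozygous or missing calls become \code{NA} at that site. Sites whose
#' ALT has more than one allele, or whose REF/ALT are not single bases, are
#' skipped and counted. The annotation class (synonymous / other / unknown)
#' is read from a designated INFO key when present.
#'
#' @param vcf_path path to a VCF (v4.x, GT format field)
#' @param ann_key INFO key carrying the annotation class
#' @return object of class \code{variant_set}: parallel vectors
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt}, \code{ann},
#'   a sites x samples integer genotype matrix \code{geno}, and skip
#'   counters
#' @export
load_variants <- function(vcf_path, ann_key = "ANN") {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    stop(sprintf("malformed POS at record(s): %s",
                 paste(which(is.na(pos)), collapse = ", ")))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !multi &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  ann <- rep("unknown", length(chrom))
  info_ann <- vcfR::extract.info(vcf, element = ann_key)
  if (!all(is.na(info_ann))) {
    ann[!is.na(info_ann)] <- info_ann[!is.na(info_ann)]
    ann[!ann %in% c("synonymous", "other", "unknown")] <- "other"
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  g <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt_clean <- gsub("\\|", "/", gt)
  g[gt_clean %in% c("0/0", "0")] <- 0L
  g[gt_clean %in% c("1/1", "1")] <- 1L
  keep <- which(snp)
  structure(list(chrom = chrom[keep], pos = pos[keep],
                 ref = ref[keep], alt = alt[keep], ann = ann[keep],
                 geno = g[keep, , drop = FALSE],
                 samples = colnames(gt),
                 n_skipped_multiallelic = sum(multi),
                 n_skipped_nonsnp = sum(!snp & !multi)),
            class = "variant_set")
}

#' Construct a variant set in memory (used by the generators and tests)
#' @param chrom,pos,geno site coordinates and sites x samples 0/1/NA matrix
#' @param ref,alt,ann optional per-site fields
#' @return \code{variant_set}
#' @export
variant_set <- function(chrom, pos, geno, ref = NULL, alt = NULL, ann = NULL) {
  ns <- length(pos)
  if (is.null(dim(geno)) && ns == 1L) geno <- matrix(geno, nrow = 1)
  stopifnot(nrow(geno) == ns, length(chrom) == ns, all(pos >= 1))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref %||% rep("A", ns), alt = alt %||% rep("T", ns),
                 ann = ann %||% rep("unknown", ns),
                 geno = geno,
                 samples = colnames(geno) %||% paste0("s", seq_len(ncol(geno))),
                 n_skipped_multiallelic = 0L, n_skipped_nonsnp = 0L),
            class = "variant_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d SNPs x %d samples (%d multi-allelic skipped)\n",
              length(x$pos), ncol(x$geno), x$n_skipped_multiallelic))
  invisible(x)
}

#' Number of sites in a variant set
#' @param v \code{variant_set}
#' @return integer site count
#' @export
n_variants <- function(v) length(v$pos)

#' Subset a variant set by site index
#' @param v \code{variant_set}
#' @param idx integer or logical site index
#' @return \code{variant_set}
#' @export
subset_variants <- function(v, idx) {
  v$chrom <- v$chrom[idx]; v$pos <- v$pos[idx]
  v$ref <- v$ref[idx]; v$alt <- v$alt[idx]; v$ann <- v$ann[idx]
  v$geno <- v$geno[idx, , drop = FALSE]
  v
}

#' Keep only SNPs annotated as synonymous
#' @param v \code{variant_set}
#' @return \code{variant_set} with only synonymous sites, order preserved
#' @export
filter_synonymous <- function(v) {
  if (n_variants(v) > 0 && all(v$ann == "unknown"))
    stop(paste("all annotation classes are unknown; load the VCF with the",
               "INFO key that carries the synonymous/other classification"))
  subset_variants(v, v$ann == "synonymous")
}

#' Read a BED file of regions (0-based half-open)
#' @param path BED path (first three columns used)
#' @return data.frame with chrom, start, end
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  if (any(b$start < 0) || any(b$end < b$start)) stop("malformed BED intervals")
  b[order(b$chrom, b$start), ]
}

#' Drop SNPs inside excluded regions
#'
#' Regions are 0-based half-open: the interval [start, end) removes 1-based
#' positions start+1 .. end. Region chromosomes absent from the variant set
#' raise a warning and are ignored.
#'
#' @param v \code{variant_set}
#' @param regions data.frame chrom/start/end as from [read_bed()]
#' @return filtered \code{variant_set}
#' @export
exclude_regions <- function(v, regions) {
  if (nrow(regions) == 0L) return(v)
  unknown <- setdiff(unique(regions$chrom), unique(v$chrom))
  if (length(unknown)) {
    warning("regions on chromosome(s) absent from the variants ignored: ",
            paste(unknown, collapse = ", "))
    regions <- regions[!regions$chrom %in% unknown, , drop = FALSE]
    if (nrow(regions) == 0L) return(v)
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  vg <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hit <- GenomicRanges::countOverlaps(vg, rg) > 0L
  subset_variants(v, !hit)
}

#' Distance thinning of SNPs, replicated
#'
#' Per replicate, sites are visited in a random sweep order and accepted
#' greedily when no previously accepted site on the same chromosome lies
#' within \code{min_bp}; every retained pair therefore sits >= min_bp
#' apart. Replicates differ through their sweep order but are reproducible
#' from (seed, replicate index).
#'
#' @param v \code{variant_set} sorted by (chrom, pos)
#' @param min_bp minimum pairwise distance, bp
#' @param reps number of independent thinning replicates
#' @param seed integer seed
#' @param order \code{"random"} (default) or \code{"sweep"} for a
#'   deterministic left-to-right pass
#' @return list of \code{variant_set} replicates; each carries attributes
#'   \code{seed} and \code{replicate}
#' @export
thin_variants <- function(v, min_bp = 2000, reps = 10, seed,
                          order = c("random", "sweep")) {
  order <- match.arg(order)
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_along(o))) stop("variants must be sorted by (chrom, pos)")
  out <- vector("list", reps)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    visit <- if (order == "random") sample.int(n_variants(v)) else seq_len(n_variants(v))
    accepted <- logical(n_variants(v))
    acc_by_chrom <- list()
    for (s in visit) {
      ch <- v$chrom[s]
      ps <- v$pos[s]
      near <- acc_by_chrom[[ch]]
      if (is.null(near) || all(abs(near - ps) >= min_bp)) {
        accepted[s] <- TRUE
        acc_by_chrom[[ch]] <- c(near, ps)
      }
    }
    rv <- subset_variants(v, accepted)
    attr(rv, "seed") <- seed
    attr(rv, "replicate") <- r
    out[[r]] <- rv
  }
  out
}

#' Population assignment
#'
#' @param samples character vector of sample names
#' @param pop character vector of population labels, parallel to samples
#' @param threshold membership-probability threshold used upstream when the
#'   assignment was made (recorded only)
#' @return named character vector sample -> population with attribute
#'   \code{threshold}
#' @export
pop_assignment <- function(samples, pop, threshold = 0.60) {
  if (length(samples) != length(pop)) stop("samples and pop differ in length")
  if (anyDuplicated(samples)) stop("each sample must be assigned exactly once")
  structure(stats::setNames(as.character(pop), samples), threshold = threshold)
}

#' Read a two-column sample/population file
#' @param path TSV with columns sample, pop (no header)
#' @return [pop_assignment()]
#' @export
read_pops <- function(path) {
  p <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("sample", "pop"),
                         colClasses = "character")
  pop_assignment(p$sample, p$pop)
}

# cached hypergeometric projection weights for one site
site_proj_weights <- local({
  cache <- new.env(parent = emptyenv())
  function(count, size, m) {
    key <- paste(count, size, m, sep = ":")
    w <- cache[[key]]
    if (is.null(w)) {
      w <- stats::dhyper(0:m, count, size - count, m)
      cache[[key]] <- w
    }
    w
  }
})

#' Build the observed joint SFS from genotypes
#'
#' Per site, alt-allele counts are taken over non-missing haplotypes in
#' each of the two populations and spread onto the projected sample sizes
#' with hypergeometric weights; projected masses accumulate into the
#' spectrum and the monomorphic corners are masked. Sites with fewer
#' non-missing haplotypes than the projection size in either population are
#' dropped and counted. With \code{polarization = "unfolded"} the alt
#' allele is taken as derived; the default folds the spectrum.
#'
#' @param v \code{variant_set}
#' @param pops [pop_assignment()] covering the samples to use
#' @param pop_pair length-2 character: the two population labels, in
#'   (pop1, pop2) order
#' @param proj length-2 integer: projected haplotype counts
#' @param polarization \code{"folded"} or \code{"unfolded"}
#' @return \code{joint_sfs} with attribute \code{dropped_sites}
#' @export
joint_sfs_from_genotypes <- function(v, pops, pop_pair = NULL,
                                     proj = c(60, 60),
                                     polarization = c("folded", "unfolded")) {
  polarization <- match.arg(polarization)
  pops <- pops[names(pops) %in% v$samples]
  if (is.null(pop_pair)) pop_pair <- unique(unname(pops))
  if (length(pop_pair) != 2L) stop("exactly two populations are required")
  s1 <- names(pops)[pops == pop_pair[1]]
  s2 <- names(pops)[pops == pop_pair[2]]
  if (!length(s1) || !length(s2)) stop("both populations must have samples")
  g1 <- v$geno[, s1, drop = FALSE]
  g2 <- v$geno[, s2, drop = FALSE]
  m1 <- as.integer(proj[1]); m2 <- as.integer(proj[2])
  acc <- matrix(0, m1 + 1L, m2 + 1L)
  dropped <- 0L
  for (s in seq_len(n_variants(v))) {
    x1 <- g1[s, ]; x2 <- g2[s, ]
    n1s <- sum(!is.na(x1)); n2s <- sum(!is.na(x2))
    if (n1s < m1 || n2s < m2) { dropped <- dropped + 1L; next }
    c1 <- sum(x1, na.rm = TRUE); c2 <- sum(x2, na.rm = TRUE)
    acc <- acc + outer(site_proj_weights(c1, n1s, m1),
                       site_proj_weights(c2, n2s, m2))
  }
  out <- joint_sfs(acc)
  if (polarization == "folded") out <- fold_sfs(out)
  attr(out, "dropped_sites") <- dropped
  out
}
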