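# shared fixtures for the suite

MU_REF <- 2.230e-8
L_REF <- 3.8e6

neutral_tl <- function() build_timeline(scaled_params("neutral"))

# a small two-deme piecewise-constant model for oracle cross-checks
toy_split <- function(nu1 = 0.5, nu2 = 0.3, tau = 0.3, M = 1.5) {
  build_timeline(scaled_params("split1", nu1 = nu1, nu2 = nu2,
                               tau = tau, M = M))
}

# draw a Poisson-sampled observed spectrum around an expectation
poisson_sfs <- function(expected, seed) {
  m <- unclass(expected)
  ok <- !is.na(m)
  set.seed(seed)
  m[ok] <- stats::rpois(sum(ok), m[ok])
  joint_sfs(m, folded = attr(expected, "folded"))
}

# toy variant set: sites x samples matrix given directly
toy_variants <- function(geno, pos = NULL, chrom = "chr1", ann = NULL) {
  ns <- nrow(geno)
  variant_set(rep(chrom, ns), pos %||% (seq_len(ns) * 1000L), geno, ann = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
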