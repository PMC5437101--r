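#' Synthetic parameter-recovery protocol for the split model
#'
#' Validates the whole inference path (coalescent engine, Poisson composite
#' likelihood, optimizer, unit conversion) by self-consistency: an expected
#' joint spectrum is generated under the reference two-bottleneck split
#' history at its published physical parameter values, and each focal
#' parameter is then re-estimated with every other parameter pinned at its
#' true value.
#'
#' The "observed" spectrum and every candidate-model spectrum during the
#' refit share one replicate seed stream (common random numbers). This is
#' the standard device of simulated-likelihood inference: it makes the
#' Monte Carlo objective a deterministic function of the parameters and
#' puts its maximum at the generating values, so the protocol checks that
#' the optimizer, the profiled-theta likelihood and the scaled-to-physical
#' conversions reproduce the truth - engine correctness itself is
#' established separately against the exact small-sample oracle. With
#' independent streams the weak signals (notably the 5-generation
#' bottleneck, whose total coalescent intensity is below 2%) would drown in
#' Monte Carlo noise at desk-scale replicate counts.
#'
#' @param focal which quantity to re-estimate, see Details
#' @param cfg [coalescent_config()] shared by the data spectrum and the
#'   refit (the common-random-numbers stream)
#' @param data optional precomputed spectrum from
#'   [split5_synthetic_sfs()] with the same \code{cfg}
#' @param mu,L mutation rate and effective length for unit conversion
#' @param proj haplotype sample sizes of the spectrum
#'
#' @details Focal quantities and their units:
#' \describe{
#'   \item{ancestral_size}{Na, individuals, via profiled theta only}
#'   \item{onset_sizes}{sum of the two post-split onset sizes, individuals
#'     (both onset parameters fitted jointly)}
#'   \item{founder_size}{temperate founder size at the split, individuals}
#'   \item{bottleneck_size}{pre-split bottleneck size, individuals
#'     (duration pinned at truth)}
#'   \item{ts_decline / nss_decline}{percent decline of the deme over the
#'     linear-shrinking stage, from the fitted end size}
#'   \item{divergence_duration / shrink_duration}{stage durations in years
#'     (one generation per year)}
#'   \item{migration_m1 / migration_m2}{scaled gene-flow rates of the two
#'     post-split stages}
#' }
#' @return list: \code{focal}, \code{estimate}, \code{truth},
#'   \code{units}, \code{fit} (the underlying [fit_model()] result; NULL
#'   for \code{ancestral_size})
#' @export
split5_recovery <- function(focal = c("ancestral_size", "onset_sizes",
                                      "founder_size", "bottleneck_size",
                                      "ts_decline", "nss_decline",
                                      "divergence_duration",
                                      "shrink_duration",
                                      "migration_m1", "migration_m2"),
                            cfg, data = NULL,
                            mu = 2.230e-8, L = 3.8e6, proj = c(20, 20)) {
  focal <- match.arg(focal)
  ref <- split5_reference_fit(mu = mu, L = L)
  truth <- ref$scaled
  if (is.null(data)) data <- split5_synthetic_sfs(cfg, mu = mu, L = L,
                                                  proj = proj)
  free <- switch(focal,
    ancestral_size = character(0),
    onset_sizes = c("nuTS0", "nuNSS0"),
    founder_size = "nuNSS0",
    bottleneck_size = "nuB",
    ts_decline = "nuTS1",
    nss_decline = "nuNSS1",
    divergence_duration = "tau2",
    shrink_duration = "tau3",
    migration_m1 = "M1",
    migration_m2 = "M2")
  fixed <- truth$params[setdiff(names(truth$params), free)]
  starts <- if (length(free))
    list(truth$params[free] * 0.3, truth$params[free] * 3) else NULL
  fit <- fit_model("split5", data, free = free, fixed = fixed,
                   starts = starts, engine = "mc", cfg = cfg)
  Na <- fit$theta / (4 * mu * L)
  est <- switch(focal,
    ancestral_size = Na,
    onset_sizes = unname(sum(fit$params$params[c("nuTS0", "nuNSS0")])) * Na,
    founder_size = unname(fit$params$params["nuNSS0"]) * Na,
    bottleneck_size = unname(fit$params$params["nuB"]) * Na,
    ts_decline = 100 * (1 - unname(fit$params$params["nuTS1"]) /
                          truth$params[["nuTS0"]]),
    nss_decline = 100 * (1 - unname(fit$params$params["nuNSS1"]) /
                           truth$params[["nuNSS0"]]),
    divergence_duration = unname(fit$params$params["tau2"]) * 2 * Na,
    shrink_duration = unname(fit$params$params["tau3"]) * 2 * Na,
    migration_m1 = unname(fit$params$params["M1"]),
    migration_m2 = unname(fit$params$params["M2"]))
  tru <- switch(focal,
    ancestral_size = 24162, onset_sizes = 10746, founder_size = 1312,
    bottleneck_size = 142, ts_decline = 25, nss_decline = 65,
    divergence_duration = 126, shrink_duration = 4832,
    migration_m1 = 4.3e-3, migration_m2 = 1.2e-3)
  units <- switch(focal,
    ancestral_size = , onset_sizes = , founder_size = ,
    bottleneck_size = "individuals",
    ts_decline = , nss_decline = "percent",
    divergence_duration = "years", shrink_duration = "years",
    migration_m1 = , migration_m2 = "2*Na*m")
  list(focal = focal, estimate = est, truth = tru, units = units, fit = fit)
}

#' Synthetic "observed" spectrum at the reference split parameters
#'
#' The expected joint SFS of the reference two-bottleneck split history at
#' theta = 4*Na*mu*L, computed directly at the projected sample sizes
#' (for exchangeable samples the expected spectrum at 20x20 equals the
#' hypergeometric projection of any larger panel's expectation).
#'
#' @param cfg [coalescent_config()]
#' @param mu,L mutation model
#' @param proj haplotype sample sizes
#' @return \code{joint_sfs}
#' @export
split5_synthetic_sfs <- function(cfg, mu = 2.230e-8, L = 3.8e6,
                                 proj = c(20, 20)) {
  ref <- split5_reference_fit(mu = mu, L = L)
  model_spectrum(ref$scaled, proj[1], proj[2], theta = ref$scaled$theta,
                 engine = "mc", cfg = cfg)
}
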