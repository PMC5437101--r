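#' Poisson composite log-likelihood of a joint SFS
#'
#' Cells are treated as independent Poisson counts: the log-likelihood is
#' the sum over unmasked cells of \code{S*log(M) - M - log(S!)} where S is
#' the observed and M the model expectation. A cell with M = 0 but S > 0
#' contributes \code{-Inf}.
#'
#' @param model,data \code{joint_sfs} objects of identical shape and mask
#' @return scalar log-likelihood
#' @export
poisson_loglik <- function(model, data) {
  stopifnot_sfs(model); stopifnot_sfs(data)
  if (!identical(dim(model), dim(data)))
    stop("model and data spectra differ in shape")
  mm <- unclass(model); dd <- unclass(data)
  if (!identical(is.na(mm), is.na(dd)))
    stop("model and data spectra differ in mask")
  ok <- !is.na(mm)
  M <- mm[ok]; S <- dd[ok]
  if (any(S < 0) || any(M < 0)) stop("negative spectrum entries")
  if (any(M == 0 & S > 0)) return(-Inf)
  pos <- M > 0
  sum(S[pos] * log(M[pos]) - M[pos] - lgamma(S[pos] + 1))
}

#' Profile-optimal theta for a model spectrum shape
#'
#' With the model spectrum linear in theta, the Poisson composite likelihood
#' is maximized analytically at \code{theta_hat = sum(S) / sum(M)} over the
#' unmasked cells, where M is the shape computed at theta = 1.
#'
#' @param model_shape \code{joint_sfs} computed at theta = 1
#' @param data observed \code{joint_sfs}
#' @return scalar theta estimate
#' @export
optimal_theta <- function(model_shape, data) {
  stopifnot_sfs(model_shape); stopifnot_sfs(data)
  tm <- sfs_total(model_shape)
  if (tm <= 0) stop("model shape has zero unmasked mass")
  sfs_total(data) / tm
}

#' Anscombe residuals between model and data spectra
#'
#' Variance-stabilized Poisson residuals
#' \code{r = 1.5 * (S^(2/3) - M^(2/3)) / M^(1/6)} per unmasked cell; cells
#' with M = 0 are reported as \code{NaN} (undefined), masked cells as
#' \code{NA}.
#'
#' @param model,data \code{joint_sfs} objects of identical shape
#' @return matrix of residuals
#' @export
anscombe_residuals <- function(model, data) {
  stopifnot_sfs(model); stopifnot_sfs(data)
  if (!identical(dim(model), dim(data)))
    stop("model and data spectra differ in shape")
  M <- unclass(model); S <- unclass(data)
  r <- 1.5 * (S^(2 / 3) - M^(2 / 3)) / M^(1 / 6)
  r[!is.na(M) & M == 0] <- NaN
  r
}

#' Likelihood-ratio test for nested models
#'
#' @param ll_null,ll_alt log-likelihoods of the nested (null) and nesting
#'   (alternative) model
#' @param df difference in free parameter count (>= 1)
#' @param tol tolerance for a slightly negative statistic from optimizer
#'   noise
#' @return upper-tail chi-square p-value of 2*(ll_alt - ll_null)
#' @export
lrt <- function(ll_null, ll_alt, df, tol = 1e-6) {
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (ll_alt - ll_null)
  if (stat < -tol) stop("alternative log-likelihood below null beyond tolerance")
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Akaike information criterion
#' @param ll log-likelihood
#' @param k number of free parameters
#' @return 2k - 2*ll
#' @export
aic <- function(ll, k) {
  if (k < 0) stop("k must be >= 0")
  2 * k - 2 * ll
}

#' Model spectrum at given parameters
#'
#' Computes the expected joint SFS for a model at unit theta, dispatching to
#' the deterministic one-population path, the exact small-sample oracle, or
#' the Monte Carlo engine.
#'
#' @param params [scaled_params()]
#' @param n1,n2 haplotype sample sizes
#' @param theta scaled mutation supply
#' @param engine \code{"auto"} (deterministic for one-deme models, Monte
#'   Carlo otherwise), \code{"onepop"}, \code{"exact"} or \code{"mc"}
#' @param cfg [coalescent_config()], required for the Monte Carlo engine
#' @param folded fold the spectrum before returning
#' @return \code{joint_sfs}
#' @export
model_spectrum <- function(params, n1, n2 = 0, theta = 1,
                           engine = c("auto", "onepop", "exact", "mc"),
                           cfg = NULL, folded = FALSE) {
  engine <- match.arg(engine)
  tl <- build_timeline(params)
  if (engine == "auto")
    engine <- if (timeline_ndemes(tl) == 1L) "onepop" else "mc"
  out <- switch(engine,
    onepop = expected_sfs_onepop(tl, n1, theta),
    exact = exact_small_sfs(tl, n1, n2, theta),
    mc = {
      if (is.null(cfg)) stop("the Monte Carlo engine requires a coalescent_config")
      expected_joint_sfs(tl, n1, n2, theta, cfg)
    })
  if (folded) out <- fold_sfs(out)
  out
}

#' Fit a demographic model to an observed joint SFS
#'
#' Maximizes the Poisson composite likelihood over the chosen free
#' parameters by Nelder-Mead on log-transformed parameters (golden-section
#' search for a single free parameter), with theta profiled analytically at
#' every evaluation. Parameters named in \code{fixed} are held constant, so
#' constrained refits (e.g. one focal parameter with the rest pinned) use
#' the same entry point as full fits. By default each start set is doubled
#' with a companion one order of magnitude away.
#'
#' When the Monte Carlo engine is used, the replicate stream is re-seeded
#' identically at every evaluation (common random numbers), making the
#' objective deterministic in the parameters.
#'
#' @param model_id one of [model_ids()]
#' @param data observed \code{joint_sfs}
#' @param free names of parameters to optimize; default all not in
#'   \code{fixed}
#' @param fixed named numeric of parameters held at given values
#' @param starts list of named numeric start vectors for the free
#'   parameters; default: a unit-scale guess and the same shifted one order
#'   of magnitude
#' @param engine,cfg passed to [model_spectrum()]
#' @param lower,upper box bounds applied to every free parameter
#' @param ll_tol convergence tolerance on the log-likelihood
#' @param max_eval maximum objective evaluations per start
#' @return object of class \code{fit_result}: best parameters (full vector,
#'   fixed included), profiled theta, log-likelihood, AIC with
#'   \code{k = n_free + 1} (the profiled theta counts as free), per-start
#'   trace, and the best model spectrum
#' @export
fit_model <- function(model_id, data, free = NULL, fixed = NULL,
                      starts = NULL,
                      engine = c("auto", "onepop", "exact", "mc"), cfg = NULL,
                      lower = 1e-6, upper = 1e4,
                      ll_tol = 1e-8, max_eval = 1e4) {
  engine <- match.arg(engine)
  stopifnot_sfs(data)
  model_id <- match.arg(model_id, model_ids())
  pnames <- model_param_names(model_id)
  fixed <- unlist(fixed)
  if (length(fixed) && !all(names(fixed) %in% pnames))
    stop("unknown fixed parameter name")
  if (is.null(free)) free <- setdiff(pnames, names(fixed))
  if (!all(free %in% pnames)) stop("unknown free parameter name")
  if (length(intersect(free, names(fixed))))
    stop("a parameter cannot be both free and fixed")
  if (!setequal(c(free, names(fixed)), pnames))
    stop("free + fixed must cover all model parameters")
  n <- sfs_sizes(data)
  folded <- attr(data, "folded")

  default_start <- function(nm) {
    if (startsWith(nm, "nu")) 0.5 else if (startsWith(nm, "tau")) 0.1 else 0.5
  }
  if (is.null(starts)) {
    base <- vapply(free, default_start, 0)
    starts <- list(base, base * 10)
  }
  starts <- lapply(starts, function(s) {
    s <- unlist(s)
    if (is.null(names(s)) && length(s) == length(free)) names(s) <- free
    if (!setequal(names(s), free)) stop("start vector names must match free parameters")
    pmin(pmax(s[free], lower), upper)
  })
  if (length(free) > 0L && length(starts) < 2L)
    stop("at least two starts are required")

  objective <- function(logp) {
    vals <- exp(logp)
    names(vals) <- free
    full <- c(vals, fixed)[pnames]
    sp <- scaled_params(model_id, full)
    shape <- model_spectrum(sp, n[1], n[2], theta = 1,
                            engine = engine, cfg = cfg, folded = folded)
    th <- optimal_theta(shape, data)
    ll <- poisson_loglik(joint_sfs(th * unclass(shape), folded = folded), data)
    if (!is.finite(ll)) ll <- -1e300
    -ll
  }

  trace <- list()
  best <- NULL
  if (length(free) == 0L) {
    # pure profile fit: only theta is free
    full <- fixed[pnames]
    sp <- scaled_params(model_id, full)
    shape <- model_spectrum(sp, n[1], n[2], theta = 1,
                            engine = engine, cfg = cfg, folded = folded)
    th <- optimal_theta(shape, data)
    ll <- poisson_loglik(joint_sfs(th * unclass(shape), folded = folded), data)
    best <- list(par = numeric(0), value = -ll, convergence = 0L, evals = 1L)
    trace[[1]] <- list(start = numeric(0), loglik = ll, convergence = 0L, evals = 1L)
  } else {
    if (length(free) == 1L) {
      # one free parameter: bracket the optimum by a coarse scan over the
      # union of the start points, zoom once, then refine by golden-section
      lo <- log(max(min(unlist(starts)) / 30, lower))
      hi <- log(min(max(unlist(starts)) * 30, upper))
      grid <- seq(lo, hi, length.out = 19)
      gv <- vapply(grid, objective, 0)
      b <- which.min(gv)
      span <- c(grid[max(1L, b - 1L)], grid[min(length(grid), b + 1L)])
      zoom <- seq(span[1], span[2], length.out = 11)
      zv <- vapply(zoom, objective, 0)
      zb <- which.min(zv)
      zspan <- c(zoom[max(1L, zb - 1L)], zoom[min(length(zoom), zb + 1L)])
      op <- stats::optimize(objective, interval = zspan, tol = 1e-6)
      cand_par <- c(grid[b], zoom[zb], op$minimum)
      cand_val <- c(gv[b], zv[zb], op$objective)
      pick <- which.min(cand_val)
      res <- list(par = cand_par[pick], value = cand_val[pick],
                  convergence = 0L, evals = length(grid) + length(zoom) + 30L)
      trace[[1]] <- list(start = starts[[1]], loglik = -res$value,
                         convergence = 0L, evals = res$evals)
      best <- res
    } else {
    for (s in seq_along(starts)) {
      st <- starts[[s]]
      {
        op <- stats::optim(log(st), objective, method = "Nelder-Mead",
                           control = list(maxit = max_eval, reltol = ll_tol))
        res <- list(par = op$par, value = op$value,
                    convergence = op$convergence, evals = op$counts[["function"]])
      }
      trace[[s]] <- list(start = st, loglik = -res$value,
                         convergence = res$convergence, evals = res$evals)
      if (is.null(best) || res$value < best$value) best <- res
    }
    # one restart from the incumbent guards against premature collapse of
    # the simplex on rugged surfaces
    op <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = max_eval, reltol = ll_tol))
    if (op$value < best$value)
      best <- list(par = op$par, value = op$value,
                   convergence = op$convergence,
                   evals = op$counts[["function"]])
    }
  }

  vals <- exp(best$par)
  names(vals) <- free
  full <- c(vals, fixed)[pnames]
  names(full) <- pnames
  sp <- scaled_params(model_id, full)
  shape <- model_spectrum(sp, n[1], n[2], theta = 1,
                          engine = engine, cfg = cfg, folded = folded)
  th <- optimal_theta(shape, data)
  expected <- joint_sfs(th * unclass(shape), folded = folded)
  ll <- poisson_loglik(expected, data)
  k <- length(free) + 1L
  on_bound <- length(free) > 0L &&
    any(vals <= lower * (1 + 1e-6) | vals >= upper * (1 - 1e-6))
  if (on_bound) warning("best fit lies on a parameter bound")
  structure(list(model_id = model_id,
                 params = scaled_params(model_id, full, theta = th),
                 free = free, fixed = fixed,
                 theta = th, loglik = ll, k = k, aic = aic(ll, k),
                 expected = expected, on_bound = on_bound,
                 engine = engine,
                 seed = if (!is.null(cfg)) cfg$seed else NA_integer_,
                 trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: loglik = %.4f, theta = %.6g, AIC = %.4f (k = %d)\n",
              x$model_id, x$loglik, x$theta, x$aic, x$k))
  if (length(x$free))
    cat("  free:", paste(sprintf("%s = %.6g", x$free,
                                 x$params$params[x$free]), collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), collapse = ", "), "\n")
  if (x$on_bound) cat("  NOTE: best fit on a parameter bound\n")
  invisible(x)
}

#' Parametric bootstrap confidence intervals for a fit
#'
#' Resamples every unmasked cell of the fitted expectation as Poisson, refits
#' with the same free/fixed configuration (started at the point estimate),
#' and reports percentile intervals for the free parameters and theta; when
#' \code{mu} and \code{L} are given, intervals are also reported in physical
#' units (individuals for sizes, years for durations).
#'
#' @param fit a [fit_model()] result
#' @param n_boot number of bootstrap replicates (0 gives empty intervals)
#' @param seed integer seed
#' @param level confidence level
#' @param mu,L optional mutation rate and effective length for physical-unit
#'   intervals
#' @param max_fail_frac abort if more than this fraction of refits fail
#' @param ... passed through to [fit_model()] (e.g. engine, cfg)
#' @return list with \code{scaled} (matrix of lower/upper per parameter),
#'   \code{physical} (or NULL), \code{draws} (matrix of bootstrap estimates)
#' @export
bootstrap_ci <- function(fit, n_boot, seed, level = 0.95,
                         mu = NULL, L = NULL, max_fail_frac = 0.2, ...) {
  if (!inherits(fit, "fit_result")) stop("expected a fit_result")
  cols <- c(fit$free, "theta")
  if (n_boot == 0)
    return(list(scaled = matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("lower", "upper"))),
                physical = NULL,
                draws = matrix(numeric(0), 0, length(cols),
                               dimnames = list(NULL, cols))))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Mhat <- unclass(fit$expected)
  ok <- !is.na(Mhat)
  start_pt <- fit$params$params[fit$free]
  draws <- matrix(NA_real_, n_boot, length(cols), dimnames = list(NULL, cols))
  fails <- 0L
  for (b in seq_len(n_boot)) {
    bm <- Mhat
    bm[ok] <- stats::rpois(sum(ok), Mhat[ok])
    bdata <- joint_sfs(bm, folded = attr(fit$expected, "folded"))
    bf <- tryCatch(
      fit_model(fit$model_id, bdata, free = fit$free, fixed = fit$fixed,
                starts = list(start_pt, start_pt * 10), ...),
      error = function(e) NULL)
    if (is.null(bf)) { fails <- fails + 1L; next }
    draws[b, ] <- c(bf$params$params[fit$free], bf$theta)
  }
  if (fails / n_boot > max_fail_frac)
    stop(sprintf("bootstrap aborted: %d of %d refits failed", fails, n_boot))
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  phys <- NULL
  if (!is.null(mu) && !is.null(L)) {
    Na <- draws[, "theta"] / (4 * mu * L)
    pd <- matrix(NA_real_, nrow(draws), length(cols),
                 dimnames = list(NULL, cols))
    for (nm in fit$free) {
      pd[, nm] <- if (startsWith(nm, "nu")) draws[, nm] * Na
                  else if (startsWith(nm, "tau")) draws[, nm] * 2 * Na
                  else draws[, nm]
    }
    pd[, "theta"] <- Na
    colnames(pd)[ncol(pd)] <- "Na"
    phys <- t(apply(pd, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
    colnames(phys) <- c("lower", "upper")
  }
  list(scaled = ci, physical = phys, draws = draws)
}
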