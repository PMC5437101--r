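#' Demographic models for the tropical-temperate maize split
#'
#' Eight models are defined. Three single-population models describe the
#' history of one deme: \code{neutral} (constant size), \code{two_epoch}
#' (one instantaneous size change), \code{three_epoch} (a bottleneck of
#' finite duration followed by a recovery epoch). Five two-population models
#' describe the split of the temperate (NSS) deme from the tropical (TS)
#' deme: \code{split1} (instantaneous size change in both demes at the onset
#' of the split, symmetric gene flow), \code{split2} (adds an ancestral size
#' change before the split), \code{split3} (adds a post-split size change in
#' the NSS deme), \code{split4} (a pre-split bottleneck with exponential
#' regrowth), and \code{split5} (two successive bottlenecks - domestication
#' then the temperate founder event - a constant divergence stage with gene
#' flow, and a closing stage in which both demes decline linearly with a
#' second gene-flow rate).
#'
#' All parameters are in coalescent diffusion scaling: relative sizes
#' \code{nu} in units of the ancestral size Na, durations \code{tau} in
#' units of 2*Na generations, migration \code{M = 2*Na*m} where \code{m} is
#' the per-generation fraction of a deme replaced by migrants.
#'
#' @name demographic-models
NULL

# parameter names per model, in canonical order (theta handled separately)
MODEL_PARAMS <- list(
  neutral     = character(0),
  two_epoch   = c("nu", "tau"),
  three_epoch = c("nuB", "nuF", "tauB", "tauF"),
  split1      = c("nu1", "nu2", "tau", "M"),
  split2      = c("nuPre", "tauPre", "nu1", "nu2", "tau", "M"),
  split3      = c("nu1", "nu2a", "nu2b", "tauA", "tauB", "M"),
  split4      = c("nuB", "nuF", "tauPre", "nu1", "nu2", "tau", "M"),
  split5      = c("nuB", "tau1", "nuTS0", "nuNSS0", "tau2", "M1",
                  "nuTS1", "nuNSS1", "tau3", "M2")
)

#' List defined demographic models
#' @return character vector of model identifiers
#' @export
model_ids <- function() names(MODEL_PARAMS)

#' Number of demes a model describes
#' @param model_id one of [model_ids()]
#' @return 1 or 2
#' @export
model_ndemes <- function(model_id) {
  match.arg(model_id, model_ids())
  if (startsWith(model_id, "split")) 2L else 1L
}

#' Free parameters of a model
#' @param model_id one of [model_ids()]
#' @return character vector of parameter names (excluding theta)
#' @export
model_param_names <- function(model_id) {
  MODEL_PARAMS[[match.arg(model_id, model_ids())]]
}

#' Scaled (coalescent-unit) model parameters
#'
#' @param model_id one of [model_ids()]
#' @param ... named parameter values, or a single named vector/list; names
#'   must match [model_param_names()] exactly.
#' @param theta optional scaled mutation supply 4*Na*mu*L; may be left
#'   \code{NULL} when theta is profiled out during fitting.
#' @return object of class \code{scaled_params}
#' @export
scaled_params <- function(model_id, ..., theta = NULL) {
  model_id <- match.arg(model_id, model_ids())
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || !is.null(names(dots[[1]]))))
    dots <- as.list(dots[[1]])
  vals <- unlist(dots)
  if (is.null(vals)) vals <- numeric(0)
  want <- MODEL_PARAMS[[model_id]]
  if (!setequal(names(vals), want) || length(vals) != length(want))
    stop(sprintf("model '%s' requires parameters: %s", model_id,
                 paste(want, collapse = ", ")))
  vals <- vals[want]
  names(vals) <- want
  nus  <- vals[startsWith(names(vals), "nu")]
  taus <- vals[startsWith(names(vals), "tau")]
  Ms   <- vals[startsWith(names(vals), "M")]
  if (any(nus <= 0)) stop("all relative sizes nu must be > 0")
  if (any(taus < 0)) stop("all durations tau must be >= 0")
  if (any(Ms < 0)) stop("all migration rates M must be >= 0")
  if (!is.null(theta) && theta <= 0) stop("theta must be > 0 when present")
  structure(list(model_id = model_id, params = vals, theta = theta),
            class = "scaled_params")
}

#' @export
print.scaled_params <- function(x, ...) {
  cat(sprintf("scaled_params [%s]%s\n", x$model_id,
              if (is.null(x$theta)) "" else sprintf(", theta = %.6g", x$theta)))
  if (length(x$params)) print(x$params)
  invisible(x)
}

epoch <- function(duration, sizes, mig = NULL) {
  # sizes: list of per-deme list(type, start, end); start = ancient edge
  nd <- length(sizes)
  if (is.null(mig)) mig <- matrix(0, nd, nd)
  for (s in sizes) {
    if (!s$type %in% c("constant", "linear", "exponential"))
      stop("unknown size-function type")
    if (s$start <= 0 || s$end <= 0)
      stop("deme size must stay strictly positive over every epoch")
  }
  list(duration = duration, ndemes = nd, sizes = sizes, mig = mig)
}

const_size <- function(nu) list(type = "constant", start = nu, end = nu)
lin_size   <- function(from, to) list(type = "linear", start = from, end = to)
exp_size   <- function(from, to) list(type = "exponential", start = from, end = to)

sym_mig <- function(M) matrix(c(0, M, M, 0), 2, 2)

#' Build an explicit epoch timeline from scaled parameters
#'
#' Timelines are ordered past to present. The first epoch is the ancestral
#' equilibrium (one deme of relative size 1, infinite duration). Each
#' subsequent epoch records its duration (units of 2*Na generations), the
#' per-deme size function of forward time across the epoch (constant, linear
#' or exponential, with sizes at the ancient and recent edge), and the
#' scaled migration matrix \code{M[i,j] = 2*Na*m[i,j]} (forward migration
#' into deme i from deme j). Split models change deme count 1 -> 2 exactly
#' once.
#'
#' @param params a [scaled_params()] object
#' @return object of class \code{demog_timeline}
#' @export
build_timeline <- function(params) {
  if (!inherits(params, "scaled_params")) stop("expected scaled_params")
  p <- as.list(params$params)
  anc <- epoch(Inf, list(const_size(1)))
  eps <- switch(params$model_id,
    neutral = list(anc),
    two_epoch = list(anc, epoch(p$tau, list(const_size(p$nu)))),
    three_epoch = list(anc,
                       epoch(p$tauB, list(const_size(p$nuB))),
                       epoch(p$tauF, list(const_size(p$nuF)))),
    split1 = list(anc,
                  epoch(p$tau, list(const_size(p$nu1), const_size(p$nu2)),
                        sym_mig(p$M))),
    split2 = list(anc,
                  epoch(p$tauPre, list(const_size(p$nuPre))),
                  epoch(p$tau, list(const_size(p$nu1), const_size(p$nu2)),
                        sym_mig(p$M))),
    split3 = list(anc,
                  epoch(p$tauA, list(const_size(p$nu1), const_size(p$nu2a)),
                        sym_mig(p$M)),
                  epoch(p$tauB, list(const_size(p$nu1), const_size(p$nu2b)),
                        sym_mig(p$M))),
    split4 = list(anc,
                  epoch(p$tauPre, list(exp_size(p$nuB, p$nuF))),
                  epoch(p$tau, list(const_size(p$nu1), const_size(p$nu2)),
                        sym_mig(p$M))),
    split5 = list(anc,
                  epoch(p$tau1, list(const_size(p$nuB))),
                  epoch(p$tau2, list(const_size(p$nuTS0), const_size(p$nuNSS0)),
                        sym_mig(p$M1)),
                  epoch(p$tau3, list(lin_size(p$nuTS0, p$nuTS1),
                                     lin_size(p$nuNSS0, p$nuNSS1)),
                        sym_mig(p$M2))),
    stop("unknown model_id")
  )
  structure(list(model_id = params$model_id, epochs = eps),
            class = "demog_timeline")
}

#' @export
print.demog_timeline <- function(x, ...) {
  cat(sprintf("demog_timeline [%s], %d epochs (past -> present)\n",
              x$model_id, length(x$epochs)))
  for (k in seq_along(x$epochs)) {
    e <- x$epochs[[k]]
    sz <- vapply(e$sizes, function(s)
      if (s$type == "constant") sprintf("%.4g", s$start)
      else sprintf("%s %.4g->%.4g", s$type, s$start, s$end), "")
    cat(sprintf("  epoch %d: tau = %.6g, demes = %d, sizes = [%s], M = [%s]\n",
                k, e$duration, e$ndemes, paste(sz, collapse = ", "),
                paste(format(e$mig[e$mig > 0 | upper.tri(e$mig)], digits = 3),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Physical-unit model parameters
#'
#' Holds a model's parameters in natural units: the ancestral effective size
#' \code{Na} (individuals), per-breakpoint deme sizes (individuals), epoch
#' durations in years at a generation time of one year, migration in the
#' printed \code{M = 2*Na*m} convention together with the per-generation
#' migrant fraction \code{m}, and the mutation model (\code{mu} per bp per
#' generation, effective length \code{L} bp) through
#' \code{theta = 4*Na*mu*L}.
#'
#' @param model_id one of [model_ids()]
#' @param Na ancestral effective population size, individuals
#' @param mu substitution rate per bp per generation
#' @param L effective sequence length, bp
#' @param sizes named vector, individuals; names are the model's \code{nu}
#'   parameter names
#' @param durations_years named vector, years; names are the model's
#'   \code{tau} parameter names
#' @param M named vector of scaled migration rates (2*Na*m); names are the
#'   model's \code{M} parameter names
#' @return object of class \code{physical_params} with derived fields
#'   \code{theta} and \code{migrant_fraction}
#' @export
physical_params <- function(model_id, Na, mu, L,
                            sizes = numeric(0), durations_years = numeric(0),
                            M = numeric(0)) {
  model_id <- match.arg(model_id, model_ids())
  if (Na <= 0 || mu <= 0 || L <= 0) stop("Na, mu, L must be > 0")
  if (any(sizes <= 0)) stop("sizes must be > 0")
  if (any(durations_years < 0)) stop("durations must be >= 0")
  structure(list(model_id = model_id, Na = Na, mu = mu, L = L,
                 sizes = sizes, durations_years = durations_years, M = M,
                 migrant_fraction = M / (2 * Na),
                 theta = 4 * Na * mu * L),
            class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat(sprintf("physical_params [%s]: Na = %.6g, theta = %.6g (mu = %.4g, L = %.4g)\n",
              x$model_id, x$Na, x$theta, x$mu, x$L))
  if (length(x$sizes)) { cat("  sizes (individuals):\n"); print(x$sizes) }
  if (length(x$durations_years)) { cat("  durations (years):\n"); print(x$durations_years) }
  if (length(x$M)) { cat("  migration (M = 2*Na*m):\n"); print(x$M) }
  invisible(x)
}

#' Convert scaled parameters to physical units
#'
#' \code{Na = theta / (4*mu*L)}; durations in years are \code{tau * 2 * Na}
#' at a generation time of one year; sizes are \code{nu * Na}; migration is
#' reported in the scaled convention \code{M = 2*Na*m} together with the
#' migrant fraction \code{m = M/(2*Na)}.
#'
#' @param params [scaled_params()] with \code{theta} set
#' @param mu substitution rate per bp per generation
#' @param L effective sequence length, bp
#' @return [physical_params()]
#' @export
to_physical <- function(params, mu, L) {
  if (!inherits(params, "scaled_params")) stop("expected scaled_params")
  if (is.null(params$theta))
    stop("theta is required to convert to physical units")
  if (mu <= 0 || L <= 0) stop("mu and L must be > 0")
  Na <- params$theta / (4 * mu * L)
  v <- params$params
  nus  <- v[startsWith(names(v), "nu")]
  taus <- v[startsWith(names(v), "tau")]
  Ms   <- v[startsWith(names(v), "M")]
  physical_params(params$model_id, Na = Na, mu = mu, L = L,
                  sizes = nus * Na,
                  durations_years = taus * 2 * Na,
                  M = Ms)
}

#' Convert physical parameters back to scaled units
#'
#' Exact inverse of [to_physical()]: \code{theta = 4*Na*mu*L},
#' \code{nu = size/Na}, \code{tau = years/(2*Na)} at one generation per
#' year, \code{M} unchanged.
#'
#' @param phys [physical_params()]
#' @return [scaled_params()] with theta set
#' @export
to_scaled <- function(phys) {
  if (!inherits(phys, "physical_params")) stop("expected physical_params")
  vals <- c(phys$sizes / phys$Na,
            phys$durations_years / (2 * phys$Na),
            phys$M)
  scaled_params(phys$model_id, vals[model_param_names(phys$model_id)],
                theta = phys$theta)
}

#' Reference best-fit parameters for the two-bottleneck split model
#'
#' The package's reference parameter set for the tropical-temperate maize
#' split under \code{split5}: ancestral size 24,162; a domestication
#' bottleneck of 142 individuals lasting 5 generations; a split into a
#' tropical deme of 9,434 (derived as the 10,746 onset total minus the
#' founder size) and a temperate founder deme of 1,312; a 126-generation
#' divergence-and-recovery stage with scaled gene flow 4.3e-3; then 4,832
#' years of linear decline by 25% (TS) and 65% (NSS) with gene flow 1.2e-3.
#' Generation time is one year throughout, mutation rate 2.230e-8 per bp per
#' generation over an effective length of 3.8 Mbp.
#'
#' @param mu substitution rate per bp per generation
#' @param L effective sequence length, bp
#' @return list with elements \code{physical} ([physical_params()]) and
#'   \code{scaled} ([scaled_params()])
#' @export
split5_reference_fit <- function(mu = 2.230e-8, L = 3.8e6) {
  Na <- 24162
  ts0 <- 10746 - 1312          # onset TS size, derived from the onset total
  nss0 <- 1312
  phys <- physical_params(
    "split5", Na = Na, mu = mu, L = L,
    sizes = c(nuB = 142, nuTS0 = ts0, nuNSS0 = nss0,
              nuTS1 = 0.75 * ts0, nuNSS1 = 0.35 * nss0),
    durations_years = c(tau1 = 5, tau2 = 126, tau3 = 4832),
    M = c(M1 = 4.3e-3, M2 = 1.2e-3))
  list(physical = phys, scaled = to_scaled(phys))
}

#' Write / read flat key-value model parameter files
#'
#' One parameter per line, `name value`, preceded by a `units:` header
#' (`scaled` or `physical`) and a `model:` line. Physical files also carry
#' `Na`, `mu` and `L`; scaled files carry `theta` when set.
#'
#' @param params a [scaled_params()] or [physical_params()]
#' @param path file path
#' @return \code{read_params} returns the parameter object; \code{write_params}
#'   returns \code{path} invisibly.
#' @export
write_params <- function(params, path) {
  ln <- character(0)
  if (inherits(params, "scaled_params")) {
    ln <- c("units: scaled", paste("model:", params$model_id))
    if (!is.null(params$theta)) ln <- c(ln, sprintf("theta %.17g", params$theta))
    ln <- c(ln, sprintf("%s %.17g", names(params$params), params$params))
  } else if (inherits(params, "physical_params")) {
    ln <- c("units: physical", paste("model:", params$model_id),
            sprintf("Na %.17g", params$Na), sprintf("mu %.17g", params$mu),
            sprintf("L %.17g", params$L),
            sprintf("size_%s %.17g", names(params$sizes), params$sizes),
            sprintf("years_%s %.17g", names(params$durations_years),
                    params$durations_years),
            sprintf("%s %.17g", names(params$M), params$M))
  } else stop("expected scaled_params or physical_params")
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  units <- sub("^units:\\s*", "", ln[grepl("^units:", ln)])
  model <- sub("^model:\\s*", "", ln[grepl("^model:", ln)])
  kv <- ln[!grepl("^(units|model):", ln)]
  parts <- strsplit(kv, "\\s+")
  vals <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                          vapply(parts, `[`, "", 1))
  if (identical(units, "scaled")) {
    theta <- if ("theta" %in% names(vals)) vals[["theta"]] else NULL
    scaled_params(model, vals[setdiff(names(vals), "theta")], theta = theta)
  } else if (identical(units, "physical")) {
    sz <- vals[startsWith(names(vals), "size_")]
    names(sz) <- sub("^size_", "", names(sz))
    yr <- vals[startsWith(names(vals), "years_")]
    names(yr) <- sub("^years_", "", names(yr))
    Ms <- vals[startsWith(names(vals), "M")]
    physical_params(model, Na = vals[["Na"]], mu = vals[["mu"]], L = vals[["L"]],
                    sizes = sz, durations_years = yr, M = Ms)
  } else stop("parameter file must declare `units: scaled` or `units: physical`")
}
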