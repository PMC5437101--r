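#' Monte Carlo configuration for the coalescent SFS engine
#'
#' @param replicates number of independent genealogies to average (>= 1)
#' @param seed integer seed; mandatory so that every spectrum is reproducible
#'   and so that fits can hold the replicate stream fixed across parameter
#'   values (common random numbers)
#' @return object of class \code{coalescent_config}
#' @export
coalescent_config <- function(replicates = 1e5, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(replicates = replicates, seed = as.integer(seed)),
            class = "coalescent_config")
}

# flatten a past->present timeline into the present->past epoch matrix the
# C++ engine consumes; validates the ancestral epoch
timeline_to_matrix <- function(timeline) {
  eps <- rev(timeline$epochs)
  anc <- eps[[length(eps)]]
  if (!is.infinite(anc$duration) || anc$ndemes != 1L ||
      anc$sizes[[1]]$type != "constant")
    stop("the most ancient epoch must be an infinite constant one-deme epoch")
  type_code <- c(constant = 0, linear = 1, exponential = 2)
  m <- matrix(0, length(eps), 10)
  for (k in seq_along(eps)) {
    e <- eps[[k]]
    s0 <- e$sizes[[1]]
    m[k, 1] <- e$duration
    m[k, 2] <- e$ndemes
    m[k, 3:5] <- c(type_code[[s0$type]], s0$start, s0$end)
    if (e$ndemes == 2L) {
      s1 <- e$sizes[[2]]
      m[k, 6:8] <- c(type_code[[s1$type]], s1$start, s1$end)
      m[k, 9] <- e$mig[1, 2]
      m[k, 10] <- e$mig[2, 1]
    }
  }
  m
}

timeline_ndemes <- function(timeline) max(vapply(timeline$epochs, `[[`, 0L, "ndemes"))

#' Expected joint SFS by Monte Carlo structured coalescent
#'
#' Averages, over simulated genealogies, the total branch length T(i, j)
#' subtending exactly i population-1 and j population-2 leaves (time in
#' units of 2*Na generations), and reports E[S(i,j)] = (theta/2) * E[T(i,j)].
#' Coalescence in deme d proceeds at rate C(k,2)/nu_d(t); each lineage
#' migrates (backward) at rate M/2. Linear or exponential size epochs are
#' simulated by thinning against a per-epoch rate bound from the epoch's
#' extreme sizes.
#'
#' @param timeline a [build_timeline()] result
#' @param n1,n2 haplotype sample sizes (n2 = 0 for one-deme timelines)
#' @param theta scaled mutation supply 4*Na*mu*L
#' @param cfg a [coalescent_config()]
#' @return a \code{joint_sfs} of expectations with attributes \code{se}
#'   (per-cell Monte Carlo standard error of the expectation), \code{seed}
#'   and \code{replicates}
#' @export
expected_joint_sfs <- function(timeline, n1, n2, theta, cfg) {
  if (!inherits(timeline, "demog_timeline")) stop("expected a demog_timeline")
  if (!inherits(cfg, "coalescent_config")) stop("expected a coalescent_config")
  nd <- timeline_ndemes(timeline)
  if (nd == 2L && (n1 < 2L || n2 < 2L))
    stop("two-deme timelines require n1 >= 2 and n2 >= 2")
  if (nd == 1L && n2 != 0L)
    stop("one-deme timelines take n2 = 0")
  if (theta <= 0) stop("theta must be > 0")
  m <- timeline_to_matrix(timeline)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  res <- sfs_mc_engine(m, as.integer(n1), as.integer(n2), cfg$replicates)
  out <- joint_sfs(theta / 2 * res$mean)
  attr(out, "se") <- theta / 2 * res$se
  attr(out, "seed") <- cfg$seed
  attr(out, "replicates") <- cfg$replicates
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Deterministic expected SFS for one-deme piecewise-constant timelines
#'
#' Exact expected branch lengths via the block-counting (pure death) chain:
#' the expected time W_k spent with k ancestral lineages is integrated epoch
#' by epoch from the chain's occupancies, and
#' E[T(i)] = sum_k W_k * k * C(n-i-1, k-2) / C(n-1, k-1).
#' Fast enough to sit inside an optimizer, and an independent oracle for the
#' Monte Carlo engine.
#'
#' @param timeline one-deme [build_timeline()] result with constant epochs
#' @param n haplotype sample size
#' @param theta scaled mutation supply
#' @return a \code{joint_sfs} of dimension (n+1) x 1
#' @export
expected_sfs_onepop <- function(timeline, n, theta = 1) {
  if (timeline_ndemes(timeline) != 1L)
    stop("expected_sfs_onepop handles one-deme timelines only")
  for (e in timeline$epochs)
    if (e$sizes[[1]]$type != "constant")
      stop("expected_sfs_onepop requires piecewise-constant epochs")
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  eps <- rev(timeline$epochs)            # present -> past
  # transient states k = n..2 (index 1..n-1); absorbing k = 1
  K <- n - 1L
  p <- c(1, rep(0, K - 1L))              # start with n lineages
  W <- rep(0, K)                         # occupancy of k = n..2
  for (idx in seq_along(eps)) {
    e <- eps[[idx]]
    nu <- e$sizes[[1]]$start
    lam <- choose(n:2, 2) / nu
    Q <- diag(-lam, K)
    if (K > 1L) Q[cbind(1:(K - 1L), 2:K)] <- lam[1:(K - 1L)]
    if (is.infinite(e$duration)) {
      W <- W + as.vector(p %*% solve(-Q))
      p <- rep(0, K)
      break
    }
    if (e$duration > 0) {
      P <- as.matrix(Matrix::expm(Q * e$duration))
      pt <- as.vector(p %*% P)
      W <- W + as.vector((pt - p) %*% solve(Q))
      p <- pt
    }
  }
  ks <- n:2
  Ti <- vapply(1:(n - 1L), function(i)
    sum(W * ks * choose(n - i - 1, ks - 2) / choose(n - 1, ks - 1)), 0)
  joint_sfs(matrix(c(NA, theta / 2 * Ti, NA), ncol = 1))
}

# ---- exact small-sample two-deme oracle --------------------------------

# enumerate all ancestral lineage configurations: a state is a multiset of
# lineages (i, j, deme), i = pop1 leaves subtended, j = pop2 leaves
state_key <- function(st) paste(apply(st, 1, paste, collapse = ","), collapse = ";")

canon_state <- function(st) {
  st[order(st[, 1], st[, 2], st[, 3]), , drop = FALSE]
}

enumerate_states <- function(start, ndemes) {
  # BFS closure under coalescence (same deme) and, if ndemes == 2, migration
  seen <- new.env(parent = emptyenv())
  states <- list()
  queue <- list(canon_state(start))
  assign(state_key(queue[[1]]), TRUE, envir = seen)
  while (length(queue)) {
    st <- queue[[1]]; queue <- queue[-1]
    states[[length(states) + 1L]] <- st
    k <- nrow(st)
    if (k >= 2L) for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
      if (st[a, 3] != st[b, 3]) next
      ns <- st[-b, , drop = FALSE]
      ns[if (b < a) a - 1L else a, 1:2] <- st[a, 1:2] + st[b, 1:2]
      ns <- canon_state(ns)
      key <- state_key(ns)
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- ns
      }
    }
    if (ndemes == 2L) for (a in 1:k) {
      ns <- st
      ns[a, 3] <- 1L - ns[a, 3]
      ns <- canon_state(ns)
      key <- state_key(ns)
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- ns
      }
    }
  }
  states
}

# rate matrix over the enumerated states for one piecewise-constant epoch
state_rates <- function(states, index, nu, M) {
  # nu: deme sizes length 2 (second ignored for 1-deme); M: c(M0, M1)
  S <- length(states)
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(i, j, x) {
    trip$i[[length(trip$i) + 1L]] <<- i
    trip$j[[length(trip$j) + 1L]] <<- j
    trip$x[[length(trip$x) + 1L]] <<- x
  }
  for (s in seq_len(S)) {
    st <- states[[s]]
    k <- nrow(st)
    if (k >= 2L) for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
      if (st[a, 3] != st[b, 3]) next
      ns <- st[-b, , drop = FALSE]
      ns[if (b < a) a - 1L else a, 1:2] <- st[a, 1:2] + st[b, 1:2]
      tgt <- index[[state_key(canon_state(ns))]]
      add(s, tgt, 1 / nu[st[a, 3] + 1L])
    }
    if (any(M > 0)) for (a in seq_len(k)) {
      ns <- st
      ns[a, 3] <- 1L - ns[a, 3]
      tgt <- index[[state_key(canon_state(ns))]]
      add(s, tgt, M[st[a, 3] + 1L] / 2)
    }
  }
  Q <- matrix(0, S, S)
  for (t in seq_along(trip$i)) Q[trip$i[t], trip$j[t]] <- Q[trip$i[t], trip$j[t]] + trip$x[t]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Exact expected joint SFS for small samples
#'
#' Solves the ancestral-configuration Markov chain epoch by epoch: state
#' occupancies are integrated with matrix exponentials (finite epochs) or
#' the fundamental matrix (the infinite ancestral epoch), and expected
#' branch lengths are read off as occupancy-weighted lineage counts.
#' Deterministic; restricted to piecewise-constant epochs and n1 + n2 <= 6
#' to keep the state space small. Serves as the independent oracle for the
#' Monte Carlo engine.
#'
#' @param timeline a [build_timeline()] result with constant-size epochs
#' @param n1,n2 haplotype sample sizes, n1 + n2 <= 6
#' @param theta scaled mutation supply
#' @return a \code{joint_sfs} of expectations
#' @export
exact_small_sfs <- function(timeline, n1, n2, theta = 1) {
  if (!inherits(timeline, "demog_timeline")) stop("expected a demog_timeline")
  if (n1 + n2 > 6L) stop("exact oracle limited to n1 + n2 <= 6")
  for (e in timeline$epochs)
    for (s in e$sizes)
      if (s$type != "constant")
        stop("exact oracle requires piecewise-constant epochs")
  nd_max <- timeline_ndemes(timeline)
  if (nd_max == 1L && n2 != 0L) stop("one-deme timelines take n2 = 0")
  eps <- rev(timeline$epochs)            # present -> past

  start <- rbind(
    if (n1 > 0) cbind(1L, 0L, 0L)[rep(1, n1), , drop = FALSE],
    if (n2 > 0) cbind(0L, 1L, if (eps[[1]]$ndemes == 2L) 1L else 0L)[rep(1, n2), , drop = FALSE])
  states <- enumerate_states(canon_state(start), nd_max)
  index <- new.env(parent = emptyenv())
  for (s in seq_along(states)) assign(state_key(states[[s]]), s, envir = index)
  index <- as.list(index)

  S <- length(states)
  ksz <- vapply(states, nrow, 0L)
  transient <- which(ksz >= 2L)
  # per-cell lineage counts for each state
  counts <- matrix(0, S, (n1 + 1) * (n2 + 1))
  for (s in seq_len(S)) {
    st <- states[[s]]
    for (a in seq_len(nrow(st)))
      counts[s, st[a, 1] + st[a, 2] * (n1 + 1L) + 1L] <-
        counts[s, st[a, 1] + st[a, 2] * (n1 + 1L) + 1L] + 1
  }

  p <- rep(0, S)
  p[index[[state_key(canon_state(start))]]] <- 1
  Tvec <- rep(0, (n1 + 1) * (n2 + 1))
  for (ei in seq_along(eps)) {
    e <- eps[[ei]]
    if (e$ndemes == 1L) {
      # collapse any deme-1 mass onto the deme-0 states
      for (s in seq_len(S)) if (p[s] > 0 && any(states[[s]][, 3] == 1L)) {
        ns <- states[[s]]; ns[, 3] <- 0L
        tgt <- index[[state_key(canon_state(ns))]]
        p[tgt] <- p[tgt] + p[s]; p[s] <- 0
      }
    }
    nu <- c(e$sizes[[1]]$start,
            if (e$ndemes == 2L) e$sizes[[2]]$start else 1)
    M <- if (e$ndemes == 2L) c(e$mig[1, 2], e$mig[2, 1]) else c(0, 0)
    Q <- state_rates(states, index, nu, M)
    if (is.infinite(e$duration)) {
      # restrict to states reachable from the current mass; a reachable
      # non-absorbing state with no outflow would never coalesce
      reach <- which(p > 0)
      repeat {
        nxt <- unique(c(reach, which(colSums(Q[reach, , drop = FALSE] > 0) > 0)))
        if (length(nxt) == length(reach)) break
        reach <- nxt
      }
      tr <- intersect(reach, transient)
      Qtt <- Q[tr, tr, drop = FALSE]
      if (any(rowSums(Q[tr, , drop = FALSE] > 0) == 0))
        stop("timeline never coalesces remaining lineages")
      occ <- as.vector(p[tr] %*% solve(-Qtt))
      Tvec <- Tvec + as.vector(occ %*% counts[tr, , drop = FALSE])
      break
    }
    if (e$duration > 0) {
      # augmented exponential gives the transition kernel and its integral
      A <- rbind(cbind(Q, diag(S)), matrix(0, S, 2 * S))
      E <- as.matrix(Matrix::expm(A * e$duration))
      P <- E[1:S, 1:S, drop = FALSE]
      Intg <- E[1:S, (S + 1):(2 * S), drop = FALSE]
      occ <- as.vector(p %*% Intg)
      Tvec <- Tvec + as.vector(occ[transient] %*% counts[transient, , drop = FALSE])
      p <- as.vector(p %*% P)
    }
  }
  joint_sfs(matrix(theta / 2 * Tvec, n1 + 1L, n2 + 1L))
}
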