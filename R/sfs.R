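#' Joint site-frequency spectrum container
#'
#' A joint SFS is an (n1+1) x (n2+1) matrix whose entry \code{[i+1, j+1]}
#' holds the count (or expectation) of sites with \code{i} derived copies in
#' the population-1 sample and \code{j} in the population-2 sample. The two
#' corner cells (0,0) and (n1,n2) carry no polymorphism information and are
#' always masked (stored as \code{NA}). A single-population spectrum is the
#' degenerate case \code{n2 = 0}, i.e. an (n+1) x 1 matrix.
#'
#' @param mat numeric matrix of dimension (n1+1) x (n2+1); \code{NA} entries
#'   are treated as masked cells.
#' @param folded logical; \code{TRUE} if entries are indexed by minor-allele
#'   configuration (see [fold_sfs()]).
#' @return an object of class \code{joint_sfs}: the matrix with attributes
#'   \code{n1}, \code{n2}, \code{folded}.
#' @export
joint_sfs <- function(mat, folded = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("`mat` must be a numeric matrix")
  n1 <- nrow(mat) - 1L
  n2 <- ncol(mat) - 1L
  if (n1 < 1L || n2 < 0L) stop("spectrum must have n1 >= 1, n2 >= 0")
  if (any(mat < 0, na.rm = TRUE)) stop("spectrum entries must be non-negative")
  mat[1L, 1L] <- NA_real_
  mat[n1 + 1L, n2 + 1L] <- NA_real_
  structure(mat, n1 = n1, n2 = n2, folded = isTRUE(folded),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("joint_sfs: n1 = %d, n2 = %d, %s, unmasked mass = %.6g\n",
              attr(x, "n1"), attr(x, "n2"),
              if (attr(x, "folded")) "folded" else "unfolded",
              sfs_total(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Total unmasked mass of a spectrum
#' @param x a \code{joint_sfs}
#' @return scalar sum over unmasked cells
#' @export
sfs_total <- function(x) sum(x, na.rm = TRUE)

sfs_sizes <- function(x) c(attr(x, "n1"), attr(x, "n2"))

stopifnot_sfs <- function(x) {
  if (!inherits(x, "joint_sfs")) stop("expected a `joint_sfs` object")
  invisible(x)
}

#' Hypergeometric projection of a joint SFS to smaller sample sizes
#'
#' Projects an unfolded spectrum from sample sizes (n1, n2) down to (m1, m2)
#' haplotypes: a site with i derived copies among n contributes to the class
#' of a derived copies among m with hypergeometric weight
#' C(i,a) C(n-i, m-a) / C(n,m). Projection absorbs missing data by averaging
#' over all down-samplings; it is linear and mass-non-increasing (mass is lost
#' only into the re-masked monomorphic corners).
#'
#' @param x unfolded \code{joint_sfs}
#' @param m1,m2 target haplotype counts, \code{m1 <= n1}, \code{m2 <= n2}
#' @return a \code{joint_sfs} of dimension (m1+1) x (m2+1)
#' @export
project_sfs <- function(x, m1, m2) {
  stopifnot_sfs(x)
  if (attr(x, "folded")) stop("projection is defined on unfolded spectra")
  n <- sfs_sizes(x)
  if (m1 > n[1] || m2 > n[2]) stop("projection size exceeds sample size")
  if (m1 < 1L || m2 < 0L) stop("projection sizes must be >= 1 (pop1) / >= 0 (pop2)")
  W1 <- proj_weights(n[1], m1)
  W2 <- proj_weights(n[2], m2)
  m <- unclass(x)
  m[is.na(m)] <- 0
  out <- t(W1) %*% m %*% W2
  joint_sfs(out, folded = FALSE)
}

# weight matrix (n+1) x (m+1): row i+1 gives the hypergeometric spread of a
# site with i derived copies among n onto 0..m copies among m
proj_weights <- function(n, m) {
  W <- matrix(0, n + 1L, m + 1L)
  for (i in 0:n) W[i + 1L, ] <- stats::dhyper(0:m, i, n - i, m)
  W
}

#' Fold a joint SFS onto minor-allele configurations
#'
#' Without ancestral-allele polarization, configuration (i, j) cannot be told
#' apart from its complement (n1-i, n2-j); folding sums each such pair into
#' the configuration whose total allele count is the minor one. Cells on the
#' fold line (total count exactly half the sample) keep one representative;
#' the self-conjugate cell (if any) is kept as-is rather than doubled. Total
#' unmasked mass is conserved.
#'
#' @param x unfolded \code{joint_sfs}
#' @return folded \code{joint_sfs}; cells for major-allele configurations are
#'   masked \code{NA}
#' @export
fold_sfs <- function(x) {
  stopifnot_sfs(x)
  if (attr(x, "folded")) stop("spectrum is already folded")
  n <- sfs_sizes(x)
  n1 <- n[1]; n2 <- n[2]
  m <- unclass(x)
  m[is.na(m)] <- 0
  out <- matrix(NA_real_, n1 + 1L, n2 + 1L)
  half <- (n1 + n2) / 2
  for (i in 0:n1) for (j in 0:n2) {
    ic <- n1 - i; jc <- n2 - j
    tot <- i + j
    keep <- tot < half || (tot == half && (i < ic || (i == ic && j <= jc)))
    if (!keep) next
    if (i == ic && j == jc) {
      out[i + 1L, j + 1L] <- m[i + 1L, j + 1L]       # self-conjugate
    } else {
      out[i + 1L, j + 1L] <- m[i + 1L, j + 1L] + m[ic + 1L, jc + 1L]
    }
  }
  joint_sfs(out, folded = TRUE)
}

#' Read / write the plain-text SFS interchange format
#'
#' Format: one header line `n1 n2 folded` (folded is 0 or 1) followed by the
#' (n1+1) x (n2+1) entries row-major, whitespace-separated, `NA` for masked
#' cells.
#'
#' @param x a \code{joint_sfs}
#' @param path file path
#' @return \code{read_sfs} returns a \code{joint_sfs}; \code{write_sfs}
#'   returns \code{path} invisibly.
#' @export
write_sfs <- function(x, path) {
  stopifnot_sfs(x)
  n <- sfs_sizes(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", n[1], n[2], as.integer(attr(x, "folded"))), con)
  vals <- format(as.vector(t(unclass(x))), digits = 17, trim = TRUE)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 3L) stop("malformed SFS header")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(paste(lines[-1], collapse = " ")),
                                               "\\s+")[[1]]))
  if (length(vals) != (hdr[1] + 1L) * (hdr[2] + 1L))
    stop("SFS entry count does not match header dimensions")
  m <- matrix(vals, nrow = hdr[1] + 1L, byrow = TRUE)
  joint_sfs(m, folded = hdr[3] == 1L)
}
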