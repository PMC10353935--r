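# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
  invisible(TRUE)
}

#' Derive a stage seed from a run seed
#'
#' Stages of the pipeline draw their own seeds from one run-level seed via a
#' fixed affine-mod scheme, so any stage can be re-run in isolation and still
#' reproduce the full run bit-for-bit. All derived seeds stay below 2^31.
#'
#' @param seed integer run seed.
#' @param k integer stage counter (0, 1, 2, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Gauss-Legendre nodes/weights on [-1, 1], fixed order (Golub-Welsch).
gauss_legendre <- function(n = 32L) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

.gl32 <- NULL

gl_cache <- function() {
  if (is.null(.gl32)) utils::assignInMyNamespace(".gl32", gauss_legendre(32L))
  .gl32
}

#' Standard bivariate normal CDF
#'
#' P(X <= h, Y <= k) for correlated standard normals, vectorised over equal
#' length inputs. Uses the identity dPhi2/drho = phi2(h, k; rho) integrated by
#' fixed-order Gauss-Legendre quadrature from 0 to rho.
#'
#' @param h,k upper limits.
#' @param rho correlation(s) in (-1, 1).
#' @return vector of probabilities.
#' @export
pbinorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  gl <- gl_cache()
  # t-grid per element: rho/2 * (x + 1), x in [-1, 1]
  tt <- outer(rho / 2, gl$nodes + 1)           # n x q
  om <- 1 - tt^2
  num <- h^2 + k^2 - 2 * (h * k) * tt   # recycles h, k down rows
  dens <- exp(-num / (2 * om)) / (2 * pi * sqrt(om))
  integral <- (rho / 2) * as.vector(dens %*% gl$weights)
  pmin(pmax(stats::pnorm(h) * stats::pnorm(k) + integral, 0), 1)
}

# Correlation between threshold indicators 1{Z1 < t1}, 1{Z2 < t2} implied by
# latent correlation rho.
indicator_cor <- function(t1, t2, rho, f1 = stats::pnorm(t1), f2 = stats::pnorm(t2)) {
  (pbinorm(t1, t2, rho) - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

#' Latent correlation achieving a target indicator correlation
#'
#' Inverse of the threshold-model map: given allele frequencies (threshold
#' probabilities) and a target correlation between the 0/1 indicators, finds
#' the latent bivariate-normal correlation by vectorised bisection. Targets
#' outside the attainable (Frechet) range are clipped to the nearest bound.
#'
#' @param f1,f2 allele frequencies in (0, 1).
#' @param target target indicator correlations.
#' @param iter bisection iterations.
#' @return latent correlations in (-1, 1).
#' @export
latent_cor_for_target <- function(f1, f2, target, iter = 45L) {
  n <- max(length(f1), length(f2), length(target))
  f1 <- rep_len(f1, n); f2 <- rep_len(f2, n); target <- rep_len(target, n)
  t1 <- stats::qnorm(f1); t2 <- stats::qnorm(f2)
  lo <- rep(-0.9995, n); hi <- rep(0.9995, n)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    val <- indicator_cor(t1, t2, mid, f1, f2)
    up <- val < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

ensure_parent <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  path
}

# Repair a symmetric matrix to positive semi-definiteness by eigenvalue
# clipping, then rescale to unit diagonal.
psd_repair <- function(R, eps = 1e-8, unit_diag = TRUE) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  if (unit_diag) {
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    diag(R2) <- 1
  }
  (R2 + t(R2)) / 2
}
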