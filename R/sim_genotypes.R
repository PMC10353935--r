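# Genotype simulation under a latent-Gaussian threshold model.

# Latent haplotype correlation matrix reproducing target dosage correlations
# after thresholding, plus the realised (attainable) correlation it implies.
# Deterministic: no RNG involved.
threshold_block <- function(target, freq) {
  m <- nrow(target)
  if (m == 1L) return(list(R = matrix(1, 1, 1), latent = matrix(1, 1, 1)))
  iu <- which(upper.tri(target), arr.ind = TRUE)
  rho <- latent_cor_for_target(freq[iu[, 1]], freq[iu[, 2]], target[iu])
  L <- diag(m)
  L[iu] <- rho
  L[lower.tri(L)] <- t(L)[lower.tri(L)]
  L <- psd_repair(L, eps = 1e-6)
  R <- diag(m)
  R[iu] <- indicator_cor(stats::qnorm(freq[iu[, 1]]), stats::qnorm(freq[iu[, 2]]),
                         L[iu], freq[iu[, 1]], freq[iu[, 2]])
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R <- psd_repair(R, eps = 0)
  list(R = R, latent = L)
}

latent_block_matrix <- function(block) {
  if (!is.null(block$latent)) return(block$latent)
  threshold_block(block$R, block$variants$freq)$latent
}

#' Simulate genotype dosages from an LD panel
#'
#' Each haplotype is a latent multivariate Gaussian per block, thresholded at
#' the frequency quantile (carrier when z < qnorm(freq)); the dosage is the
#' sum of two independent haplotypes, so dosages lie in {0, 1, 2}, the mean
#' dosage is 2 * freq and the dosage correlation equals the indicator
#' correlation. The latent correlation is calibrated per variant pair by the
#' bivariate-normal correction so the realised (post-threshold) correlation
#' matches the panel's target matrix; targets beyond the Frechet bound for the
#' pair of frequencies are clipped to the nearest attainable value.
#'
#' @param panel an `ld_panel`.
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return n x M integer dosage matrix, columns named by variant id.
#' @export
simulate_genotypes <- function(panel, n, seed) {
  assert_that(n >= 1, "n must be >= 1")
  M <- panel_size(panel)
  with_seed(seed, {
    out <- matrix(0L, n, M)
    ids <- character(M)
    off <- 0L
    for (b in panel$blocks) {
      m <- nrow(b$variants)
      f <- b$variants$freq
      L <- latent_block_matrix(b)
      C <- chol(L)
      thr <- stats::qnorm(f)
      h1 <- matrix(stats::rnorm(n * m), n, m) %*% C
      h2 <- matrix(stats::rnorm(n * m), n, m) %*% C
      d <- (sweep(h1, 2, thr, "<")) + (sweep(h2, 2, thr, "<"))
      out[, off + seq_len(m)] <- d
      ids[off + seq_len(m)] <- b$variants$id
      off <- off + m
    }
    colnames(out) <- ids
    out
  })
}

#' Simulate shared causal effects across ancestries and traits
#'
#' Draws a single causal-variant indicator vector (shared by all ancestries
#' and traits), then for each causal variant an effect vector over the
#' (ancestry x trait) grid from a zero-mean multivariate normal whose
#' correlation is the Kronecker product of the cross-trait and cross-ancestry
#' correlation matrices. Effects are expressed on the standardized-genotype
#' scale and rescaled per (ancestry, trait) so the genetic variance
#' `t(beta) %*% R %*% beta` (accumulated over blocks of that ancestry's
#' panel) equals `h2` exactly.
#'
#' @param panel_set named list of `ld_panel`s sharing variant ids.
#' @param p_causal causal fraction in (0, 1].
#' @param h2 target genetic variance per trait, in `[0, 1)`; scalar or one
#'   value per trait.
#' @param rg_anc cross-ancestry effect correlation: scalar (exchangeable) or
#'   correlation matrix.
#' @param rg_trait cross-trait effect correlation, same conventions.
#' @param n_traits number of traits.
#' @param seed integer seed.
#' @return object of class `true_effects`: list with `causal` (logical M),
#'   `beta` (M x ancestry x trait array, standardized scale), `h2`,
#'   `p_causal`, and the correlation inputs.
#' @export
simulate_true_effects <- function(panel_set, p_causal, h2, rg_anc = 1,
                                  rg_trait = 1, n_traits = 1, seed) {
  assert_that(p_causal > 0 && p_causal <= 1, "p_causal must lie in (0, 1]")
  assert_that(all(h2 >= 0 & h2 < 1), "h2 must lie in [0, 1)")
  A <- length(panel_set)
  h2 <- rep_len(h2, n_traits)
  Ra <- exch_cor(rg_anc, A, "rg_anc")
  Rt <- exch_cor(rg_trait, n_traits, "rg_trait")
  Sig <- kronecker(Rt, Ra)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8, "effect correlation matrix not positive semidefinite")
  Sig <- psd_repair(Sig, eps = 1e-10, unit_diag = FALSE)
  ids <- panel_variants(panel_set[[1]])$id
  M <- length(ids)
  with_seed(seed, {
    causal <- stats::runif(M) < p_causal
    if (!any(causal)) causal[sample.int(M, 1)] <- TRUE
    nc <- sum(causal)
    C <- chol(Sig + diag(1e-12, nrow(Sig)))
    raw <- matrix(stats::rnorm(nc * A * n_traits), nc) %*% C
    beta <- array(0, dim = c(M, A, n_traits),
                  dimnames = list(ids, names(panel_set),
                                  paste0("trait", seq_len(n_traits))))
    for (a in seq_len(A)) for (t in seq_len(n_traits)) {
      beta[causal, a, t] <- raw[, (t - 1) * A + a]
    }
    # exact per-(ancestry, trait) calibration of genetic variance to h2
    for (a in seq_len(A)) {
      pan <- panel_set[[a]]
      for (t in seq_len(n_traits)) {
        v <- 0
        off <- 0L
        for (b in pan$blocks) {
          m <- nrow(b$variants)
          bb <- beta[off + seq_len(m), a, t]
          v <- v + drop(crossprod(bb, b$R %*% bb))
          off <- off + m
        }
        if (v > 0 && h2[t] > 0) {
          beta[, a, t] <- beta[, a, t] * sqrt(h2[t] / v)
        } else beta[, a, t] <- 0
      }
    }
    structure(list(causal = causal, beta = beta, h2 = h2, p_causal = p_causal,
                   rg_anc = Ra, rg_trait = Rt),
              class = "true_effects")
  })
}

exch_cor <- function(r, k, what) {
  if (is.matrix(r)) {
    assert_that(nrow(r) == k && ncol(r) == k, "%s matrix has wrong dimension", what)
    return(r)
  }
  assert_that(abs(r) <= 1, "%s must lie in [-1, 1]", what)
  m <- matrix(r, k, k)
  diag(m) <- 1
  m
}

#' Genetic score of a cohort under a set of true effects
#'
#' Standardizes dosage columns with the panel frequencies (mean 2f, variance
#' 2f(1-f)) and accumulates the standardized-scale effects. Used as the
#' simulation ground truth for liability and hazards.
#'
#' @param dosages n x M dosage matrix with variant-id column names.
#' @param effects a `true_effects` object.
#' @param panel the `ld_panel` matching the cohort's ancestry.
#' @param trait trait index.
#' @return numeric vector of genetic scores (variance ~ h2).
#' @export
genetic_score <- function(dosages, effects, panel, trait = 1) {
  v <- panel_variants(panel)
  a <- match(panel$ancestry, dimnames(effects$beta)[[2]])
  assert_that(!is.na(a), "panel ancestry not present in effects")
  b <- effects$beta[v$id, a, trait]
  sdv <- sqrt(2 * v$freq * (1 - v$freq))
  w <- b / sdv
  drop(dosages[, v$id, drop = FALSE] %*% w) - sum(w * 2 * v$freq)
}
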