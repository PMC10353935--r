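# Two-layer score combination: candidate tuning, bidirectional stepwise AIC
# selection, logistic mixing weights and flattening to variant-level weights.

#' Pick the best candidate weight set on a training cohort
#'
#' Each candidate is scored and standardized on the training cohort and
#' entered (alone) into a covariate-adjusted logistic model for the prevalent
#' outcome; the candidate with the highest log-likelihood (equivalently the
#' lowest AIC at fixed dimension) wins. Ties are broken by smaller p, then
#' smaller s, then the non-sparse setting. Zero-variance candidates are
#' skipped; all candidates degenerate is an error.
#'
#' @param candidates list of `weight_set`s.
#' @param cohort training `cohort` with `prevalent_case`.
#' @param covariates covariate columns (default [baseline_covariates()]).
#' @return the winning `weight_set`, with attribute `tuning` (data.frame of
#'   per-candidate log-likelihoods and hyperparameters).
#' @export
tune_best_candidate <- function(candidates, cohort,
                                covariates = baseline_covariates()) {
  assert_that(length(candidates) >= 1, "need at least one candidate")
  y <- cohort$pheno$prevalent_case
  cmat <- covariate_matrix(cohort$pheno, covariates)
  rows <- lapply(seq_along(candidates), function(i) {
    ws <- candidates[[i]]
    meta <- attr(ws, "meta")
    sc <- tryCatch(score_cohort(cohort, ws), error = function(e) NULL)
    if (is.null(sc) || stats::sd(sc$raw) < 1e-12) {
      return(data.frame(i = i, logLik = -Inf, p = meta$p %||% NA,
                        s = meta$s %||% NA, sparse = meta$sparse %||% NA))
    }
    fit <- stats::glm.fit(cbind(cmat, score = sc$standardized), y,
                          family = stats::binomial())
    data.frame(i = i, logLik = glmfit_loglik(fit), p = meta$p %||% NA,
               s = meta$s %||% NA, sparse = meta$sparse %||% NA)
  })
  tab <- do.call(rbind, rows)
  assert_that(any(is.finite(tab$logLik)), "all candidates degenerate")
  ord <- order(-tab$logLik, tab$p, tab$s, tab$sparse)
  best <- candidates[[tab$i[ord[1]]]]
  attr(best, "tuning") <- tab
  best
}

covariate_matrix <- function(pheno, covariates) {
  if (length(covariates) == 0) return(matrix(1, nrow(pheno), 1,
                                             dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., data = pheno[, covariates, drop = FALSE])
}

glmfit_loglik <- function(fit) {
  -fit$deviance / 2
}

glmfit_aic <- function(fit) {
  fit$deviance + 2 * fit$rank
}

fit_logistic <- function(X, y, ridge = 0) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged || any(!is.finite(fit$coefficients)) ||
      any(abs(fit$coefficients) > 50)) {
    # separation fallback: tiny ridge via augmented least squares on IRLS
    warning("logistic fit unstable; applying ridge fallback (1e-6)")
    fit <- ridge_logistic(X, y, lambda = 1e-6)
  }
  fit
}

ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, w * X) + diag(lambda, p)
    bnew <- solve(H, crossprod(X, w * z))
    if (max(abs(bnew - beta)) < 1e-10) { beta <- drop(bnew); break }
    beta <- drop(bnew)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  dev <- -2 * sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coefficients = stats::setNames(beta, colnames(X)), deviance = dev,
       rank = p, converged = TRUE)
}

#' Bidirectional stepwise AIC selection of component scores
#'
#' Logistic model `outcome ~ covariates + components`, starting from the full
#' model. At each step the single addition or removal of one component that
#' most reduces AIC (2k - 2 logL) is taken; the search stops when no move
#' reduces AIC. Covariates are never candidates for removal. Components that
#' are exact duplicates keep only their first copy (collinearity guard).
#'
#' @param component_scores n x k matrix (or data.frame) of standardized
#'   component scores, named columns.
#' @param outcome 0/1 vector.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list: `selected` column names, `aic_trace` numeric vector (AIC
#'   after each accepted step, starting with the full model), `final_aic`.
#' @export
stepwise_aic_select <- function(component_scores, outcome, covariates = NULL) {
  S <- as.matrix(component_scores)
  assert_that(ncol(S) >= 1, "need at least one component")
  if (is.null(colnames(S))) colnames(S) <- paste0("S", seq_len(ncol(S)))
  dup <- duplicated(t(S))
  S <- S[, !dup, drop = FALSE]
  cmat <- if (is.null(covariates)) {
    matrix(1, length(outcome), 1, dimnames = list(NULL, "(Intercept)"))
  } else covariate_matrix(covariates, names(covariates))
  all_comp <- colnames(S)
  current <- all_comp
  aic_of <- function(set) {
    X <- cbind(cmat, S[, set, drop = FALSE])
    glmfit_aic(fit_logistic(X, outcome))
  }
  cache <- new.env()
  aic_cached <- function(set) {
    key <- paste0("k:", paste(sort(set), collapse = "|"))
    if (is.null(cache[[key]])) cache[[key]] <- aic_of(set)
    cache[[key]]
  }
  trace <- aic_cached(current)
  repeat {
    best_move <- NULL
    best_aic <- trace[length(trace)]
    for (comp in current) {
      a <- aic_cached(setdiff(current, comp))
      if (a < best_aic - 1e-9) { best_aic <- a; best_move <- list(drop = comp) }
    }
    for (comp in setdiff(all_comp, current)) {
      a <- aic_cached(c(current, comp))
      if (a < best_aic - 1e-9) { best_aic <- a; best_move <- list(add = comp) }
    }
    if (is.null(best_move)) break
    current <- if (!is.null(best_move$drop)) setdiff(current, best_move$drop)
               else c(current, best_move$add)
    trace <- c(trace, best_aic)
  }
  list(selected = current, aic_trace = trace, final_aic = trace[length(trace)])
}

#' Fit logistic mixing weights for selected components
#'
#' One logistic fit of the outcome on covariates plus the selected
#' standardized component scores; the score coefficients are the mixing
#' weights. Training standardization constants for each component must be
#' supplied so the model can later be flattened or applied to new cohorts.
#'
#' @param selected_scores n x k matrix of standardized selected components.
#' @param outcome 0/1 vector.
#' @param covariates optional data.frame of adjustment covariates.
#' @param standardization named list (per component) of per-ancestry
#'   constants from [standardize_scores()].
#' @param layer 1 or 2.
#' @param aic_trace optional trace from [stepwise_aic_select()].
#' @return a `mix_model`: list with `layer`, `components`, `beta` (named
#'   mixing weights), `covariate_coef`, `standardization`, `aic_trace`.
#' @export
fit_mixing_weights <- function(selected_scores, outcome, covariates = NULL,
                               standardization = NULL, layer = 1L,
                               aic_trace = NULL) {
  S <- as.matrix(selected_scores)
  cmat <- if (is.null(covariates)) {
    matrix(1, length(outcome), 1, dimnames = list(NULL, "(Intercept)"))
  } else covariate_matrix(covariates, names(covariates))
  X <- cbind(cmat, S)
  fit <- fit_logistic(X, outcome)
  assert_that(isTRUE(fit$converged), "mixing regression did not converge")
  cf <- fit$coefficients
  comp <- colnames(S)
  structure(list(layer = layer, components = comp,
                 beta = cf[comp],
                 covariate_coef = cf[setdiff(names(cf), comp)],
                 standardization = standardization,
                 aic_trace = aic_trace),
            class = "mix_model")
}

#' @export
print.mix_model <- function(x, ...) {
  cat(sprintf("mix_model (layer %d): %d components\n", x$layer,
              length(x$components)))
  print(round(x$beta, 4))
  invisible(x)
}

#' Combine component scores with a fitted mix model
#'
#' @param mix a `mix_model`.
#' @param scores matrix of standardized component scores (training-constant
#'   standardization for validation cohorts).
#' @return numeric combined score.
#' @export
combine_scores <- function(mix, scores) {
  S <- as.matrix(scores)[, mix$components, drop = FALSE]
  drop(S %*% mix$beta)
}

#' Flatten a two-layer mix into a single variant-level weight set
#'
#' final_w_j = sum_t beta2_t / sd_t * sum_a beta1_{t,a} / sd_{t,a} * w_{t,a,j}
#' over the union of variants (absent weights count 0), after harmonizing all
#' components to the orientation of the first component carrying each
#' variant; swapped orientations contribute with flipped sign, irreconcilable
#' allele pairs are dropped (counted in the `dropped` attribute). Scoring a
#' cohort with the flattened set equals the explicit two-layer combination up
#' to an affine transform.
#'
#' Standard deviations divide the weights because the mixing regressions
#' consumed standardized scores: a coefficient per SD of component score maps
#' to per-raw-unit weights as beta / sd. When a component was standardized
#' per ancestry group, the SD of the mixing cohort's own group is used.
#'
#' @param layer1 named list (per trait) of layer-1 `mix_model`s whose
#'   components are ancestry labels.
#' @param layer2 a layer-2 `mix_model` whose components are trait labels, or
#'   NULL for a single-trait (layer-1 only) flatten.
#' @param weightsets nested named list: `weightsets[[trait]][[ancestry]]` is
#'   the component `weight_set`.
#' @param sd1 function(trait, ancestry) -> numeric SD, or nested list of SDs;
#'   `sd2` likewise per trait. Defaults of 1 assume pre-scaled inputs.
#' @param sd2 see `sd1`.
#' @return a `weight_set` with metadata `source = "flattened"`.
#' @export
flatten_weights <- function(layer1, layer2, weightsets, sd1 = NULL, sd2 = NULL) {
  get_sd <- function(x, a, b = NULL) {
    if (is.null(x)) return(1)
    if (is.function(x)) return(if (is.null(b)) x(a) else x(a, b))
    v <- if (is.null(b)) x[[a]] else x[[a]][[b]]
    v %||% 1
  }
  traits <- if (is.null(layer2)) names(layer1) else layer2$components
  acc <- NULL
  dropped <- 0L
  for (tr in traits) {
    b2 <- if (is.null(layer2)) 1 else unname(layer2$beta[tr]) / get_sd(sd2, tr)
    m1 <- layer1[[tr]]
    for (anc in m1$components) {
      b1 <- unname(m1$beta[anc]) / get_sd(sd1, tr, anc)
      ws <- weightsets[[tr]][[anc]]
      assert_that(!is.null(ws), "missing weight set for %s/%s", tr, anc)
      contrib <- data.frame(id = ws$id, chr = ws$chr, pos = ws$pos,
                            effect_allele = ws$effect_allele,
                            other_allele = ws$other_allele,
                            weight = b2 * b1 * ws$weight,
                            stringsAsFactors = FALSE)
      if (is.null(acc)) {
        acc <- contrib
      } else {
        i <- match(contrib$id, acc$id)
        new <- is.na(i)
        if (any(!new)) {
          ii <- i[!new]
          cc <- contrib[!new, ]
          same <- cc$effect_allele == acc$effect_allele[ii] &
            cc$other_allele == acc$other_allele[ii]
          swap <- cc$effect_allele == acc$other_allele[ii] &
            cc$other_allele == acc$effect_allele[ii]
          fea <- unname(COMPLEMENT[cc$effect_allele])
          foa <- unname(COMPLEMENT[cc$other_allele])
          same <- same | (fea == acc$effect_allele[ii] & foa == acc$other_allele[ii])
          swap <- swap | (fea == acc$other_allele[ii] & foa == acc$effect_allele[ii])
          ok <- same | swap
          dropped <- dropped + sum(!ok)
          sgn <- ifelse(swap, -1, 1)
          upd <- ii[ok]
          acc$weight[upd] <- acc$weight[upd] + (sgn * cc$weight)[ok]
        }
        acc <- rbind(acc, contrib[new, ])
      }
    }
  }
  acc <- acc[order(acc$id), ]
  rownames(acc) <- NULL
  ws <- weight_set(acc, source = "flattened", dropped = dropped)
  ws
}
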