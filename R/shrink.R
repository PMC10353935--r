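# Spike-and-slab shrinkage of marginal GWAS effects over block LD panels,
# LD-score-regression heritability, and the candidate hyperparameter grid.

#' Default shrinkage hyperparameter grid
#'
#' 17 causal-fraction values (1e-4 to 1 on a 1.0/1.8/3.2/5.6 log ladder),
#' three heritability scale multipliers (0.7, 1, 1.4) and both LD-matrix
#' settings (dense, sparsified) — 102 combinations in total.
#'
#' @param gibbs_iterations kept Gibbs iterations per candidate.
#' @param burn_in discarded iterations.
#' @param seed seed for the samplers.
#' @return a `grid_config` list.
#' @export
default_grid <- function(gibbs_iterations = 500L, burn_in = 500L, seed = 1L) {
  p <- as.vector(outer(c(1.0, 1.8, 3.2, 5.6), 10^(-4:-1)))
  grid_config(causal_fractions = c(sort(p), 1),
              h2_scales = c(0.7, 1, 1.4),
              sparse_flags = c(FALSE, TRUE),
              gibbs_iterations = gibbs_iterations,
              burn_in = burn_in, seed = seed)
}

#' Construct a shrinkage grid configuration
#'
#' @param causal_fractions vector of causal-fraction values p in (0, 1].
#' @param h2_scales vector of heritability multipliers s > 0.
#' @param sparse_flags logical vector of LD-sparsification settings.
#' @param gibbs_iterations,burn_in,seed Gibbs sampler settings.
#' @return a `grid_config` list.
#' @export
grid_config <- function(causal_fractions, h2_scales, sparse_flags,
                        gibbs_iterations = 500L, burn_in = 500L, seed = 1L) {
  assert_that(length(causal_fractions) > 0 && length(h2_scales) > 0 &&
                length(sparse_flags) > 0, "grid must be non-empty")
  assert_that(all(causal_fractions > 0 & causal_fractions <= 1),
              "causal fractions must lie in (0, 1]")
  assert_that(all(h2_scales > 0), "h2 scales must be > 0")
  structure(list(causal_fractions = causal_fractions, h2_scales = h2_scales,
                 sparse_flags = sparse_flags,
                 gibbs_iterations = as.integer(gibbs_iterations),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "grid_config")
}

#' Heritability from summary statistics by LD-score regression
#'
#' Computes per-variant LD scores from the panel (sum of squared within-block
#' correlations) and regresses the chi-square statistics on N * l_j / M under
#' E[chi2_j] = 1 + N h2 l_j / M. The slope is the observed-scale heritability
#' estimate; the intercept captures confounding/misspecification. The
#' estimate is clipped to [1e-4, 0.99] by downstream users before serving as
#' a prior parameter; the raw value is reported here.
#'
#' @param sumstats a `sumstats` data.frame.
#' @param panel matching `ld_panel`.
#' @param min_variants minimum variants with usable statistics (default 200).
#' @return list with `h2_hat`, `intercept`, `se` (of h2_hat).
#' @export
estimate_heritability_ldsc <- function(sumstats, panel, min_variants = 200L) {
  ld <- ld_scores(panel)
  dat <- merge(sumstats, ld, by.x = "variant_id", by.y = "id")
  dat <- dat[is.finite(dat$beta) & is.finite(dat$se) & dat$se > 0, ]
  assert_that(nrow(dat) >= min_variants,
              "need >= %d variants with non-missing statistics, got %d",
              min_variants, nrow(dat))
  chi2 <- (dat$beta / dat$se)^2
  M <- nrow(dat)
  x <- dat$n * dat$ldscore / M
  # two-step weighted regression: OLS start, then the canonical LD-score
  # weights 1 / (l_j * (1 + N h2 l_j / M)^2) for over-counting and
  # heteroskedasticity
  fit <- stats::lm(chi2 ~ x)
  for (i in 1:2) {
    h2_cur <- max(min(unname(stats::coef(fit)[2]), 1), 0)
    w <- 1 / (pmax(dat$ldscore, 1) * (1 + h2_cur * x)^2)
    fit <- stats::lm(chi2 ~ x, weights = w)
  }
  co <- summary(fit)$coefficients
  list(h2_hat = unname(co[2, 1]), intercept = unname(co[1, 1]),
       se = unname(co[2, 2]))
}

clip_h2 <- function(h2) min(max(h2, 1e-4), 0.99)

# Sparsify a block correlation matrix: |r| < threshold set to 0, then PSD
# repair by eigenvalue clipping.
sparsify_block <- function(R, threshold = 0.01, eps = 1e-8) {
  R2 <- R
  R2[abs(R2) < threshold] <- 0
  diag(R2) <- 1
  psd_repair(R2, eps = eps)
}

# Match sumstats to panel variants: inner join on id with allele alignment.
# Swapped alleles flip the sign of beta and take eaf -> 1 - eaf; mismatched
# alleles are dropped. Returns per-block index/statistics lists.
match_sumstats_panel <- function(sumstats, panel, freq_bounds = c(0.005, 0.995)) {
  blocks <- list()
  dropped <- 0L
  for (b in panel$blocks) {
    v <- b$variants
    i <- match(v$id, sumstats$variant_id)
    keep <- !is.na(i)
    ss <- sumstats[i[keep], , drop = FALSE]
    vv <- v[keep, , drop = FALSE]
    same <- ss$effect_allele == vv$a1 & ss$other_allele == vv$a2
    swap <- ss$effect_allele == vv$a2 & ss$other_allele == vv$a1
    sign <- ifelse(same, 1, ifelse(swap, -1, NA))
    usable <- !is.na(sign) & is.finite(ss$beta) & is.finite(ss$se) & ss$se > 0 &
      vv$freq >= freq_bounds[1] & vv$freq <= freq_bounds[2]
    dropped <- dropped + (nrow(v) - sum(usable))
    blocks[[length(blocks) + 1]] <- list(
      idx = which(keep)[usable],
      block = b,
      variants = vv[usable, , drop = FALSE],
      beta = sign[usable] * ss$beta[usable],
      se = ss$se[usable],
      n = ss$n[usable],
      n_cases = if ("n_cases" %in% names(ss)) ss$n_cases[usable] else rep(NA, sum(usable)))
  }
  list(blocks = blocks, n_dropped = dropped,
       n_matched = sum(vapply(blocks, function(x) length(x$beta), 1L)))
}

effective_n <- function(n, n_cases) {
  ifelse(!is.na(n_cases) & n_cases > 0 & n_cases < n,
         4 / (1 / n_cases + 1 / (n - n_cases)), n)
}

#' Posterior mean effects under a spike-and-slab prior with LD
#'
#' Gibbs sampler over standardized effects: each variant is causal with
#' probability `p`, causal effects have prior variance `h2_prior / (M p)`.
#' Marginal effects are standardized as z/sqrt(n_eff) and per-variant
#' conditional updates residualize against the current effects of LD partners
#' within the block; blocks are processed independently. The output is the
#' across-iteration (post burn-in) Rao-Blackwellised posterior mean, mapped
#' back to the per-allele scale via `se * sqrt(n_eff)`. Deterministic given
#' the seed. Variants with reference frequency outside [0.005, 0.995] or
#' missing statistics are excluded (count recorded in the result).
#'
#' @param sumstats a `sumstats` data.frame.
#' @param panel matching `ld_panel`.
#' @param p causal fraction in (0, 1].
#' @param h2_prior prior heritability (> 0), typically s * h2_hat.
#' @param sparse apply LD-matrix sparsification (|r| < 0.01 zeroed, PSD
#'   repaired) before sampling.
#' @param gibbs_iterations,burn_in sampler length.
#' @param seed integer seed.
#' @return a `weight_set`: data.frame (id, chr, pos, effect_allele,
#'   other_allele, weight) with metadata attributes (p, s if supplied,
#'   sparse, trait, ancestry, n_dropped).
#' @export
posterior_mean_effects <- function(sumstats, panel, p, h2_prior, sparse = FALSE,
                                   gibbs_iterations = 500L, burn_in = 500L,
                                   seed = 1L) {
  assert_that(p > 0 && p <= 1, "p must lie in (0, 1]")
  assert_that(h2_prior > 0, "h2_prior must be > 0")
  mt <- match_sumstats_panel(sumstats, panel)
  M <- mt$n_matched
  assert_that(M > 0, "no variants matched between sumstats and panel")
  sigma2 <- h2_prior / (M * p)
  out <- with_seed(seed, {
    lapply(mt$blocks, function(bl) {
      m <- length(bl$beta)
      if (m == 0) return(NULL)
      R <- bl$block$R[bl$idx, bl$idx, drop = FALSE]
      if (sparse) R <- sparsify_block(R)
      ne <- effective_n(bl$n, bl$n_cases)
      beta_std <- (bl$beta / bl$se) / sqrt(ne)
      post <- .gibbs_block(R, beta_std, ne, sigma2, p,
                           as.integer(burn_in), as.integer(gibbs_iterations))
      w <- post * bl$se * sqrt(ne)
      data.frame(id = bl$variants$id, chr = bl$variants$chr,
                 pos = bl$variants$pos,
                 effect_allele = bl$variants$a1,
                 other_allele = bl$variants$a2,
                 weight = w, stringsAsFactors = FALSE)
    })
  })
  ws <- as.data.frame(data.table::rbindlist(out))
  weight_set(ws, trait = attr(sumstats, "trait") %||% NA_character_,
             ancestry = panel$ancestry, p = p, h2_prior = h2_prior,
             sparse = sparse, n_dropped = mt$n_dropped)
}

#' Construct a weight set
#'
#' Variant-level scoring weights with provenance metadata. Invariants: finite
#' weights, unique ids, effect allele differs from other allele.
#'
#' @param df data.frame with id, chr, pos, effect_allele, other_allele, weight.
#' @param ... metadata fields (trait, ancestry, p, s, sparse, ...).
#' @return a `weight_set`.
#' @export
weight_set <- function(df, ...) {
  assert_that(all(is.finite(df$weight)), "weights must be finite")
  assert_that(!anyDuplicated(df$id), "variant ids must be unique")
  assert_that(all(df$effect_allele != df$other_allele),
              "effect allele must differ from other allele")
  meta <- list(...)
  attr(df, "meta") <- meta
  class(df) <- c("weight_set", "data.frame")
  df
}

#' @export
print.weight_set <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("weight_set: %d variants [%s]\n", nrow(x),
              paste(names(m), vapply(m, function(v) paste(format(v), collapse = ","), ""),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Enumerate the candidate grid
#'
#' One weight set per (p, s, sparse) combination of the grid, with prior
#' heritability `s * h2_hat` (clipped to [1e-4, 0.99]). The default grid
#' yields 102 candidates. Each candidate's metadata records all three
#' hyperparameters. The sampler seed is derived per candidate from the grid
#' seed so the enumeration is reproducible yet candidates are independent.
#'
#' @param sumstats a `sumstats` data.frame.
#' @param panel matching `ld_panel`.
#' @param grid a `grid_config` (default [default_grid()]).
#' @param h2_hat optional externally supplied base heritability; when NULL it
#'   is estimated by [estimate_heritability_ldsc()].
#' @param min_variants passed to the heritability estimator.
#' @return list of `weight_set` objects.
#' @export
enumerate_grid <- function(sumstats, panel, grid = default_grid(),
                           h2_hat = NULL, min_variants = 200L) {
  assert_that(inherits(grid, "grid_config"), "grid must be a grid_config")
  if (is.null(h2_hat)) {
    h2_hat <- estimate_heritability_ldsc(sumstats, panel,
                                         min_variants = min_variants)$h2_hat
  }
  combos <- expand.grid(p = grid$causal_fractions, s = grid$h2_scales,
                        sparse = grid$sparse_flags,
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    p <- combos$p[i]; s <- combos$s[i]; sp <- combos$sparse[i]
    ws <- posterior_mean_effects(
      sumstats, panel, p = p, h2_prior = clip_h2(s * h2_hat), sparse = sp,
      gibbs_iterations = grid$gibbs_iterations, burn_in = grid$burn_in,
      seed = derive_seed(grid$seed, i))
    meta <- attr(ws, "meta")
    meta$s <- s
    meta$h2_hat <- h2_hat
    attr(ws, "meta") <- meta
    ws
  })
}

#' Write a weight set as a scoring file
#'
#' PGS-Catalog-style text format: `#` comment header lines carrying the
#' metadata, then tab-separated columns rsID, chr_name, chr_position,
#' effect_allele, other_allele, effect_weight. Weights are written with full
#' precision so files round-trip bit-exactly.
#'
#' @param ws a `weight_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weight_set <- function(ws, path) {
  meta <- attr(ws, "meta")
  hdr <- vapply(names(meta), function(k)
    sprintf("#%s=%s", k, paste(format(meta[[k]], digits = 17), collapse = ",")), "")
  con <- file(ensure_parent(path), "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste("rsID", "chr_name", "chr_position", "effect_allele",
                   "other_allele", "effect_weight", sep = "\t"), con)
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%.17g", ws$id, ws$chr, ws$pos,
                     ws$effect_allele, ws$other_allele, ws$weight), con)
  invisible(path)
}

#' Read a scoring file written by [write_weight_set()]
#'
#' @param path scoring file.
#' @return a `weight_set` with metadata restored (as character).
#' @export
read_weight_set <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", lines[h])
    k <- sub("=.*", "", kv)
    meta[[k]] <- utils::type.convert(sub("^[^=]*=", "", kv), as.is = TRUE)
  }
  df <- data.table::fread(text = lines[setdiff(seq_along(lines), hdr)])
  df <- data.frame(id = df$rsID, chr = df$chr_name, pos = df$chr_position,
                   effect_allele = df$effect_allele,
                   other_allele = df$other_allele,
                   weight = df$effect_weight, stringsAsFactors = FALSE)
  do.call(weight_set, c(list(df), meta))
}
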