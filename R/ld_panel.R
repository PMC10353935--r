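# Block LD reference panels: construction, validation, simulation and I/O.

#' Construct an LD reference panel
#'
#' An `ld_panel` is an ancestry-labelled list of LD blocks. Each block carries
#' a variant metadata table (`id`, `chr`, `pos`, `a1` effect allele, `a2`
#' other allele, `freq` effect-allele frequency) and the dense correlation
#' matrix of the block's genotypes. Blocks are mutually independent; there is
#' no cross-block LD.
#'
#' @param ancestry single ancestry label.
#' @param blocks list of blocks, each `list(variants = data.frame, R = matrix)`.
#' @return object of class `ld_panel`.
#' @export
ld_panel <- function(ancestry, blocks) {
  obj <- structure(list(ancestry = ancestry, blocks = blocks),
                   class = "ld_panel")
  validate_ld_panel(obj)
  obj
}

#' Validate an LD panel
#'
#' Checks the structural invariants: symmetric unit-diagonal correlation
#' matrices with eigenvalues >= -1e-8, frequencies strictly inside (0, 1) and
#' variant ids unique across all blocks.
#'
#' @param panel an `ld_panel`.
#' @return the panel, invisibly.
#' @export
validate_ld_panel <- function(panel) {
  ids <- character(0)
  for (b in panel$blocks) {
    v <- b$variants
    R <- b$R
    m <- nrow(v)
    assert_that(is.matrix(R) && nrow(R) == m && ncol(R) == m,
                "block correlation matrix does not match variant count")
    assert_that(max(abs(R - t(R))) < 1e-10, "correlation matrix not symmetric")
    assert_that(max(abs(diag(R) - 1)) < 1e-10, "correlation diagonal not 1")
    assert_that(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >=
                  -1e-8, "correlation matrix has eigenvalue < -1e-8")
    assert_that(all(v$freq > 0 & v$freq < 1),
                "allele frequencies must lie strictly in (0, 1)")
    ids <- c(ids, v$id)
  }
  assert_that(!anyDuplicated(ids), "variant ids duplicated across blocks")
  invisible(panel)
}

#' @export
print.ld_panel <- function(x, ...) {
  m <- sum(vapply(x$blocks, function(b) nrow(b$variants), 1L))
  cat(sprintf("ld_panel: ancestry %s, %d blocks, %d variants\n",
              x$ancestry, length(x$blocks), m))
  invisible(x)
}

#' Variant metadata of a panel, across blocks
#'
#' @param panel an `ld_panel`.
#' @return data.frame of variant metadata in block order.
#' @export
panel_variants <- function(panel) {
  as.data.frame(data.table::rbindlist(lapply(panel$blocks, function(b) b$variants)))
}

#' Number of variants in a panel
#'
#' @param panel an `ld_panel`.
#' @return integer count.
#' @export
panel_size <- function(panel) {
  sum(vapply(panel$blocks, function(b) nrow(b$variants), 1L))
}

#' Simulate a set of diverged LD panels
#'
#' Generates one block structure shared by all ancestries: block sizes drawn
#' uniformly from `block_size_range`, within-block correlations proposed by a
#' first-order autoregressive decay with adjacent-variant correlation
#' `exp(-decay_param)`. Ancestry divergence acts twice, mirroring how real
#' populations differ: the per-block AR(1) parameter is damped by a random
#' factor in `[1 - divergence, 1]`, and allele frequencies receive a
#' logit-scale shift shared by the block (sd `0.6 * sqrt(divergence)`) plus
#' small per-variant jitter (sd `0.15 * sqrt(divergence)`). Within a block
#' the ancestral frequencies follow a logit random walk (step sd 0.25) so
#' tightly linked variants have similar frequencies.
#'
#' The documented correlation of each block is the realised post-threshold
#' correlation of the latent-Gaussian genotype model: the AR(1) proposal is
#' mapped through the bivariate-normal threshold calibration (clipping
#' unattainable pairs at the Frechet bound), so [simulate_genotypes()]
#' reproduces the panel within Monte-Carlo error by construction. The
#' calibrated latent matrix is stored with the block.
#'
#' @param ancestries character vector of ancestry labels.
#' @param n_blocks number of LD blocks.
#' @param block_size_range length-2 integer range of block sizes (inclusive).
#' @param decay_param AR(1) decay rate; adjacent proposal correlation is
#'   `exp(-decay_param)`. Must be > 0.
#' @param ancestry_divergence divergence in `[0, 1]`; 0 gives identical panels.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return named list of `ld_panel` objects, one per ancestry.
#' @export
simulate_ld_panel_set <- function(ancestries, n_blocks, block_size_range,
                                  decay_param, ancestry_divergence, seed) {
  assert_that(all(block_size_range >= 1), "block sizes must be >= 1")
  assert_that(decay_param > 0, "decay_param must be > 0")
  assert_that(ancestry_divergence >= 0 && ancestry_divergence <= 1,
              "ancestry_divergence must lie in [0, 1]")
  rho_base <- exp(-decay_param)
  with_seed(seed, {
    sizes <- sample(seq(block_size_range[1], block_size_range[2]),
                    n_blocks, replace = TRUE)
    offsets <- c(0L, cumsum(sizes))
    # shared ancestral frequencies: logit random walk per block
    lgs0 <- lapply(sizes, function(m) {
      cumsum(c(stats::rnorm(1, 0, 1.2), stats::rnorm(m - 1, 0, 0.25)))
    })
    dv <- ancestry_divergence
    panels <- lapply(ancestries, function(anc) {
      blocks <- lapply(seq_len(n_blocks), function(b) {
        m <- sizes[b]
        damp <- if (dv > 0) 1 - dv * stats::runif(1) else 1
        rho <- rho_base * damp
        target <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
        lg <- lgs0[[b]]
        if (dv > 0) {
          lg <- lg + stats::rnorm(1, 0, 0.6 * sqrt(dv)) +
            stats::rnorm(m, 0, 0.15 * sqrt(dv))
        }
        f <- pmin(pmax(stats::plogis(lg), 0.05), 0.95)
        cal <- threshold_block(target, f)
        idx <- offsets[b] + seq_len(m)
        alleles <- matrix(c("A", "G", "C", "T")[
          1 + (idx %% 2) * 2 + rep(c(0, 1), each = m)], ncol = 2)
        variants <- data.frame(
          id = sprintf("rs%06d", idx),
          chr = 1L + ((b - 1L) %% 22L),
          pos = idx * 1000L,
          a1 = alleles[, 1], a2 = alleles[, 2],
          freq = f, stringsAsFactors = FALSE)
        list(variants = variants, R = cal$R, latent = cal$latent)
      })
      ld_panel(anc, blocks)
    })
    names(panels) <- ancestries
    panels
  })
}

#' Simulate a single-ancestry LD panel
#'
#' Convenience wrapper around [simulate_ld_panel_set()] for one ancestry.
#'
#' @inheritParams simulate_ld_panel_set
#' @param ancestry ancestry label.
#' @return an `ld_panel`.
#' @export
simulate_ld_panel <- function(n_blocks, block_size_range, decay_param,
                              ancestry_divergence = 0, seed,
                              ancestry = "ANC1") {
  simulate_ld_panel_set(ancestry, n_blocks, block_size_range, decay_param,
                        ancestry_divergence, seed)[[1]]
}

#' Per-variant LD scores
#'
#' The LD score of variant j is the sum of squared correlations with all
#' variants in its block (including itself); with all blocks of size 1 every
#' score is exactly 1.
#'
#' @param panel an `ld_panel`.
#' @return data.frame with columns `id`, `ldscore`.
#' @export
ld_scores <- function(panel) {
  data.table::rbindlist(lapply(panel$blocks, function(b) {
    data.frame(id = b$variants$id, ldscore = colSums(b$R^2))
  }))
}

#' Write an LD panel to a directory
#'
#' One subdirectory per panel: a `manifest.tsv` listing blocks plus, per
#' block, a variant table (`block_<k>.variants.tsv`) and a dense correlation
#' matrix (`block_<k>.cor.tsv`), all tab-separated text.
#'
#' @param panel an `ld_panel`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ld_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(block = seq_along(panel$blocks),
                    n_variants = vapply(panel$blocks,
                                        function(b) nrow(b$variants), 1L),
                    ancestry = panel$ancestry)
  data.table::fwrite(man, file.path(dir, "manifest.tsv"), sep = "\t")
  for (k in seq_along(panel$blocks)) {
    b <- panel$blocks[[k]]
    data.table::fwrite(b$variants,
                       file.path(dir, sprintf("block_%04d.variants.tsv", k)),
                       sep = "\t")
    data.table::fwrite(as.data.frame(b$R),
                       file.path(dir, sprintf("block_%04d.cor.tsv", k)),
                       sep = "\t", col.names = FALSE)
    if (!is.null(b$latent)) {
      data.table::fwrite(as.data.frame(b$latent),
                         file.path(dir, sprintf("block_%04d.latent.tsv", k)),
                         sep = "\t", col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read an LD panel written by [write_ld_panel()]
#'
#' @param dir panel directory.
#' @return an `ld_panel`.
#' @export
read_ld_panel <- function(dir) {
  man <- data.table::fread(file.path(dir, "manifest.tsv"))
  blocks <- lapply(man$block, function(k) {
    v <- as.data.frame(data.table::fread(
      file.path(dir, sprintf("block_%04d.variants.tsv", k))))
    R <- as.matrix(data.table::fread(
      file.path(dir, sprintf("block_%04d.cor.tsv", k)), header = FALSE))
    dimnames(R) <- NULL
    blk <- list(variants = v, R = R)
    lf <- file.path(dir, sprintf("block_%04d.latent.tsv", k))
    if (file.exists(lf)) {
      L <- as.matrix(data.table::fread(lf, header = FALSE))
      dimnames(L) <- NULL
      blk$latent <- L
    }
    blk
  })
  ld_panel(man$ancestry[1], blocks)
}
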