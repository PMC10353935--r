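# Pipeline orchestration: validated config, staged execution with persisted
# artifacts and a hash manifest.

#' Default pipeline configuration
#'
#' The default fixture: 3 ancestries, 2,000 variants in 40 LD blocks, two
#' traits (disease plus one quantitative risk factor), 20,000 training and
#' 20,000 validation samples, 5% prevalence, 12-year follow-up and the full
#' 102-candidate shrinkage grid.
#'
#' @param name run name.
#' @param seed integer run seed.
#' @return a validated `pipeline_config` list.
#' @export
default_pipeline_config <- function(name = "default", seed = 1L) {
  validate_config(list(name = name, seed = seed))
}

config_defaults <- function() {
  list(
    name = "run",
    seed = 1L,
    simulation = list(
      ancestries = c("ANC1", "ANC2", "ANC3"),
      n_traits = 2L,
      n_blocks = 40L,
      block_size_range = c(30L, 70L),
      decay_param = 0.25,
      ancestry_divergence = 0.5,
      p_causal = 0.05,
      h2 = c(0.3, 0.3),
      rg_anc = 0.8,
      rg_trait = 0.5,
      prevalence_K = 0.05,
      incident_rate = 0.004,
      followup_years = 12,
      hazard_per_sd = 0.5,
      clinical_hazard_coef = 0.5,
      n_gwas = 20000L,
      n_train = 20000L,
      n_val = 20000L),
    grid = list(
      causal_fractions = NULL,   # NULL -> the default 17-value ladder
      h2_scales = c(0.7, 1, 1.4),
      sparse_flags = c(FALSE, TRUE),
      gibbs_iterations = 500L,
      burn_in = 500L),
    mixing = list(
      covariates = baseline_covariates()),
    evaluation = list(
      nri_threshold = 0.075,
      n_boot = 100L,
      fold_thresholds = c(3, 4, 5)))
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and checks value ranges; errors name
#' the offending key. Accepts a list or a path to a JSON file.
#'
#' @param config list or JSON file path.
#' @return a `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), "config file %s does not exist", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- config_defaults()
  merged <- merge_config(def, config, path = "")
  cfg <- merged
  s <- cfg$simulation
  assert_that(s$p_causal > 0 && s$p_causal <= 1,
              "simulation.p_causal must lie in (0, 1], got %s", s$p_causal)
  assert_that(all(s$h2 >= 0 & s$h2 < 1), "simulation.h2 must lie in [0, 1)")
  assert_that(s$prevalence_K > 0 && s$prevalence_K < 1,
              "simulation.prevalence_K must lie in (0, 1)")
  assert_that(s$incident_rate > 0, "simulation.incident_rate must be > 0")
  assert_that(length(s$h2) == s$n_traits,
              "simulation.h2 must have one value per trait")
  g <- cfg$grid
  cfg$grid_config <- grid_config(
    causal_fractions = g$causal_fractions %||% default_grid()$causal_fractions,
    h2_scales = g$h2_scales, sparse_flags = g$sparse_flags,
    gibbs_iterations = g$gibbs_iterations, burn_in = g$burn_in,
    seed = derive_seed(cfg$seed, 100))
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(def, cfg, path) {
  if (!is.list(def)) return(cfg)
  unknown <- setdiff(names(cfg), names(def))
  assert_that(length(unknown) == 0, "unknown config key%s: %s",
              if (length(unknown) > 1) "s" else "",
              paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  out <- def
  for (k in names(cfg)) {
    out[[k]] <- if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      merge_config(def[[k]], cfg[[k]], paste0(path, ".", k))
    } else cfg[[k]]
  }
  out
}

#' Run the full pipeline
#'
#' Executes simulate -> GWAS -> shrink -> tune -> two-layer mix -> flatten ->
#' evaluate, persisting every intermediate artifact under `out_dir` with a
#' manifest of md5 hashes and a per-stage log. Identical config and seed give
#' identical manifests. Tuning, selection and mixing all use the first
#' ancestry's training cohort; evaluation uses that ancestry's held-out
#' validation cohort with training-derived standardization constants.
#'
#' @param config a `pipeline_config` (or list / JSON path accepted by
#'   [validate_config()]).
#' @param out_dir run directory (created; must not contain a previous
#'   manifest).
#' @return list with the run artifacts (invisible paths in `manifest`):
#'   `final_weights`, `report`, `mix_layer1`, `mix_layer2`, `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("[stage %s] start", name)
    r <- tryCatch(expr, error = function(e) {
      log_line("[stage %s] FAILED: %s", name, conditionMessage(e))
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_line("[stage %s] done", name)
    r
  }
  s <- cfg$simulation
  seed <- cfg$seed

  panels <- stage("panels", {
    ps <- simulate_ld_panel_set(s$ancestries, s$n_blocks, s$block_size_range,
                                s$decay_param, s$ancestry_divergence,
                                seed = derive_seed(seed, 1))
    for (a in names(ps)) write_ld_panel(ps[[a]], file.path(out_dir, "panels", a))
    ps
  })
  effects <- stage("effects", {
    simulate_true_effects(panels, s$p_causal, s$h2, s$rg_anc, s$rg_trait,
                          n_traits = s$n_traits, seed = derive_seed(seed, 2))
  })
  sim_coh <- function(i, n, k) {
    simulate_cohort(panels[[i]], n, effects, seed = derive_seed(seed, k),
                    prevalence_K = s$prevalence_K,
                    incident_rate = s$incident_rate,
                    followup_years = s$followup_years,
                    hazard_per_sd = s$hazard_per_sd,
                    clinical_hazard_coef = s$clinical_hazard_coef,
                    ancestry_index = i)
  }
  # discovery cohorts (one per ancestry, GWAS only) are disjoint from the
  # training cohort used for tuning/selection/mixing, mirroring the
  # two-stage design: external discovery GWAS, one training biobank
  cohorts <- stage("cohorts", {
    lapply(seq_along(panels), function(i) {
      list(discovery = sim_coh(i, s$n_gwas, 10 + i),
           train = if (i == 1) sim_coh(i, s$n_train, 30 + i) else NULL,
           val = if (i == 1) sim_coh(i, s$n_val, 40 + i) else NULL)
    }) |> stats::setNames(names(panels))
  })
  trait_cols <- c("prevalent_case",
                  if (s$n_traits > 1) paste0("trait", 2:s$n_traits))
  sumstats <- stage("gwas", {
    out <- list()
    for (a in names(panels)) {
      for (tc in trait_cols) {
        mt <- if (tc == "prevalent_case") "logistic" else "linear"
        ss <- run_gwas(cohorts[[a]]$discovery, tc, mt)
        attr(ss, "trait") <- tc
        key <- paste(tc, a, sep = ".")
        write_sumstats(ss, file.path(out_dir, "sumstats",
                                     paste0(key, ".tsv")))
        out[[key]] <- ss
      }
    }
    out
  })
  train <- cohorts[[1]]$train
  val <- cohorts[[1]]$val
  best <- stage("shrink_tune", {
    out <- list()
    for (key in names(sumstats)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      pan <- panels[[parts[2]]]
      cand <- enumerate_grid(sumstats[[key]], pan, grid = cfg$grid_config,
                             min_variants = min(200L, panel_size(pan) %/% 2L))
      b <- tune_best_candidate(cand, train, cfg$mixing$covariates)
      write_weight_set(b, file.path(out_dir, "weights",
                                    paste0("best_", key, ".txt")))
      out[[key]] <- b
    }
    out
  })
  mixres <- stage("mix", {
    two_layer_mix(best, train, traits = trait_cols,
                  ancestries = names(panels),
                  covariates = cfg$mixing$covariates)
  })
  final_ws <- stage("flatten", {
    ws <- mixres$final_weights
    write_weight_set(ws, file.path(out_dir, "weights", "final.txt"))
    ws
  })
  report <- stage("evaluate", {
    sc_train <- score_cohort(train, final_ws)
    sc <- score_cohort(val, final_ws, constants = sc_train$constants)
    ev <- cfg$evaluation
    orr <- odds_per_sd(sc$standardized, val, cfg$mixing$covariates)
    hrr <- hazard_per_sd(sc$standardized, val, cfg$mixing$covariates)
    lr2 <- liability_r2(sc$standardized, val, s$prevalence_K,
                        cfg$mixing$covariates)
    keep <- val$pheno$prevalent_case == 0
    hc <- harrell_c(sc$standardized[keep], val$pheno$follow_up_time[keep],
                    val$pheno$incident_case[keep])
    imod <- integrated_risk_model(sc$standardized, val$pheno$clinical_risk_10yr,
                                  val)
    new_risk <- pmin(pmax(val$pheno$clinical_risk_10yr *
                            exp(imod$fit$coefficients["gps"] * sc$standardized),
                          0), 1)
    nri <- net_reclassification(val$pheno$clinical_risk_10yr, new_risk,
                                val$pheno$incident_case,
                                threshold = ev$nri_threshold,
                                n_boot = ev$n_boot,
                                seed = derive_seed(seed, 90))
    ptab <- percentile_prevalence(sc$standardized, val$pheno$prevalent_case)
    ttab <- tail_fraction_scan(sc$standardized, val, ev$fold_thresholds,
                               "top", cfg$mixing$covariates)
    rep <- eval_report(or_sd = orr, hr_sd = hrr, liability_r2 = lr2,
                       harrell_c = hc, nri = nri,
                       percentile_table = ptab, tail_table = ttab,
                       integrated = imod)
    write_eval_report(rep, file.path(out_dir, "report"))
    rep
  })
  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          c("manifest.tsv", "pipeline.log")))
    man <- data.frame(file = files,
                      md5 = unname(tools::md5sum(file.path(out_dir, files))))
    data.table::fwrite(man, file.path(out_dir, "manifest.tsv"), sep = "\t")
    man
  })
  invisible(list(final_weights = final_ws, report = report,
                 mix_layer1 = mixres$layer1, mix_layer2 = mixres$layer2,
                 manifest = manifest,
                 manifest_path = file.path(out_dir, "manifest.tsv")))
}

#' Two-layer mixing of tuned candidate scores on a training cohort
#'
#' Layer 1: per trait, the tuned ancestry-specific scores are standardized on
#' the training cohort, reduced by stepwise AIC and combined by logistic
#' mixing weights (prevalent disease outcome throughout, per the two-layer
#' design: every mixing regression predicts the disease). Layer 2: the
#' layer-1 trait-level combined scores are themselves standardized, selected
#' and mixed. Flattening yields the final variant-level weight set.
#'
#' @param best named list of tuned `weight_set`s, keys `trait.ancestry`.
#' @param train training `cohort`.
#' @param traits character vector of trait column names (first = disease).
#' @param ancestries ancestry labels.
#' @param covariates covariate columns for the mixing regressions.
#' @return list: `layer1` (per-trait mix models), `layer2`, `final_weights`,
#'   `combined_train` (final combined score on the training cohort).
#' @export
two_layer_mix <- function(best, train, traits, ancestries,
                          covariates = baseline_covariates()) {
  y <- train$pheno$prevalent_case
  cov_df <- train$pheno[, covariates, drop = FALSE]
  layer1 <- list()
  sd1 <- list()
  weightsets <- list()
  trait_scores <- list()
  for (tr in traits) {
    comp_cols <- list()
    sds <- list()
    weightsets[[tr]] <- list()
    for (a in ancestries) {
      ws <- best[[paste(tr, a, sep = ".")]]
      if (is.null(ws)) next
      sc <- score_cohort(train, ws)
      grp <- train$pheno$ancestry[1]
      comp_cols[[a]] <- sc$standardized
      sds[[a]] <- sc$constants[[grp]]$sd
      weightsets[[tr]][[a]] <- ws
    }
    assert_that(length(comp_cols) > 0, "no usable components for trait %s", tr)
    comp <- as.data.frame(comp_cols)
    sel <- stepwise_aic_select(comp, y, cov_df)
    assert_that(length(sel$selected) > 0,
                "stepwise selection removed every component for trait %s", tr)
    mm <- fit_mixing_weights(as.matrix(comp)[, sel$selected, drop = FALSE], y,
                             cov_df, standardization = sds[sel$selected],
                             layer = 1L, aic_trace = sel$aic_trace)
    layer1[[tr]] <- mm
    sd1[[tr]] <- sds
    trait_scores[[tr]] <- combine_scores(mm, comp)
  }
  trait_scores <- as.data.frame(trait_scores)
  # layer 2 over standardized trait-level scores
  sd2 <- lapply(trait_scores, stats::sd)
  t_std <- scale(as.matrix(trait_scores))
  layer2 <- NULL
  if (ncol(t_std) > 1) {
    sel2 <- stepwise_aic_select(t_std, y, cov_df)
    keep2 <- if (traits[1] %in% sel2$selected) sel2$selected else
      c(traits[1], sel2$selected)   # the disease score always participates
    layer2 <- fit_mixing_weights(t_std[, keep2, drop = FALSE], y, cov_df,
                                 standardization = sd2[keep2], layer = 2L,
                                 aic_trace = sel2$aic_trace)
    combined_train <- combine_scores(layer2, t_std)
  } else {
    combined_train <- trait_scores[[1]]
  }
  final <- flatten_weights(layer1, layer2, weightsets, sd1 = sd1, sd2 = sd2)
  list(layer1 = layer1, layer2 = layer2, final_weights = final,
       combined_train = combined_train)
}

#' Serialize a mix model to structured text
#'
#' @param mix a `mix_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mix_model <- function(mix, path) {
  obj <- list(layer = mix$layer, components = mix$components,
              beta = as.list(mix$beta),
              covariate_coef = as.list(mix$covariate_coef),
              standardization = mix$standardization,
              aic_trace = mix$aic_trace)
  jsonlite::write_json(obj, ensure_parent(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a mix model written by [write_mix_model()]
#'
#' @param path file path.
#' @return a `mix_model`.
#' @export
read_mix_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(layer = o$layer, components = o$components,
                 beta = unlist(o$beta), covariate_coef = unlist(o$covariate_coef),
                 standardization = o$standardization,
                 aic_trace = o$aic_trace),
            class = "mix_model")
}
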