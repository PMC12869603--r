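PIPELINE_STAGES <- c("simulate", "connectome", "identifiability", "icc",
                     "differential", "features", "classify", "stats")

default_pipeline_config <- function() {
  list(
    simulate = list(),
    input_dir = NULL,
    output_dir = "brainfp_run",
    stages = PIPELINE_STAGES,
    seed = 1L,
    fisher_z = FALSE,
    residualize_scope = "per_group",
    subsample = list(n_iter = 100L, fraction = 0.8),
    identifiability = list(bootstrap_iter = 1000L, match_scope = "both"),
    differential = list(n_perm = 1000L, alpha = 0.01, use_subsample = TRUE),
    classifier = list(family = "random_forest", n_perm = 1000L,
                      threshold_percent = 15, inner_folds = 5L)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills every omitted setting with
#' its default (1000 permutations and bootstrap iterations, 100 x 80%
#' ICC subsampling, adjusted-p threshold 0.01, responder boundary 15%),
#' and collects rule violations with their config paths. An empty input
#' yields the fully defaulted simulate-mode configuration.
#'
#' @param x path to a YAML file, a list, or `NULL`.
#' @return list with `config` (normalized) and `violations` (character
#'   vector, empty when the config is valid).
#' @export
validate_config <- function(x = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop_brainfp("config file not found: %s", x)
    x <- yaml::read_yaml(x) %||% list()
  }
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop_brainfp("config must parse to a mapping")
  cfg <- utils::modifyList(default_pipeline_config(), x, keep.null = TRUE)
  v <- character(0)
  if (!is.null(cfg$input_dir) && length(x$simulate %||% list()) > 0) {
    v <- c(v, "input_dir/simulate: exactly one of input_dir and simulate may be set")
  }
  fr <- cfg$subsample$fraction
  if (!is_scalar_number(fr) || fr <= 0 || fr > 1) {
    v <- c(v, "subsample.fraction must be in (0,1]")
  }
  if (!is_scalar_number(cfg$subsample$n_iter) || cfg$subsample$n_iter < 1) {
    v <- c(v, "subsample.n_iter must be a positive integer")
  }
  if (!is_scalar_number(cfg$differential$alpha) ||
      cfg$differential$alpha <= 0 || cfg$differential$alpha >= 1) {
    v <- c(v, "differential.alpha must be in (0,1)")
  }
  if (!is_scalar_number(cfg$differential$n_perm) || cfg$differential$n_perm < 1) {
    v <- c(v, "differential.n_perm must be a positive integer")
  }
  if (!cfg$classifier$family %in% CLASSIFIER_FAMILIES) {
    v <- c(v, sprintf("classifier.family must be one of: %s",
                      paste(CLASSIFIER_FAMILIES, collapse = ", ")))
  }
  if (!is_scalar_number(cfg$classifier$threshold_percent) ||
      cfg$classifier$threshold_percent <= 0) {
    v <- c(v, "classifier.threshold_percent must be positive")
  }
  bad_stage <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad_stage) > 0) {
    v <- c(v, sprintf("stages: unknown stage(s) %s", paste(bad_stage, collapse = ", ")))
  }
  if (!cfg$residualize_scope %in% c("per_group", "pooled")) {
    v <- c(v, "residualize_scope must be per_group or pooled")
  }
  list(config = cfg, violations = v)
}

#' Run the fingerprinting pipeline end to end
#'
#' Executes the requested stages in dependency order — simulate (or load
#' fixtures), split-half connectome construction with residualization,
#' identifiability metrics, subsampled edgewise ICC with network
#' profiles, the differential-reliability permutation test with masks,
#' masked-graph topology features, responder classification with
#' permutation significance, and group statistics — writing every stage
#' artifact plus a checksummed manifest to the output directory.
#' Re-running with an identical configuration reproduces identical
#' artifacts.
#'
#' @param cfg a config accepted by [validate_config()] (path, list, or
#'   `NULL` for defaults).
#' @return the run manifest (list of stage outputs and file checksums),
#'   invisibly; the in-memory stage results are attached as the
#'   `"state"` attribute.
#' @export
run_pipeline <- function(cfg = NULL) {
  vc <- validate_config(cfg)
  if (length(vc$violations) > 0) {
    stop_brainfp("invalid configuration:\n%s",
                 paste("-", vc$violations, collapse = "\n"))
  }
  cfg <- vc$config
  stages <- cfg$stages
  need <- function(stage, deps) {
    missing <- setdiff(deps, stages)
    if (length(missing) > 0 && !(stage %in% c("simulate"))) {
      stop_brainfp("stage '%s' requires upstream stage(s): %s",
                   stage, paste(missing, collapse = ", "))
    }
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())

  # --- data acquisition ------------------------------------------------
  if ("simulate" %in% stages) {
    cc_args <- cfg$simulate
    if (is.null(cc_args$seed)) cc_args$seed <- cfg$seed
    cohort_cfg <- do.call(cohort_config, cc_args)
    state$cohort <- generate_cohort(cohort_cfg)
    state$clinical <- generate_clinical_outcomes(state$cohort)
    write_fixture_set(state$cohort, file.path(cfg$output_dir, "cohort"),
                      state$clinical)
    state$atlas <- state$cohort$atlas
    state$covariates <- state$cohort$covariates
    state$ts <- state$cohort$ts
  } else if (!is.null(cfg$input_dir)) {
    fx <- load_fixture_set(cfg$input_dir)
    state$ts <- fx$ts
    state$atlas <- fx$atlas
    state$covariates <- fx$covariates
    state$clinical <- fx$clinical
  } else if (length(setdiff(stages, "simulate")) > 0) {
    stop_brainfp("stage '%s' requires upstream stage(s): simulate (or input_dir)",
                 setdiff(stages, "simulate")[1])
  }

  groups <- vapply(state$ts %||% list(), `[[`, character(1), "group")

  if ("connectome" %in% stages) {
    need("connectome", "simulate")
    pairs <- lapply(state$ts, compute_split_fc)
    maybe_z <- function(m) if (isTRUE(cfg$fisher_z)) atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)) else m
    full_fc <- t(vapply(state$ts, function(ts) {
      vectorize_fc(stats::cor(ts$data))
    }, numeric(nrow(edge_index(ncol(state$ts[[1]]$data))))))
    rownames(full_fc) <- vapply(state$ts, `[[`, character(1), "subject_id")
    halves <- list(
      test = maybe_z(edge_matrix(pairs, "test")),
      retest = maybe_z(edge_matrix(pairs, "retest")),
      full = maybe_z(full_fc)
    )
    resid <- list()
    for (h in names(halves)) {
      if (cfg$residualize_scope == "pooled") {
        resid[[h]] <- residualize_edges(halves[[h]], state$covariates)
      } else {
        parts <- lapply(unique(groups), function(g) {
          residualize_edges(halves[[h]][groups == g, , drop = FALSE],
                            state$covariates[state$covariates$group == g, ])
        })
        resid[[h]] <- do.call(rbind, parts)[rownames(halves[[h]]), , drop = FALSE]
      }
    }
    state$edges <- list(raw = halves, resid = resid)
    state$groups <- groups
  }

  group_rows <- function(mat, g) mat[groups == g, , drop = FALSE]

  if ("identifiability" %in% stages) {
    need("identifiability", c("simulate", "connectome"))
    state$ident <- lapply(unique(groups), function(g) {
      im_res <- build_identifiability_matrix(
        group_rows(state$edges$resid$test, g),
        group_rows(state$edges$resid$retest, g))
      im_raw <- build_identifiability_matrix(
        group_rows(state$edges$raw$test, g),
        group_rows(state$edges$raw$retest, g))
      list(group = g,
           matrix = im_res,
           metrics = compute_identifiability_metrics(
             im_res, match_scope = cfg$identifiability$match_scope),
           resid_vs_raw = bootstrap_idiff_norm(
             im_raw, im_res, paired = TRUE,
             n_iter = cfg$identifiability$bootstrap_iter,
             seed = derive_seed(cfg$seed, 11L)))
    })
    names(state$ident) <- unique(groups)
    ident_json <- lapply(state$ident, function(z) {
      list(group = z$group,
           i_self = as.list(z$metrics$i_self),
           i_others = as.list(z$metrics$i_others),
           i_diff = z$metrics$i_diff,
           i_diff_norm = z$metrics$i_diff_norm,
           sr = z$metrics$sr,
           residualization_delta = list(
             estimate = z$resid_vs_raw$estimate,
             ci = c(z$resid_vs_raw$ci_low, z$resid_vs_raw$ci_high),
             p_value = z$resid_vs_raw$p_value))
    })
    jsonlite::write_json(ident_json,
                         file.path(cfg$output_dir, "identifiability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("icc" %in% stages) {
    need("icc", c("simulate", "connectome"))
    sub_cfg <- icc_subsample_config(n_iter = cfg$subsample$n_iter,
                                    fraction = cfg$subsample$fraction,
                                    seed = derive_seed(cfg$seed, 21L))
    state$icc <- lapply(unique(groups), function(g) {
      icc <- subsampled_icc(group_rows(state$edges$resid$test, g),
                            group_rows(state$edges$resid$retest, g),
                            sub_cfg)
      rownames(icc$values) <- colnames(icc$values) <- state$atlas$region_id
      list(group = g, icc = icc,
           nodal = icc_nodal_strength(icc),
           profile = network_icc_profile(icc, state$atlas))
    })
    names(state$icc) <- unique(groups)
    for (z in state$icc) {
      utils::write.table(round(z$icc$values, 10),
                         file.path(cfg$output_dir, sprintf("icc_%s.tsv", z$group)),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    if (length(state$icc) == 2) {
      ranks <- lapply(state$icc, function(z) z$profile$ranking)
      state$concordance <- ranking_concordance(
        ranks[[1]], ranks[[2]], n_perm = 1000,
        seed = derive_seed(cfg$seed, 22L))
    }
    icc_json <- lapply(state$icc, function(z) {
      list(group = z$group,
           network_means = as.list(z$profile$network_means),
           whole_brain_mean = z$profile$whole_brain_mean,
           ranking = z$profile$ranking)
    })
    if (!is.null(state$concordance)) {
      icc_json$concordance <- list(w = state$concordance$w,
                                   p_value = state$concordance$p_value)
    }
    jsonlite::write_json(icc_json, file.path(cfg$output_dir, "icc_profiles.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("differential" %in% stages) {
    need("differential", c("simulate", "connectome", "icc"))
    if (length(unique(groups)) != 2) {
      stop_brainfp("differential stage requires two groups")
    }
    sub <- NULL
    if (isTRUE(cfg$differential$use_subsample)) {
      sub <- icc_subsample_config(n_iter = cfg$subsample$n_iter,
                                  fraction = cfg$subsample$fraction,
                                  seed = derive_seed(cfg$seed, 23L))
    }
    ga <- "control"; gb <- "patient"
    state$perm <- permutation_test_icc_diff(
      list(test = group_rows(state$edges$resid$test, ga),
           retest = group_rows(state$edges$resid$retest, ga)),
      list(test = group_rows(state$edges$resid$test, gb),
           retest = group_rows(state$edges$resid$retest, gb)),
      n_perm = cfg$differential$n_perm,
      seed = derive_seed(cfg$seed, 31L),
      subsample = sub)
    state$diff <- state$perm$observed_diff
    state$masks <- extract_edge_masks(state$diff, state$perm,
                                      alpha = cfg$differential$alpha)
    state$blocks <- network_block_summary(state$diff, state$masks, state$atlas)
    idx <- edge_index(nrow(state$diff$values))
    sig <- state$masks$a_gt_b$edges | state$masks$b_gt_a$edges
    edge_tab <- data.frame(
      region_i = state$atlas$region_id[idx$i[sig]],
      region_j = state$atlas$region_id[idx$j[sig]],
      diff = state$diff$edge_values[sig],
      p_raw = state$perm$p_raw[sig],
      p_adj = state$perm$p_adj[sig],
      direction = ifelse(state$diff$edge_values[sig] > 0,
                         "control_gt_patient", "patient_gt_control"))
    utils::write.table(edge_tab, file.path(cfg$output_dir, "differential_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("features" %in% stages) {
    need("features", c("simulate", "connectome", "icc", "differential"))
    mask <- state$masks$a_gt_b
    if (mask$n_edges == 0) stop_brainfp("empty discriminative subnetwork")
    pat_ids <- rownames(state$edges$resid$full)[groups == "patient"]
    graphs <- lapply(pat_ids, function(sid) {
      fc <- devectorize_fc(state$edges$resid$full[sid, ], diag_value = 0)
      suppressMessages(apply_edge_mask(fc, mask))
    })
    names(graphs) <- pat_ids
    state$features <- graph_feature_table(graphs)
    utils::write.csv(state$features, file.path(cfg$output_dir, "features.csv"))
  }

  if ("classify" %in% stages) {
    need("classify", c("simulate", "connectome", "icc", "differential", "features"))
    clinical <- label_responders(state$clinical,
                                 cfg$classifier$threshold_percent)
    ord <- match(rownames(state$features), clinical$subject_id)
    if (anyNA(ord)) stop_brainfp("clinical table misses featured subjects")
    spec <- model_spec(cfg$classifier$family,
                       inner_folds = cfg$classifier$inner_folds,
                       seed = derive_seed(cfg$seed, 41L))
    state$cv <- permutation_significance(
      state$features, clinical$responder[ord], spec,
      n_perm = cfg$classifier$n_perm,
      seed = derive_seed(cfg$seed, 42L))
    report <- list(
      family = cfg$classifier$family,
      metrics = as.list(state$cv$observed$metrics),
      p_raw = as.list(state$cv$p_raw),
      p_adj = as.list(state$cv$p_adj),
      importances = as.list(state$cv$observed$importances %||% list()))
    jsonlite::write_json(report, file.path(cfg$output_dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(state$cv$observed$per_fold_predictions,
                     file.path(cfg$output_dir, "predictions.csv"),
                     row.names = FALSE)
  }

  if ("stats" %in% stages) {
    need("stats", c("simulate", "connectome", "identifiability"))
    res <- list()
    if (length(state$ident) == 2) {
      res$i_self_between_groups <- compare_groups(
        state$ident[[1]]$metrics$i_self, state$ident[[2]]$metrics$i_self)
      res$i_others_between_groups <- compare_groups(
        state$ident[[1]]$metrics$i_others, state$ident[[2]]$metrics$i_others)
      res$i_self_vs_i_others <- lapply(state$ident, function(z) {
        compare_groups(z$metrics$i_self, z$metrics$i_others, paired = TRUE)
      })
    }
    if (!is.null(state$clinical)) {
      res$updrs_pre_post <- compare_groups(state$clinical$updrs_bl,
                                           state$clinical$updrs_fu,
                                           paired = TRUE)
    }
    state$stats <- res
    jsonlite::write_json(
      lapply(res, function(r) if (inherits(r, "comparison_result")) unclass(r)
             else lapply(r, unclass)),
      file.path(cfg$output_dir, "group_statistics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }

  files <- setdiff(list.files(cfg$output_dir, recursive = TRUE,
                              full.names = FALSE), "manifest.json")
  manifest <- list(
    config = cfg[setdiff(names(cfg), "stages")],
    stages_run = stages,
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(cfg$output_dir, files))))
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "state") <- state
  invisible(manifest)
}
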