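#' Configuration for the synthetic cohort generator
#'
#' Describes a two-group cohort (controls and patients) of parcellated
#' BOLD time series generated from a latent factor model. Each subject's
#' signal mixes a group-common component, a subject-unique component (the
#' fingerprint), and white noise, with variance shares controlled by
#' `group_share` and `fingerprint_share`. Stability differences between
#' groups are planted by remixing the subject-unique component between
#' scan halves inside selected network blocks, which lowers edgewise
#' test-retest reliability there while leaving mean connectivity
#' unchanged.
#'
#' @param n_per_group subjects per group (default 23).
#' @param n_regions atlas size (default 100; 400 mirrors a full-scale
#'   cortical parcellation).
#' @param n_timepoints scan length in samples (default 400; halves get
#'   `floor(T/2)` and the remainder).
#' @param network_sizes integer partition of the regions into the 7
#'   canonical networks (named or in canonical order); defaults to a
#'   near-even split.
#' @param fingerprint_share fraction of signal variance carried by the
#'   subject-unique component (default 0.5).
#' @param group_share fraction carried by the group-common component
#'   (default 0.2).
#' @param noise_sd residual noise scale (default 1; residual variance is
#'   `(1 - fingerprint_share - group_share) * noise_sd^2`).
#' @param stability_diff_blocks list of blocks where one group's
#'   subject-unique component is partially regenerated between halves;
#'   each entry is `list(network_i =, network_j =, direction =, magnitude =)`
#'   with `direction` one of `"control_gt_patient"` (patients attenuated)
#'   or `"patient_gt_control"` (controls attenuated) and `magnitude` in
#'   \[0, 1\]. Default plants patient attenuation in DMN-DMN and DAN-DMN
#'   and control attenuation in VN-VN (disjoint region sets, so the two
#'   directions do not dilute each other).
#' @param covariate_effects named numeric vector of per-covariate
#'   edgewise effect scales (loading-perturbation units); default a small
#'   age effect.
#' @param outcome_coupling strength of the link between each patient's
#'   planted-subnetwork connectivity and responder status (default 2;
#'   0 makes outcomes independent of the features).
#' @param responder_fraction target responder share among patients
#'   (default 13/23).
#' @param seed master RNG seed.
#' @param n_factors_subject,n_factors_group latent factor counts; the
#'   subject factor count sets the edgewise signal scale and with the
#'   defaults yields split-half self-similarity near 0.6 at T = 400.
#' @return validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 23,
                          n_regions = 100,
                          n_timepoints = 400,
                          network_sizes = NULL,
                          fingerprint_share = 0.5,
                          group_share = 0.2,
                          noise_sd = 1,
                          stability_diff_blocks = NULL,
                          covariate_effects = c(age = 0.05),
                          outcome_coupling = 2,
                          responder_fraction = 13 / 23,
                          seed = 1,
                          n_factors_subject = 30,
                          n_factors_group = 6) {
  if (is.null(network_sizes)) {
    network_sizes <- rep(n_regions %/% 7L, 7L)
    extra <- n_regions %% 7L
    if (extra > 0) network_sizes[seq_len(extra)] <- network_sizes[seq_len(extra)] + 1L
  }
  if (is.null(names(network_sizes))) names(network_sizes) <- NETWORK_LABELS
  if (!identical(sort(names(network_sizes)), sort(NETWORK_LABELS))) {
    stop_brainfp("network_sizes must be named with the 7 canonical labels")
  }
  network_sizes <- network_sizes[NETWORK_LABELS]
  if (sum(network_sizes) != n_regions) {
    stop_brainfp("network_sizes sums to %d but n_regions is %d",
                 sum(network_sizes), n_regions)
  }
  if (fingerprint_share < 0 || group_share < 0 ||
      fingerprint_share + group_share > 1) {
    stop_brainfp("shares must be >= 0 with fingerprint_share + group_share <= 1")
  }
  if (n_timepoints < 4) {
    stop_brainfp("n_timepoints must be >= 4 (two halves with >= 2 samples each)")
  }
  if (responder_fraction <= 0 || responder_fraction >= 1) {
    stop_brainfp("responder_fraction must be in (0, 1)")
  }
  if (noise_sd <= 0) stop_brainfp("noise_sd must be positive")
  if (is.null(stability_diff_blocks)) {
    stability_diff_blocks <- list(
      list(network_i = "DMN", network_j = "DMN",
           direction = "control_gt_patient", magnitude = 0.8),
      list(network_i = "DAN", network_j = "DMN",
           direction = "control_gt_patient", magnitude = 0.8),
      list(network_i = "VN", network_j = "VN",
           direction = "patient_gt_control", magnitude = 0.8)
    )
  }
  for (b in stability_diff_blocks) {
    if (!all(c(b$network_i, b$network_j) %in% NETWORK_LABELS)) {
      stop_brainfp("stability block names unknown network: %s-%s",
                   b$network_i, b$network_j)
    }
    if (!b$direction %in% c("control_gt_patient", "patient_gt_control")) {
      stop_brainfp("stability block direction must be control_gt_patient or patient_gt_control")
    }
    if (!is_scalar_number(b$magnitude) || b$magnitude < 0 || b$magnitude > 1) {
      stop_brainfp("stability block magnitude must be in [0, 1]")
    }
  }
  if (n_per_group < 2) stop_brainfp("n_per_group must be >= 2")
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         network_sizes = network_sizes,
         fingerprint_share = fingerprint_share,
         group_share = group_share,
         noise_sd = noise_sd,
         stability_diff_blocks = stability_diff_blocks,
         covariate_effects = covariate_effects,
         outcome_coupling = outcome_coupling,
         responder_fraction = responder_fraction,
         seed = as.integer(seed),
         n_factors_subject = as.integer(n_factors_subject),
         n_factors_group = as.integer(n_factors_group)),
    class = "cohort_config"
  )
}

# row-normalize a loading matrix so each region draws unit variance from
# the component (zero rows are left at zero)
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Generate a synthetic two-group cohort
#'
#' Simulates parcellated time series for `n_per_group` controls and
#' patients from the latent factor model described in [cohort_config()].
#' Both scan halves of a subject share the same subject-unique loading
#' matrix (the fingerprint), except inside the configured stability
#' blocks, where the designated group's loadings are partially
#' regenerated for the second half — lowering test-retest reliability of
#' those edges without changing their expected connectivity. Covariates
#' perturb the subject loadings along fixed directions, shifting edge
#' values approximately linearly in the (standardized) covariate.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `ts` (list of
#'   [parcellated_ts()]), `atlas` (an [atlas_table()]), `covariates`
#'   (data.frame), `ground_truth` (list: `true_differential_edges`,
#'   `subject_signatures`, `patient_subnetwork_score`,
#'   `covariate_betas`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  q <- config$n_regions
  a <- config$group_share
  b <- config$fingerprint_share
  cvar <- 1 - a - b
  kg <- config$n_factors_group
  ks <- config$n_factors_subject
  t_total <- config$n_timepoints
  t1 <- t_total %/% 2L
  t2 <- t_total - t1

  network <- rep(NETWORK_LABELS, times = config$network_sizes)
  region_ids <- sprintf("R%03d", seq_len(q))
  atlas <- atlas_table(region_id = region_ids,
                       region_name = sprintf("%s_%s", network, region_ids),
                       network = network)

  idx <- edge_index(q)
  block_edges <- function(net_i, net_j) {
    in_i <- network[idx$i] == net_i & network[idx$j] == net_j
    in_j <- network[idx$i] == net_j & network[idx$j] == net_i
    in_i | in_j
  }
  true_diff <- list(
    control_gt_patient = rep(FALSE, nrow(idx)),
    patient_gt_control = rep(FALSE, nrow(idx))
  )
  # every edge incident to a remixed region loses stability, so the full
  # attenuated subnetwork is the incident edge set, a superset of the
  # block-internal true_differential_edges
  affected <- true_diff
  for (blk in config$stability_diff_blocks) {
    true_diff[[blk$direction]] <-
      true_diff[[blk$direction]] | block_edges(blk$network_i, blk$network_j)
    in_set <- network %in% c(blk$network_i, blk$network_j)
    affected[[blk$direction]] <- affected[[blk$direction]] |
      in_set[idx$i] | in_set[idx$j]
  }

  out <- with_seed(config$seed, {
    # group-common loadings, one matrix per group
    group_load <- list(
      control = normalize_rows(matrix(stats::rnorm(q * kg), q, kg)),
      patient = normalize_rows(matrix(stats::rnorm(q * kg), q, kg))
    )
    # fixed covariate perturbation directions on the subject loadings
    cov_names <- names(config$covariate_effects)
    cov_load <- lapply(cov_names, function(cn) {
      normalize_rows(matrix(stats::rnorm(q * ks), q, ks))
    })
    names(cov_load) <- cov_names

    groups <- rep(c("control", "patient"), each = config$n_per_group)
    ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "P"),
                   rep(seq_len(config$n_per_group), 2))

    covariates <- data.frame(
      subject_id = ids,
      group = groups,
      age = round(ifelse(groups == "patient",
                         stats::rnorm(length(ids), 68.5, 5.9),
                         stats::rnorm(length(ids), 64.0, 10.5)), 1),
      sex = stats::rbinom(length(ids), 1,
                          ifelse(groups == "patient", 0.348, 0.304)),
      education = round(pmax(8, stats::rnorm(length(ids), 16, 2.5)), 1)
    )
    dur <- round(pmax(1, stats::rnorm(length(ids), 7, 3.5)), 1)
    covariates$disease_duration <- ifelse(groups == "patient", dur, 0)
    # onset reported in whole years, so it is close to (but not an exact
    # linear function of) age minus duration
    covariates$onset_age <- ifelse(groups == "patient",
                                   pmax(30, round(covariates$age - dur)), 0)

    cov_std <- lapply(cov_names, function(cn) {
      v <- covariates[[cn]]
      if (stats::sd(v) == 0) rep(0, length(v)) else as.numeric(scale(v))
    })
    names(cov_std) <- cov_names

    ts_list <- vector("list", length(ids))
    signatures <- vector("list", length(ids))
    scores <- rep(NA_real_, length(ids))
    names(scores) <- ids

    for (s in seq_along(ids)) {
      grp <- groups[s]
      lg <- group_load[[grp]]
      # subject-unique loadings, perturbed along covariate directions
      bs <- matrix(stats::rnorm(q * ks), q, ks)
      for (cn in cov_names) {
        bs <- bs + sqrt(ks) * config$covariate_effects[[cn]] *
          cov_std[[cn]][s] * cov_load[[cn]]
      }
      bs1 <- normalize_rows(bs)
      # second-half loadings: remix rows of the affected networks
      bs2 <- bs1
      for (blk in config$stability_diff_blocks) {
        attenuated <- if (blk$direction == "control_gt_patient") "patient" else "control"
        if (grp != attenuated || blk$magnitude == 0) next
        rows <- network %in% c(blk$network_i, blk$network_j)
        fresh <- normalize_rows(matrix(stats::rnorm(sum(rows) * ks), sum(rows), ks))
        bs2[rows, ] <- sqrt(1 - blk$magnitude) * bs2[rows, , drop = FALSE] +
          sqrt(blk$magnitude) * fresh
      }
      bs2 <- normalize_rows(bs2)

      make_half <- function(t_len, bs_h) {
        zg <- matrix(stats::rnorm(t_len * kg), t_len, kg)
        zs <- matrix(stats::rnorm(t_len * ks), t_len, ks)
        eps <- matrix(stats::rnorm(t_len * q), t_len, q)
        sqrt(a) * zg %*% t(lg) + sqrt(b) * zs %*% t(bs_h) +
          sqrt(cvar) * config$noise_sd * eps
      }
      x <- rbind(make_half(t1, bs1), make_half(t2, bs2))
      ts_list[[s]] <- parcellated_ts(ids[s], grp, x, region_ids)
      signatures[[s]] <- bs1

      # realized connectivity on the planted predictive subnetwork: the
      # outcome mechanism acts on the subject's actual connectome, so the
      # signal is recoverable from measured FC downstream
      if (grp == "patient" && any(affected$control_gt_patient)) {
        cvec <- stats::cor(x)[upper_tri_rowmajor(q)]
        scores[s] <- mean(abs(cvec[affected$control_gt_patient]))
      }
    }
    names(signatures) <- ids
    list(ts = ts_list, covariates = covariates,
         signatures = signatures, scores = scores,
         cov_load = cov_load)
  })

  structure(
    list(ts = out$ts,
         atlas = atlas,
         covariates = out$covariates,
         ground_truth = list(
           true_differential_edges = true_diff,
           affected_edges = affected,
           subject_signatures = out$signatures,
           patient_subnetwork_score =
             out$scores[config$n_per_group + seq_len(config$n_per_group)],
           covariate_betas = list(effects = config$covariate_effects,
                                  loadings = out$cov_load)),
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d + %d subjects, %d regions, %d time points\n",
              x$config$n_per_group, x$config$n_per_group,
              x$config$n_regions, x$config$n_timepoints))
  invisible(x)
}

#' Generate clinical outcomes coupled to planted subnetwork connectivity
#'
#' Draws baseline motor scores (UPDRS-III) for the patient group from a
#' plausible clinical range and constructs follow-up scores so that the
#' probability of a clinically meaningful (>= 15%) relative reduction
#' increases with the patient's planted-subnetwork connectivity when
#' `outcome_coupling > 0`, and is independent of it when the coupling is
#' 0. The realized responder count equals
#' `round(responder_fraction * n)` by construction.
#'
#' @param cohort a `synthetic_cohort` (its ground truth supplies one
#'   subnetwork score per patient).
#' @param config the matching [cohort_config()].
#' @return a clinical data.frame from [label_responders()] with columns
#'   `subject_id`, `updrs_bl`, `updrs_fu`, `delta_percent`, `responder`.
#' @export
generate_clinical_outcomes <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  scores <- cohort$ground_truth$patient_subnetwork_score
  if (is.null(scores) || anyNA(scores)) {
    stop_brainfp("cohort ground truth lacks a subnetwork score per patient")
  }
  n <- length(scores)
  n_resp <- round(config$responder_fraction * n)
  n_resp <- max(1L, min(n - 1L, n_resp))
  with_seed(derive_seed(config$seed, 7701L), {
    z <- if (stats::sd(scores) > 0) as.numeric(scale(scores)) else rep(0, n)
    latent <- config$outcome_coupling * z + stats::rnorm(n)
    responder <- rank(-latent, ties.method = "first") <= n_resp
    bl <- pmin(70, pmax(15, round(stats::rnorm(n, 37.8, 11.7))))
    delta_target <- ifelse(responder, stats::runif(n, 20, 45),
                           stats::runif(n, -10, 10))
    fu <- pmax(0, round(bl * (1 - delta_target / 100)))
    label_responders(data.frame(subject_id = names(scores),
                                updrs_bl = bl, updrs_fu = fu))
  })
}

#' Write a cohort to delimited fixture files
#'
#' Writes one tab-separated time-series file per subject (rows = time
#' points, header = region ids), the atlas and covariate/clinical tables,
#' and a JSON manifest holding the generating configuration and file
#' list. The written values round-trip losslessly through
#' [load_fixture_set()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param clinical clinical table for the patient group (from
#'   [generate_clinical_outcomes()] or [label_responders()]).
#' @return the manifest, invisibly.
#' @export
write_fixture_set <- function(cohort, dir, clinical) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_brainfp("cannot create directory %s", dir)
  }
  write_num_table <- function(df, path, sep) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  ts_files <- vapply(cohort$ts, function(ts) {
    f <- sprintf("ts_%s.tsv", ts$subject_id)
    write_num_table(as.data.frame(ts$data), file.path(dir, f), "\t")
    f
  }, character(1))
  utils::write.table(cohort$atlas, file.path(dir, "atlas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_num_table(cohort$covariates, file.path(dir, "covariates.csv"), ",")
  write_num_table(clinical, file.path(dir, "clinical.csv"), ",")
  manifest <- list(
    seed = cohort$config$seed,
    config = cohort$config[setdiff(names(cohort$config),
                                   "stability_diff_blocks")],
    stability_diff_blocks = cohort$config$stability_diff_blocks,
    subjects = data.frame(
      subject_id = vapply(cohort$ts, `[[`, character(1), "subject_id"),
      group = vapply(cohort$ts, `[[`, character(1), "group"),
      file = ts_files),
    tables = c("atlas.tsv", "covariates.csv", "clinical.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a fixture set written by [write_fixture_set()]
#'
#' @param dir directory containing the manifest and data files.
#' @return list with `ts`, `atlas`, `covariates`, `clinical`, `manifest`.
#' @export
load_fixture_set <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_brainfp("no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  subj <- manifest$subjects
  ts <- lapply(seq_len(nrow(subj)), function(k) {
    m <- as.matrix(utils::read.table(file.path(dir, subj$file[k]),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
    parcellated_ts(subj$subject_id[k], subj$group[k], m, colnames(m))
  })
  atlas_df <- utils::read.table(file.path(dir, "atlas.tsv"), header = TRUE,
                                sep = "\t", colClasses = "character")
  list(
    ts = ts,
    atlas = atlas_table(atlas_df$region_id, atlas_df$region_name,
                        atlas_df$network),
    covariates = utils::read.csv(file.path(dir, "covariates.csv")),
    clinical = utils::read.csv(file.path(dir, "clinical.csv")),
    manifest = manifest
  )
}
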