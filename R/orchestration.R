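#' Study configuration
#'
#' Bundles the generator, lesion-mapping and elastic-net configurations with
#' the set of modalities and targets to run. A global `seed` fans out to
#' per-stage seeds through a fixed counter scheme, giving stage-level
#' reproducibility without cross-stage coupling.
#'
#' @param sim A [sim_config()].
#' @param vbcm A [vbcm_config()].
#' @param enet An [enet_config()].
#' @param modalities Subset of `c("T1", "FC", "SC", "FCSC")`, non-empty.
#' @param targets Factor indices to model; `NULL` means every retained
#'   factor.
#' @param bandpass Detrend/bandpass the time series before FC estimation.
#' @param run_residual_models Fit connectivity models on the lesion-model
#'   residuals.
#' @param run_network_summaries Produce weight maps / nodal degrees for the
#'   connectivity models.
#' @param run_seed_networks Run the healthy-control seed-network stage for
#'   the first target.
#' @param seed_network_sims Monte-Carlo simulations for the cluster-extent
#'   threshold in the seed-network stage.
#' @param seed Optional global seed overriding the sub-config seeds.
#' @return A list of class `study_config`.
#' @export
study_config <- function(sim = sim_config(),
                         vbcm = vbcm_config(n_permutations = 99),
                         enet = enet_config(n_permutations = 99),
                         modalities = c("T1", "FC", "SC", "FCSC"),
                         targets = NULL,
                         bandpass = TRUE,
                         run_residual_models = TRUE,
                         run_network_summaries = TRUE,
                         run_seed_networks = FALSE,
                         seed_network_sims = 500,
                         seed = NULL) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (!length(modalities)) stop("modality list must be non-empty", call. = FALSE)
  if (!is.null(seed)) {
    sim$seed <- stage_seed(seed, 11L)
    vbcm$seed <- stage_seed(seed, 12L)
    enet$seed <- stage_seed(seed, 13L)
  }
  structure(list(sim = sim, vbcm = vbcm, enet = enet,
                 modalities = modalities, targets = targets,
                 bandpass = bandpass,
                 run_residual_models = run_residual_models,
                 run_network_summaries = run_network_summaries,
                 run_seed_networks = run_seed_networks,
                 seed_network_sims = seed_network_sims,
                 seed = seed),
            class = "study_config")
}

run_cell <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(failed = TRUE, reason = conditionMessage(e)),
              class = "failed_cell")
  })
}

cell_summary <- function(cell) {
  if (inherits(cell, "failed_cell")) {
    return(list(failed = TRUE, reason = cell$reason))
  }
  if (inherits(cell, "prediction_result")) {
    out <- list(accuracy_r = cell$accuracy_r, perm_p = cell$perm_p,
                n = length(cell$actual))
    if (!is.null(cell$mean_alpha)) out$mean_alpha <- cell$mean_alpha
    return(out)
  }
  cell
}

#' Run the full study design end to end
#'
#' Simulates a cohort, derives behavioural factor scores, fits the lesion
#' model per target, builds the connectivity feature matrices, fits the
#' elastic-net models (per target x modality, with permutation significance),
#' compares squared errors against the lesion model, fits connectivity models
#' on the lesion residuals, summarizes networks, and (optionally) runs the
#' healthy-control seed-network overlap stage. Stage failures are recorded
#' per cell; independent cells continue.
#'
#' @param config A [study_config()].
#' @return A `study_report`: nested list with `targets` (per target:
#'   `models`, `comparisons`, `residual_models`, `networks`), `seed_network`,
#'   `summary_table` (data frame of accuracies), `n_connectivity_models` and
#'   `provenance`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cohort <- simulate_cohort(config$sim)
  scaled <- normalize_battery(cohort$battery)
  fm <- fit_varimax_pca(scaled)
  scores <- project_factor_scores(fm, scaled)
  targets <- config$targets
  if (is.null(targets)) targets <- seq_len(fm$n_retained)
  targets <- intersect(targets, seq_len(fm$n_retained))

  conn_mods <- setdiff(config$modalities, "T1")
  features <- lapply(stats::setNames(conn_mods, conn_mods), function(m) {
    run_cell(cohort_features(cohort, m, bandpass = config$bandpass))
  })
  abn_images <- lapply(cohort$lesions, `[[`, "abnormality")

  n_conn_models <- 0L
  target_reports <- list()
  for (t in targets) {
    y <- scores[, t]
    models <- list()
    if ("T1" %in% config$modalities) {
      models$T1 <- run_cell(loocv_lesion_model(abn_images, y, config$vbcm))
    }
    for (m in conn_mods) {
      models[[m]] <- run_cell({
        if (inherits(features[[m]], "failed_cell")) stop("feature stage failed")
        enet_permutation_test(features[[m]], y, config$enet)
      })
      if (!inherits(models[[m]], "failed_cell")) {
        n_conn_models <- n_conn_models + 1L
      }
    }
    comparisons <- list()
    residual_models <- list()
    if (!is.null(models$T1) && !inherits(models$T1, "failed_cell")) {
      for (m in conn_mods) {
        if (inherits(models[[m]], "failed_cell")) next
        comparisons[[paste0("T1_vs_", m)]] <-
          run_cell(compare_squared_errors(models$T1, models[[m]]))
      }
      if (config$run_residual_models) {
        resid <- run_cell(residual_targets(models$T1))
        if (!inherits(resid, "failed_cell")) {
          for (m in conn_mods) {
            residual_models[[m]] <- run_cell({
              if (inherits(features[[m]], "failed_cell")) stop("feature stage failed")
              enet_permutation_test(features[[m]], resid, config$enet)
            })
          }
        }
      }
    }
    networks <- list()
    if (config$run_network_summaries) {
      for (m in conn_mods) {
        if (inherits(models[[m]], "failed_cell")) next
        networks[[m]] <- run_cell({
          pm <- attr(features[[m]], "pair_map")
          K <- cohort$config$n_rois
          if (m == "FCSC") {
            # concatenated features: summarize the FC block over its pair map
            wm <- average_weights_z(lapply(models[[m]]$fold_artifacts,
                                           function(f) f$weights[seq_len(nrow(pm))]))
          } else {
            wm <- average_weights_z(models[[m]]$fold_artifacts)
          }
          suppressWarnings({
            deg <- nodal_degree(wm, pm)
            list(weight_map = wm, degrees = deg,
                 top_nodes = top_nodes(deg, k = min(10L, K)))
          })
        })
      }
    }
    target_reports[[paste0("factor_", t)]] <-
      list(models = models, comparisons = comparisons,
           residual_models = residual_models, networks = networks)
  }

  seed_network <- NULL
  if (config$run_seed_networks && length(targets) &&
      "T1" %in% config$modalities) {
    seed_network <- run_cell(
      run_seed_network_stage(cohort, target_reports[[1]], config))
  }

  rows <- list()
  for (tn in names(target_reports)) {
    for (mn in names(target_reports[[tn]]$models)) {
      s <- cell_summary(target_reports[[tn]]$models[[mn]])
      rows[[length(rows) + 1L]] <- data.frame(
        target = tn, modality = mn,
        accuracy_r = if (is.null(s$accuracy_r)) NA_real_ else s$accuracy_r,
        perm_p = if (is.null(s$perm_p)) NA_real_ else s$perm_p,
        mean_alpha = if (is.null(s$mean_alpha)) NA_real_ else s$mean_alpha,
        n = if (is.null(s$n)) NA_integer_ else s$n,
        failed = isTRUE(s$failed))
    }
  }
  structure(list(targets = target_reports,
                 factor_model = fm,
                 factor_scores = scores,
                 seed_network = seed_network,
                 summary_table = do.call(rbind, rows),
                 n_connectivity_models = n_conn_models,
                 provenance = list(
                   seed = config$seed,
                   sim_seed = config$sim$seed,
                   modalities = config$modalities,
                   n_patients = config$sim$n_patients,
                   package_version = as.character(utils::packageVersion("lesionconn")))),
            class = "study_report")
}

# Healthy-control seed-network stage for the first reported target: seed =
# high-stability lesion cluster; network = cluster-corrected group t-map of
# control seed maps; overlap scored for the FC model's top nodes.
run_seed_network_stage <- function(cohort, target_report, config) {
  t1 <- target_report$models$T1
  if (is.null(t1) || inherits(t1, "failed_cell")) stop("no lesion model available")
  smap <- stability_map(t1$fold_artifacts)
  n <- length(t1$actual)
  seed <- volume3d(vol_data(smap) >= 0.8 * n, vol_voxel_mm(smap))
  if (!any(vol_data(seed))) stop("no stable lesion cluster to seed from")
  zmaps <- lapply(seq_len(cohort$config$n_controls), function(i) {
    v4 <- simulate_control_volume(cohort$config, cohort$atlas, cohort$truth, i)
    seed_fc_map(seed, v4)
  })
  mc <- montecarlo_cluster_threshold(cohort$config$grid_shape,
                                     smoothness_fwhm = 2,
                                     voxel_p = 0.001, cluster_p = 0.05,
                                     n_sims = config$seed_network_sims,
                                     seed = stage_seed(cohort$config$seed, 55L))
  net <- group_network(zmaps, voxel_p = 0.001,
                       cluster_size_thr = mc$cluster_size_thr)
  overlap <- NULL
  fc_net <- target_report$networks$FC
  if (!is.null(fc_net) && !inherits(fc_net, "failed_cell")) {
    overlap <- node_overlap(fc_net$top_nodes, cohort$atlas, net$mask_positive)
  }
  list(seed = seed, network = net, cluster_size_thr = mc$cluster_size_thr,
       overlap = overlap)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$summary_table, row.names = FALSE)
  cat(sprintf("connectivity models: %d\n", x$n_connectivity_models))
  invisible(x)
}

#' Write a study report to disk
#'
#' JSON summary (accuracies, comparisons, residual models, overlaps) plus a
#' TSV twin of the summary table.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$summary_table, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(summary = report$summary_table,
             n_connectivity_models = report$n_connectivity_models,
             provenance = report$provenance)
  for (tn in names(report$targets)) {
    tr <- report$targets[[tn]]
    js[[tn]] <- list(
      comparisons = lapply(tr$comparisons, function(cc) {
        if (inherits(cc, "failed_cell")) {
          list(failed = TRUE, reason = cc$reason)
        } else {
          list(z = cc$wilcoxon_z, p = cc$wilcoxon_p, n = cc$n_pairs,
               median_sq_error = as.list(cc$median_sq_error))
        }
      }),
      residual_models = lapply(tr$residual_models, cell_summary))
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
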