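#' Assemble a pipeline configuration
#'
#' Defaults mirror the analysis protocol: k = 4 states (or `"auto"` for
#' the explained-variance elbow over k = 2..14 at a 1% gain threshold),
#' 10 k-means replicates, 10 stability runs compared by AMI, control
#' horizon T = 1.501, 1000 trapezoid steps, 1.5 x IQR outlier fences and
#' FDR at q = 0.05.
#'
#' @param out_dir output directory.
#' @param manifest,connectome,parcellation input paths (all `NULL` to
#'   simulate instead).
#' @param n_subjects,n_frames,noise_sd,group_effect simulation settings
#'   used when no manifest is given.
#' @param k number of states or `"auto"`.
#' @param k_range,gain_threshold elbow settings for `k = "auto"`.
#' @param n_replicates,stability_runs clustering settings.
#' @param t_horizon control horizon; `NULL` runs the horizon sweep.
#' @param t_grid horizon sweep grid (used when `t_horizon` is `NULL`).
#' @param n_steps trapezoid intervals per transition.
#' @param iqr_factor outlier fence multiplier.
#' @param fdr_q FDR level.
#' @param seed master seed (mandatory; every stochastic stage derives its
#'   own sub-seed from it).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            manifest = NULL, connectome = NULL,
                            parcellation = NULL,
                            n_subjects = 100L, n_frames = 200L,
                            noise_sd = 0.5, group_effect = list(),
                            k = 4L, k_range = 2:14, gain_threshold = 0.01,
                            n_replicates = 10L, stability_runs = 10L,
                            t_horizon = 1.501, t_grid = NULL,
                            n_steps = 1000L, iqr_factor = 1.5,
                            fdr_q = 0.05, seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate-or-read -> extract states -> (optional) select horizon ->
#' compute TE -> aggregate -> exclude outliers -> group statistics. Every
#' stage writes its outputs under `config$out_dir` and the run closes with
#' a JSON run manifest (config snapshot, per-output checksums, wall-clock
#' per stage, warnings).
#'
#' @param config a [pipeline_config()].
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  timings <- list()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  # --- inputs: simulate or read -------------------------------------------
  inputs <- stage("inputs", {
    if (is.null(config$manifest)) {
      parc <- default_parcellation()
      sc <- generate_connectome(nrow(parc), n_modules = 5L, density = 0.3,
                                seed = derive_seed(config$seed, "sc"))
      cent <- generate_state_centroids(parc, k = 4L, amplitude = 1,
                                       seed = config$seed)
      truth <- synthetic_truth(cent, noise_sd = config$noise_sd,
                               group_effect = config$group_effect,
                               seed = config$seed)
      cohort <- generate_cohort(config$n_subjects, truth, parc,
                                n_frames = config$n_frames,
                                seed = config$seed)
      write_cohort(cohort, sc, parc, config$out_dir)
      list(series = cohort$series, covariates = cohort$covariates,
           sc = sc, parc = parc)
    } else {
      parc <- read_parcellation(config$parcellation)
      sc <- read_matrix_tsv(config$connectome)
      man <- read_manifest(config$manifest, parc)
      list(series = man$series, covariates = man$covariates,
           sc = sc, parc = parc)
    }
  })

  # --- state extraction ----------------------------------------------------
  states <- stage("extract_states", {
    st <- extract_brain_states(inputs$series, inputs$parc, k = config$k,
                               k_range = config$k_range,
                               gain_threshold = config$gain_threshold,
                               n_replicates = config$n_replicates,
                               stability_runs = config$stability_runs,
                               seed = derive_seed(config$seed, "states"))
    gc <- st$group_centroids
    rownames(gc) <- st$labels
    write_matrix_tsv(gc, file.path(config$out_dir, "group_centroids.tsv"))
    write_matrix_tsv(st$ami_matrix,
                     file.path(config$out_dir, "ami_matrix.tsv"))
    if (!is.null(st$explained_variance_by_k))
      write_tsv(data.frame(k = as.integer(names(st$explained_variance_by_k)),
                           explained_variance = st$explained_variance_by_k),
                file.path(config$out_dir, "explained_variance_by_k.tsv"))
    lab <- data.frame(
      subject_id = rep(names(st$frame_labels),
                       times = lengths(st$frame_labels)),
      frame = unlist(lapply(st$frame_labels, seq_along)),
      state = unlist(st$frame_labels))
    write_tsv(lab, file.path(config$out_dir, "frame_labels.tsv"))
    st
  })

  # --- horizon -------------------------------------------------------------
  t_horizon <- stage("select_horizon", {
    if (is.null(config$t_horizon)) {
      sel <- select_time_horizon(inputs$sc, states$group_centroids,
                                 states$frame_labels,
                                 t_grid = config$t_grid)
      write_tsv(sel$sweep, file.path(config$out_dir, "horizon_sweep.tsv"))
      sel$T_star
    } else config$t_horizon
  })

  # --- transition energies -------------------------------------------------
  te <- stage("compute_te", {
    A <- stabilize_system(inputs$sc)
    sys <- stabilized_system(A, T_horizon = t_horizon)
    W <- controllability_gramian(sys)
    te_path <- file.path(config$out_dir, "te_regional.tsv")
    if (file.exists(te_path)) file.remove(te_path)
    tensors <- vector("list", length(inputs$series))
    for (i in seq_along(inputs$series)) {
      sid <- inputs$series[[i]]$subject_id
      tensors[[i]] <- pairwise_te(sys, W,
                                  states$subject_centroids[[i]]$centroids,
                                  n_steps = config$n_steps)
      write_te_tensor(tensors[[i]], sid, te_path, append = (i > 1L))
    }
    names(tensors) <- vapply(inputs$series, `[[`, character(1),
                             "subject_id")
    tensors
  })

  # --- aggregation + outliers ---------------------------------------------
  agg <- stage("aggregate", {
    ag <- lapply(te, aggregate_te, parc = inputs$parc)
    nets <- NETWORK_NAMES
    wide <- data.frame(subject_id = names(ag),
                       mean_global = vapply(ag, `[[`, numeric(1),
                                            "mean_global"))
    for (nw in nets)
      wide[[paste0("mean_", nw)]] <- vapply(ag, function(a)
        a$mean_network[[nw]], numeric(1))
    reg <- t(vapply(ag, `[[`, numeric(length(inputs$parc$region_name)),
                    "mean_regional"))
    colnames(reg) <- paste0("mean_", inputs$parc$region_name)
    wide <- cbind(wide, as.data.frame(reg))
    write_tsv(wide, file.path(config$out_dir, "te_aggregated.tsv"))
    wide
  })

  outliers <- stage("exclude_outliers", {
    v <- stats::setNames(agg$mean_global, agg$subject_id)
    rep <- exclude_outliers(v, factor = config$iqr_factor)
    write_tsv(data.frame(subject_id = rep$excluded_subject_ids),
              file.path(config$out_dir, "outliers.tsv"))
    rep
  })

  # --- statistics ----------------------------------------------------------
  stats_res <- stage("stats", {
    keep <- agg$subject_id %in% outliers$kept_subject_ids
    d <- merge(inputs$covariates, agg[keep, , drop = FALSE],
               by = "subject_id")
    outcomes <- c("mean_global", paste0("mean_", NETWORK_NAMES))
    families <- c("global", rep("network", length(NETWORK_NAMES)))
    anc <- do.call(rbind, lapply(seq_along(outcomes), function(i) {
      a <- fit_ancova(d, outcomes[i])
      a$outcome <- outcomes[i]
      a$family <- families[i]
      a
    }))
    # FDR within each term x family grouping
    anc$p_fdr <- NA_real_
    for (tm in unique(anc$term)) {
      i <- anc$term == tm
      anc$p_fdr[i] <- bh_fdr(anc$p[i], q = config$fdr_q,
                             family = anc$family[i])$p_fdr
    }
    write_tsv(anc, file.path(config$out_dir, "ancova_results.tsv"))
    ph <- do.call(rbind, lapply(outcomes, function(o) {
      r <- posthoc_within_sex(d, o); r$outcome <- o; r
    }))
    write_tsv(ph, file.path(config$out_dir, "posthoc.tsv"))
    sp <- do.call(rbind, lapply(outcomes, function(o) {
      r <- spearman_fhd(d, o); r$outcome <- o; r
    }))
    write_tsv(sp, file.path(config$out_dir, "spearman.tsv"))
    list(ancova = anc, posthoc = ph, spearman = sp)
  })

  # --- run manifest --------------------------------------------------------
  outputs <- list.files(config$out_dir, recursive = TRUE,
                        full.names = TRUE)
  outputs <- outputs[basename(outputs) != "run_manifest.json"]
  manifest <- list(
    tool = paste0("stateTE ",
                  as.character(utils::packageVersion("stateTE"))),
    config = config[setdiff(names(config), "group_effect")],
    t_horizon = t_horizon,
    k_star = states$k,
    n_outliers_excluded = outliers$n_excluded,
    checksums = as.list(tools::md5sum(sort(outputs))),
    seconds_per_stage = timings,
    warnings = warnings_log)
  path <- file.path(config$out_dir, "run_manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  file.rename(tmp, path)     # atomic write at run end
  invisible(manifest)
}
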