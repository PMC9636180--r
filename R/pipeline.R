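#' Pipeline configuration
#'
#' Bundles every stage's configuration plus the mandatory master seed.
#' Per-stage and per-iteration seeds are derived deterministically from the
#' master seed, so any stage can be re-run in isolation and full runs are
#' bit-reproducible. Accepts a YAML file with the same nested structure.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param seed Master seed (mandatory).
#' @param cohort A [cohort_config()]; defaults to one seeded from `seed`.
#' @param n_event_participants,n_cells Number of participants to simulate
#'   single-cell events for, and cells per sample.
#' @param subsample_n Live-cell subsample size per sample.
#' @param event_batch_sd Per-channel batch shift sd on the transformed scale.
#' @param align_channels Channels to landmark-align across samples.
#' @param som_grid,n_meta SOM grid and metacluster count.
#' @param test A [test_spec()].
#' @param strategy A [simulation_strategy()].
#' @param ensemble An [ensemble_config()]; its seed is overridden by a
#'   derived stage seed.
#' @param gate A [correlation_gate()].
#' @param paths Optional named list of input files (`serology_csv`,
#'   `feature_csv`) replacing the corresponding simulated tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("cytoscreen_run_"), seed = 1,
                            cohort = NULL,
                            n_event_participants = 4, n_cells = 3000,
                            subsample_n = 2000, event_batch_sd = 0.1,
                            align_channels = "CD8",
                            som_grid = c(8, 8), n_meta = 12,
                            test = test_spec(),
                            strategy = simulation_strategy(),
                            ensemble = ensemble_config(iterations = 50),
                            gate = correlation_gate(),
                            paths = list()) {
  assert_count(seed, "seed", 0L)
  cohort <- cohort %||% cohort_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 n_event_participants = n_event_participants,
                 n_cells = n_cells, subsample_n = subsample_n,
                 event_batch_sd = event_batch_sd,
                 align_channels = align_channels, som_grid = som_grid,
                 n_meta = n_meta, test = test, strategy = strategy,
                 ensemble = ensemble, gate = gate, paths = paths),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; top-level keys mirror [pipeline_config()]
#'   arguments, with `cohort`, `ensemble`, `strategy`, `test`, `gate` given
#'   as nested maps of the respective constructor arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$seed)) stop("pipeline config must set `seed`", call. = FALSE)
  args <- doc
  for (nm in c("cohort", "ensemble", "strategy", "test", "gate")) {
    if (!is.null(doc[[nm]])) {
      ctor <- switch(nm, cohort = cohort_config, ensemble = ensemble_config,
                     strategy = simulation_strategy, test = test_spec,
                     gate = correlation_gate)
      args[[nm]] <- do.call(ctor, doc[[nm]])
    }
  }
  if (is.null(args$cohort)) args$cohort <- cohort_config(seed = doc$seed)
  do.call(pipeline_config, args)
}

pipeline_stages <- c("simulate", "preprocess", "gate", "cluster", "test",
                     "stability", "correlate")

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in order (simulate, preprocess, gate,
#' cluster, test, stability, correlate), writing every stage's outputs as
#' CSV/JSON under `config$out_dir` plus a manifest (parameters, derived
#' seeds, per-stage status, md5 of every output) sufficient to reproduce the
#' run bit-identically. A stage failure is recorded in the manifest and all
#' downstream stages are skipped.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param stages Stages to run (defaults to all, in canonical order).
#' @return The manifest list, invisibly; it is also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  for (p in config$paths) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input file does not exist: ", p, call. = FALSE)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- setNames(derive_seeds(config$seed, length(pipeline_stages), "pipeline"),
                    pipeline_stages)
  manifest <- list(package = "cytoscreen",
                   version = as.character(utils::packageVersion("cytoscreen")),
                   master_seed = config$seed, stage_seeds = as.list(seeds),
                   stages = list(), outputs = list())
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  save_csv <- function(x, name) {
    f <- file.path(config$out_dir, name)
    readr::write_csv(x, f, progress = FALSE)
    manifest$outputs[[name]] <<- unname(tools::md5sum(f))
  }
  save_json <- function(x, name) {
    f <- file.path(config$out_dir, name)
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$outputs[[name]] <<- unname(tools::md5sum(f))
  }

  runners <- list(
    simulate = function() {
      state$cohort <- generate_cohort(config$cohort)
      state$truth <- cohort_truth(state$cohort)
      state$features <- generate_feature_table(state$cohort, config$cohort)
      state$serology <- if (!is.null(config$paths$serology_csv)) {
        readr::read_csv(config$paths$serology_csv, show_col_types = FALSE)
      } else {
        generate_serology(state$cohort, state$features)
      }
      save_csv(state$cohort, "cohort.csv")
      save_csv(state$features, "feature_table.csv")
      save_csv(state$serology, "serology.csv")
      save_csv(state$truth$informative_features, "truth_informative_features.csv")
      save_csv(state$truth$serology_links, "truth_serology_links.csv")
    },
    preprocess = function() {
      panel <- default_panel()
      base <- dplyr::filter(state$cohort,
                            .data$timepoint == state$cohort$timepoint[1])
      base <- head(base, config$n_event_participants)
      props <- state$truth$population_proportions
      ev_seeds <- derive_seeds(seeds[["preprocess"]], nrow(base), "events")
      samples <- purrr::map(seq_len(nrow(base)), function(i) {
        pr <- dplyr::filter(props, .data$participant_id == base$participant_id[i])
        ev <- generate_events(base[i, ], panel,
                              setNames(pr$proportion, pr$population),
                              n_cells = config$n_cells, seed = ev_seeds[i],
                              batch_sd = config$event_batch_sd)
        arcsinh_transform(ev, transform_spec())
      })
      names(samples) <- base$participant_id
      warp_audit <- list()
      for (ch in config$align_channels) {
        al <- landmark_align(samples, ch)
        samples <- al$samples
        warp_audit[[ch]] <- lapply(al$warps, function(w) {
          list(src = w$src, tgt = w$tgt)
        })
      }
      sub_seeds <- derive_seeds(seeds[["preprocess"]], length(samples), "subsample")
      samples <- purrr::imap(samples, function(s, id) {
        subsample_live(s, n = config$subsample_n,
                       seed = sub_seeds[match(id, names(samples))])
      })
      state$samples <- samples
      save_json(warp_audit, "warp_functions.json")
      save_csv(dplyr::bind_rows(samples), "events_aligned.csv")
    },
    gate = function() {
      panel <- default_panel()
      gated <- extract_gated_features(
        state$samples, default_gating_tree(), default_thresholds(),
        functional_markers = panel_markers(panel, "functional"))
      state$gated <- gated
      save_csv(gated, "gated_features.csv")
    },
    cluster = function() {
      panel <- default_panel()
      lineage <- setdiff(panel_markers(panel, "lineage"),
                         transform_spec()$excluded_markers)
      pooled <- dplyr::bind_rows(lapply(state$samples, function(s) s[lineage]))
      model <- train_som(pooled, grid = config$som_grid,
                         seed = seeds[["cluster"]])
      meta <- metacluster(model, n_meta = config$n_meta)
      prof <- assign_and_profile(state$samples, model, meta)
      state$clusters <- prof
      save_csv(prof$frequencies, "cluster_frequencies.csv")
      save_csv(prof$profiles, "cluster_profiles.csv")
    },
    test = function() {
      baseline <- dplyr::filter(state$features,
                                .data$timepoint == state$features$timepoint[1])
      res <- differential_analysis(baseline, config$test)
      state$diff <- res
      save_csv(res, "diff_results.csv")
    },
    stability = function() {
      baseline <- dplyr::filter(state$features,
                                .data$timepoint == state$features$timepoint[1])
      attr(baseline, "feature_info") <- attr(state$features, "feature_info")
      cfg <- config$ensemble
      cfg$seed <- as.integer(seeds[["stability"]])
      ens <- run_ensemble(baseline, config$strategy, cfg)
      state$ensemble <- ens
      save_csv(ens$importance, "stability_importance.csv")
      save_csv(ens$performance, "stability_performance.csv")
      save_json(as.list(glance(ens)), "stability_summary.json")
    },
    correlate = function() {
      baseline <- dplyr::filter(state$features,
                                .data$timepoint == state$features$timepoint[1])
      res <- screen_serology(baseline, state$serology, config$gate)
      state$correlations <- res
      save_csv(res, "correlations.csv")
    }
  )

  for (st in pipeline_stages) {
    if (!st %in% stages) { manifest$stages[[st]] <- "not requested"; next }
    if (failed) { manifest$stages[[st]] <- "skipped"; next }
    res <- tryCatch({ runners[[st]](); "completed" },
                    error = function(e) paste("failed:", conditionMessage(e)))
    manifest$stages[[st]] <- res
    if (!identical(res, "completed")) failed <- TRUE
  }
  f <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
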