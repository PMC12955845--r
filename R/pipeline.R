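# End-to-end pipeline orchestration (synth -> ingest -> extract ->
# train -> downstream) driven by a JSON configuration.

#' Default pipeline configuration
#'
#' Every default is either a published setting (spatial k = 10,
#' clustering with 100 neighbours, per-space Leiden resolutions
#' 1.0/0.5/1.0/0.1/0.5, alpha = 0.05) or a documented package choice
#' (split fractions, epochs, minimum category size). A single top-level
#' seed fans out deterministically to per-stage seeds.
#'
#' @param out_dir artifact directory
#' @param seed top-level seed
#' @param input_dir optional directory of already-written samples (one
#'   subdirectory per sample, [write_sample()] layout); when NULL the
#'   synthetic generator runs first
#' @param synth named list of [synthetic_spec()] overrides
#' @param model named list of [model_config()] overrides
#' @param k_spatial spatial neighbour count
#' @param n_neighbours clustering kNN size
#' @param resolutions named per-space Leiden resolutions
#' @param alpha significance level for feature ranking
#' @param min_samples minimum samples per clinical category
#' @return validated config list of class `hv_pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 0L, input_dir = NULL,
                            synth = list(), model = list(),
                            k_spatial = 10L, n_neighbours = 100L,
                            resolutions = default_resolutions(),
                            alpha = 0.05, min_samples = 5L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              input_dir = input_dir, synth = synth, model = model,
              k_spatial = as.integer(k_spatial),
              n_neighbours = as.integer(n_neighbours),
              resolutions = unlist(resolutions), alpha = alpha,
              min_samples = as.integer(min_samples))
  validate_pipeline_config(cfg)
  structure(cfg, class = "hv_pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  need <- c("out_dir", "seed", "k_spatial", "n_neighbours", "resolutions",
            "alpha", "min_samples")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    hv_stop("pipeline config missing fields: %s", paste(miss, collapse = ", "))
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    hv_stop("input_dir does not exist: %s", cfg$input_dir)
  if (!all(c("integrated", "E", "NC", "M", "SC") %in% names(cfg$resolutions)))
    hv_stop("resolutions must name all five spaces")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) hv_stop("alpha must be in (0, 1)")
  invisible(cfg)
}

#' Read / write a pipeline configuration as JSON
#'
#' Configurations round-trip through serialize/deserialize unchanged.
#' @param path JSON file
#' @return an `hv_pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$resolutions <- unlist(raw$resolutions)
  cfg <- do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg an `hv_pipeline_config`
#' @export
write_pipeline_config <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$resolutions <- as.list(ser$resolutions)   # keep names in JSON
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

run_stage <- function(name, expr) {
  hv_log("stage %s ...", name)
  tryCatch(expr, error = function(e)
    hv_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes synth (unless `input_dir` is given), ingest, feature
#' extraction, VAE training, clustering over all spaces, feature
#' ranking, prevalence, clinical association, survival analysis (when
#' survival columns and events are present) and the segmentation QC,
#' writing every result table under `cfg$out_dir`. Reruns with the same
#' seeds produce identical outputs.
#'
#' @param cfg an `hv_pipeline_config` (or path to its JSON)
#' @return invisibly, a list with the main in-memory artifacts
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- cfg$input_dir
  if (is.null(data_dir)) {
    data_dir <- file.path(cfg$out_dir, "synth")
    run_stage("synth", {
      sargs <- cfg$synth
      sargs$seed <- sargs$seed %||% hv_child_seed(cfg$seed, "synth")
      gen <- do.call(synthetic_spec, sargs)
      write_synthetic(generate_synthetic(gen), data_dir)
    })
  }
  samples <- run_stage("ingest", {
    dirs <- list.dirs(data_dir, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "mask.csv"))]
    if (!length(dirs)) hv_stop("no sample directories under %s", data_dir)
    lapply(dirs, function(d)
      load_sample(file.path(d, "stack"), file.path(d, "mask.csv"),
                  file.path(d, "channels.csv"), sample_id = basename(d)))
  })
  hv_log("ingested %d sample(s)", length(samples))
  cv <- run_stage("extract", derive_cell_views(samples, k = cfg$k_spatial))
  save_cellviews(cv, file.path(cfg$out_dir, "cellviews"))
  model <- run_stage("train", {
    margs <- cfg$model
    margs$seed <- margs$seed %||% hv_child_seed(cfg$seed, "train")
    mcfg <- do.call(model_config, margs)
    train_hmivae(cv, mcfg)
  })
  save_model(model, file.path(cfg$out_dir, "model.json"))
  write_table(model$log, file.path(cfg$out_dir, "training_log.csv"))
  latent <- run_stage("embed", embed_all(model, cv))
  write_table(data.frame(cell_id = latent$cell_ids,
                         sample_id = latent$sample_ids, latent$z),
              file.path(cfg$out_dir, "latent.csv"))
  clusters <- run_stage("cluster", assign_clusters(
    latent, n_neighbours = min(cfg$n_neighbours, nrow(cv$Y) - 1L),
    resolutions = cfg$resolutions,
    seed = hv_child_seed(cfg$seed, "cluster")))
  write_table(clusters, file.path(cfg$out_dir, "clusters.csv"))
  intg <- clusters[clusters$space == "integrated", ]
  run_stage("rank", {
    rk <- rank_features(cv$Y, intg$cluster_id, alpha = cfg$alpha)
    write_table(rk$full, file.path(cfg$out_dir, "feature_ranking.csv"))
  })
  prev <- run_stage("prevalence",
                    prevalence(intg$cluster_id, intg$sample_id, cv$image_dims))
  write_table(prev, file.path(cfg$out_dir, "prevalence.csv"))
  clin_path <- file.path(data_dir, "clinical.csv")
  if (file.exists(clin_path)) {
    clinical <- load_clinical(clin_path)
    run_stage("associate", {
      al <- associate_latent(latent$z, latent$sample_ids, clinical,
                             min_samples = cfg$min_samples)
      write_table(al, file.path(cfg$out_dir, "association_latent.csv"))
      ap <- associate_proportion(prev, clinical, "proportion",
                                 min_samples = cfg$min_samples)
      write_table(ap, file.path(cfg$out_dir, "association_proportion.csv"))
      am <- associate_proportion(prev, clinical, "per_mm2",
                                 min_samples = cfg$min_samples)
      write_table(am, file.path(cfg$out_dir, "association_per_mm2.csv"))
    })
    if (all(c("survival_time", "event_indicator") %in% names(clinical)) &&
        sum(clinical$event_indicator) > 0) {
      run_stage("survival", {
        covs <- if (nrow(clinical) >= 20)
          intersect(c("stage", "grade"), names(clinical)) else character(0)
        sv <- survival_analysis(prev, clinical, "proportion", covariates = covs)
        write_table(sv, file.path(cfg$out_dir, "survival_proportion.csv"))
      })
    }
  }
  run_stage("segqc", {
    qc <- tryCatch(segmentation_qc(cv$Y), hmivae_error = function(e) NULL)
    if (!is.null(qc)) write_table(qc, file.path(cfg$out_dir, "segmentation_qc.csv"))
  })
  hv_log("pipeline complete: %s", cfg$out_dir)
  invisible(list(cellviews = cv, model = model, latent = latent,
                 clusters = clusters, prevalence = prev))
}
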