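#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the conventional
#' defaults: streamline length bounds 20-250 mm, at least 2 streamlines per
#' edge (5 for the conservative robustness setting), 50% consensus
#' prevalence, hubs at 2 and 3 SD, gamma grid 0.5-3, and one master seed
#' from which every stochastic stage derives its own.
#'
#' @param input either a [phantom_spec()] (the cohort is simulated), a
#'   [cohort()], or a directory of per-subject matrix CSVs (paired files
#'   `<id>_nos.csv` / `<id>_scalar.csv`).
#' @param out_dir output directory (created if missing).
#' @param min_streamlines edge threshold, usually 2 or 5.
#' @param length_bounds length filter in mm.
#' @param prevalence consensus prevalence fraction.
#' @param hub_sd SD multipliers reported for hub detection.
#' @param gammas resolution grid.
#' @param n_runs Louvain runs per resolution.
#' @param sampling_mode scalar sampling mode.
#' @param radius_mm endpoint assignment radius.
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir,
                            min_streamlines = 2,
                            length_bounds = c(20, 250),
                            prevalence = 0.5,
                            hub_sd = c(2, 3),
                            gammas = seq(0.5, 3, by = 0.1),
                            n_runs = 1000,
                            sampling_mode = "trilinear",
                            radius_mm = 2,
                            seed = 1L) {
  if (!min_streamlines >= 1) stop_param("min_streamlines must be >= 1")
  if (prevalence <= 0 || prevalence > 1)
    stop_param("prevalence must lie in (0, 1]")
  if (length_bounds[1] < 0 || length_bounds[1] > length_bounds[2])
    stop_param("invalid length bounds")
  structure(list(input = input, out_dir = out_dir,
                 min_streamlines = min_streamlines,
                 length_bounds = length_bounds, prevalence = prevalence,
                 hub_sd = hub_sd, gammas = gammas, n_runs = n_runs,
                 sampling_mode = sampling_mode, radius_mm = radius_mm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation, a prebuilt cohort, or
#' matrix CSVs on disk), group consensus, NOS-vs-scalar edge regression,
#' strength/weighted-average metrics with hub flags, the multi-resolution
#' modularity sweep with consensus partitions for both weightings, and the
#' rank-difference class analysis. All artifacts are written under
#' `cfg$out_dir` (matrices as CSV, structured results as JSON) together with
#' a provenance record (config echo, config hash, seed, package version).
#' Rerunning with the same config and seed reproduces the outputs
#' byte-identically.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `cohort`,
#'   `consensus`, `regression`, `metrics`, `sweep_nos`, `sweep_scalar`,
#'   `ranks`, `composition`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- acquire_cohort(cfg)
  classes <- co$classes
  if (is.null(classes)) classes <- default_class_map(length(co$nodes))

  mask <- consensus_mask(co, cfg$prevalence)
  cons <- consensus_weights(co, mask)
  write_connectome_csv(cons$nos, file.path(cfg$out_dir, "consensus_nos.csv"))
  write_connectome_csv(cons$scalar,
                       file.path(cfg$out_dir, "consensus_scalar.csv"))

  reg <- edge_regression(cons$scalar, cons$nos)

  s_nos <- nos_strength(cons$nos)
  s_avg <- suppressWarnings(weighted_average(cons$nos, cons$scalar))
  met <- data.frame(node = co$nodes,
                    nos_strength = as.numeric(s_nos),
                    weighted_average = as.numeric(s_avg))
  for (k in cfg$hub_sd)
    met[[sprintf("hub_%dsd", k)]] <- met$node %in% detect_hubs(s_nos, k)
  utils::write.csv(met, file.path(cfg$out_dir, "node_metrics.csv"),
                   row.names = FALSE)

  sw_nos <- gamma_sweep(cons$nos, cfg$gammas, cfg$n_runs,
                        seed = derive_seed(cfg$seed, 41L))
  sw_scl <- gamma_sweep(cons$scalar, cfg$gammas, cfg$n_runs,
                        seed = derive_seed(cfg$seed, 42L))
  for (nm in c("nos", "scalar")) {
    sw <- if (nm == "nos") sw_nos else sw_scl
    jsonlite::write_json(
      list(gammas = sw$gammas, mean_q = sw$mean_q,
           stability = sw$stability, n_modules = sw$n_modules,
           selected_gamma = sw$selected_gamma, selected_q = sw$selected_q),
      file.path(cfg$out_dir, sprintf("sweep_%s.json", nm)),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(
      data.frame(node = co$nodes, module = sw$consensus$assignment),
      file.path(cfg$out_dir, sprintf("partition_%s.csv", nm)),
      row.names = FALSE)
  }

  rk <- rank_comparison(cons$nos, cons$scalar, classes)
  utils::write.csv(rk$nodes, file.path(cfg$out_dir, "rank_differences.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(functional = as.list(rk$functional),
                            cyto = as.list(rk$cyto)),
                       file.path(cfg$out_dir, "class_medians.json"),
                       auto_unbox = TRUE, digits = NA)

  comp <- list(
    nos = module_class_composition(sw_nos$consensus, classes, "functional"),
    scalar = module_class_composition(sw_scl$consensus, classes,
                                      "functional"))
  utils::write.csv(as.data.frame(comp$nos),
                   file.path(cfg$out_dir, "composition_nos.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(comp$scalar),
                   file.path(cfg$out_dir, "composition_scalar.csv"),
                   row.names = FALSE)

  prov <- provenance_record(cfg, reg)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = co, consensus = cons, regression = reg,
                 metrics = met, sweep_nos = sw_nos, sweep_scalar = sw_scl,
                 ranks = rk, composition = comp))
}

acquire_cohort <- function(cfg) {
  input <- cfg$input
  if (inherits(input, "phantom_spec"))
    return(generate_cohort_matrices(input, seed = derive_seed(cfg$seed, 40L)))
  if (inherits(input, "cohort")) return(input)
  if (is.character(input) && dir.exists(input)) {
    nos_files <- sort(list.files(input, "_nos\\.csv$", full.names = TRUE))
    if (!length(nos_files))
      stop_param("no *_nos.csv matrices found in ", input)
    subjects <- lapply(nos_files, function(f) {
      g <- sub("_nos\\.csv$", "_scalar.csv", f)
      if (!file.exists(g)) stop_param("missing scalar matrix ", g)
      list(nos = read_connectome_csv(f, "nos"),
           scalar = read_connectome_csv(g, "scalar"))
    })
    cls_file <- file.path(input, "classes.csv")
    classes <- if (file.exists(cls_file)) read_class_table(cls_file) else NULL
    return(cohort(subjects, classes))
  }
  stop_param("input must be a phantom_spec, a cohort, or a matrix directory")
}

provenance_record <- function(cfg, reg = NULL) {
  # the output location is not part of the analysis configuration
  echo <- cfg[setdiff(names(cfg), c("input", "out_dir"))]
  echo$input <- if (is.character(cfg$input)) cfg$input
                else class(cfg$input)[1]
  cfg_json <- jsonlite::toJSON(echo, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(as.character(cfg_json), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  list(config = echo, config_md5 = hash, seed = cfg$seed,
       package_version = as.character(utils::packageVersion("myeloconn")),
       regression = reg)
}
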