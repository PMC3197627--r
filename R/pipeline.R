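# End-to-end orchestration: sequences -> (simulate | synthesize | load) ->
# geometry -> ensemble statistics -> report bundle.

#' Pipeline configuration
#'
#' Fully serializable run description; [run_pipeline()] echoes it (plus
#' derived seeds and a config hash) into the run manifest so any run can be
#' reproduced.
#'
#' @param mode `"synthetic"` (no MD; phenotype suite), `"md"` (simulate
#'   ensembles), or `"trajectories"` (analyse GRO frame sequences on disk).
#' @param group fixture group for peptide selection.
#' @param fasta optional FASTA path overriding `group` (structured headers).
#' @param wildtype_id id of the wildtype; default: the peptide labelled
#'   `wildtype`.
#' @param effect synthetic suite effect (`"piston"` or `"null"`).
#' @param n_replicas replicas per peptide.
#' @param n_frames frames per synthetic replica.
#' @param length_ns production length per MD replica (ns).
#' @param seed base seed for everything downstream.
#' @param workers parallel workers for MD replicas.
#' @param outdir output directory (NULL = return results only).
#' @param trajectory_dir for mode "trajectories": directory of
#'   `<id>_rep<k>.gro` files.
#' @param assembly list of overrides for [assembly_spec()].
#' @param engine list of overrides for [engine_params()].
#' @param conventions list of overrides for [geometry_conventions()].
#' @param n_boot bootstrap resamples.
#' @param write_gro write synthetic/MD trajectories as GRO under `outdir`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = "synthetic", group = "WY_scan", fasta = NULL,
                            wildtype_id = NULL, effect = "piston",
                            n_replicas = 10, n_frames = 100, length_ns = 1,
                            seed = 1, workers = 1, outdir = NULL,
                            trajectory_dir = NULL,
                            assembly = list(), engine = list(),
                            conventions = list(), n_boot = 500,
                            write_gro = FALSE) {
  stopifnot(mode %in% c("synthetic", "md", "trajectories"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with [pipeline_config()] fields.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_peptides <- function(config) {
  if (!is.null(config$fasta)) read_helix_fasta(config$fasta)
  else tm2_peptides(config$group)
}

#' Run the full analysis pipeline
#'
#' Per-peptide ensembles are generated (synthetic mode), simulated (md mode)
#' or ingested from GRO frame sequences, measured frame-by-frame, pooled,
#' and compared against the wildtype ensemble; the phenotype report, pooled
#' distributions and a reproducibility manifest are returned and (optionally)
#' written to `outdir` as CSV/JSON.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return list of class `pipeline_result`: peptides, geometries, report,
#'   distributions, manifest, replica_failures.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  conv <- do.call(geometry_conventions, config$conventions)
  peptides <- pipeline_peptides(config)
  failures <- list()

  if (config$mode == "synthetic") {
    suite <- generate_phenotype_suite(effect = config$effect,
                                      n_replicas = config$n_replicas,
                                      n_frames = config$n_frames,
                                      seed = config$seed)
    peptides <- suite$peptides
    trajsets <- suite$ensembles
  } else if (config$mode == "md") {
    ff <- martini_forcefield()
    eng <- do.call(engine_params, config$engine)
    trajsets <- list()
    for (k in seq_len(nrow(peptides))) {
      pep <- peptides[k, ]
      cg <- map_to_cg(build_ideal_helix(pep))
      spec <- do.call(assembly_spec, config$assembly)
      reps <- run_ensemble(spec, cg, n_replicas = config$n_replicas,
                           length_ns = config$length_ns,
                           seed = config$seed + 104729 * k,
                           workers = config$workers, ff = ff, params = eng)
      bad <- !vapply(reps, `[[`, logical(1), "ok")
      if (any(bad))
        failures[[pep$id]] <- vapply(reps[bad], `[[`, character(1), "error")
      trajsets[[pep$id]] <- lapply(reps[!bad], `[[`, "trajectory")
      if (all(bad)) abort(paste0("all replicas failed for ", pep$id))
    }
  } else {
    trajsets <- list()
    for (id in peptides$id) {
      files <- sort(list.files(config$trajectory_dir,
                               pattern = paste0("^", id, "_rep.*\\.gro$"),
                               full.names = TRUE))
      if (length(files)) trajsets[[id]] <- lapply(files, read_gro)
    }
    if (!length(trajsets)) abort("no trajectories found for any peptide")
    peptides <- peptides[peptides$id %in% names(trajsets), ]
  }

  geometries <- lapply(trajsets, ensemble_geometry, conventions = conv)
  wildtype_id <- config$wildtype_id
  if (is.null(wildtype_id)) {
    wt <- peptides$id[peptides$phenotype == "wildtype"]
    wt <- wt[wt %in% names(geometries)]
    if (!length(wt)) abort("no wildtype ensemble present")
    wildtype_id <- wt[1]
  }
  set.seed(config$seed)
  report <- phenotype_report(geometries, peptides, wildtype_id,
                             n_boot = config$n_boot)
  distributions <- lapply(geometries, function(g) {
    lapply(c(shift = "shift", tilt = "tilt", rotation = "rotation"),
           function(v) tryCatch(pool_geometry(g, v), error = function(e) NULL))
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("pistonsim")),
    config = config[setdiff(names(config), "outdir")],
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    wildtype_id = wildtype_id,
    peptide_ids = names(geometries),
    replica_failures = failures,
    forcefield = "martini-style CG table v2.1-like (shipped extdata)")

  result <- structure(list(peptides = peptides, geometries = geometries,
                           report = report, distributions = distributions,
                           manifest = manifest, replica_failures = failures),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_result(result, config, trajsets)
  result
}

write_pipeline_result <- function(result, config, trajsets = NULL) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$report$table, file.path(config$outdir, "summary.csv"),
            row.names = FALSE)
  geo <- bind_rows(lapply(names(result$geometries), function(id) {
    g <- result$geometries[[id]]
    g$id <- id
    g
  }))
  write.csv(geo, file.path(config$outdir, "frame_geometry.csv"), row.names = FALSE)
  dists <- lapply(result$distributions, function(dd) {
    lapply(dd[!vapply(dd, is.null, logical(1))], function(d) {
      list(variable = d$variable, breaks = d$breaks, counts = d$counts,
           mean = d$mean, mode = d$mode, sd = d$sd, circular = d$circular,
           n_used = d$n_used, n_excluded = d$n_excluded,
           n_replicas = d$n_replicas)
    })
  })
  jsonlite::write_json(dists, file.path(config$outdir, "distributions.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (isTRUE(config$write_gro) && !is.null(trajsets)) {
    for (id in names(trajsets)) {
      for (r in seq_along(trajsets[[id]])) {
        write_gro(trajsets[[id]][[r]],
                  file.path(config$outdir, sprintf("%s_rep%03d.gro", id, r)))
      }
    }
  }
  invisible(config$outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$geometries), " ensembles (wildtype: ",
      x$manifest$wildtype_id, ")\n", sep = "")
  print(x$report)
  invisible(x)
}
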