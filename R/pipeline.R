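#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain with defaults at the
#' conventional values: 0.65 nm contact cutoff for phospho- and glycolipid
#' headgroups and 1.0 nm for cholesterol (species table), 1 ns frame
#' interval fallback, Louvain seed 42 at resolution 1, no edge pruning,
#' strict contact continuity, and a fit window of half the trajectory.
#'
#' @param input Path to a GRO (concatenated frames) or PDB (multi-MODEL)
#'   trajectory; frame 1 provides the topology.
#' @param output_dir Directory for artifacts (created if needed).
#' @param species Species labels to analyse; `NULL` = all present.
#' @param species_table Path to a YAML species table, or `NULL` for
#'   [default_species()].
#' @param monomers_per_copy Chains per protein copy (`NULL` = one copy).
#' @param dt Fallback frame interval, ns.
#' @param cutoffs Named numeric overrides of per-species cutoffs, nm.
#' @param seed,resolution,min_weight_fraction Site-detection parameters.
#' @param gap_tolerance,fit_t_max Kinetics parameters (frames; ns).
#' @param shell_cutoff First-shell distance, nm.
#' @param rdf_bin_width RDF bin width, nm.
#' @param max_sites_per_species Residence times are fitted for at most this
#'   many top-weight sites per species.
#' @return A `run_config` list.
#' @export
run_config <- function(input, output_dir, species = NULL,
                       species_table = NULL, monomers_per_copy = NULL,
                       dt = 1, cutoffs = NULL, seed = 42L,
                       resolution = 1.0, min_weight_fraction = 0,
                       gap_tolerance = 0L, fit_t_max = NULL,
                       shell_cutoff = 1.0, rdf_bin_width = 0.1,
                       max_sites_per_species = 2L) {
  cfg <- list(
    input = input, output_dir = output_dir, species = species,
    species_table = species_table, monomers_per_copy = monomers_per_copy,
    dt = dt, cutoffs = cutoffs, seed = as.integer(seed),
    resolution = resolution, min_weight_fraction = min_weight_fraction,
    gap_tolerance = as.integer(gap_tolerance), fit_t_max = fit_t_max,
    shell_cutoff = shell_cutoff, rdf_bin_width = rdf_bin_width,
    max_sites_per_species = as.integer(max_sites_per_species)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!is.character(cfg$input) || !nzchar(cfg$input)) {
    stop("config: 'input' must be a file path", call. = FALSE)
  }
  pos <- c(dt = cfg$dt, shell_cutoff = cfg$shell_cutoff,
           rdf_bin_width = cfg$rdf_bin_width, resolution = cfg$resolution,
           cutoffs = unlist(cfg$cutoffs))
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    stop("config: parameter(s) must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$min_weight_fraction < 0 || cfg$min_weight_fraction > 1) {
    stop("config: min_weight_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$gap_tolerance < 0) {
    stop("config: gap_tolerance must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value YAML mirroring the arguments of [run_config()].
#'
#' @param path YAML file.
#' @param output_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, output_dir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(output_dir)) raw$output_dir <- output_dir
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, per lipid species: contact detection, hotspot table (+ CSV and
#' B-factor-coloured PDB), lateral RDF and first-shell enrichment per
#' leaflet, interaction-site detection on the pooled co-interaction graph
#' (JSON + CSV + edge list), and residence-time fits for the top-weight
#' sites. Also writes the RMSF profile and a machine-readable manifest of
#' parameters and artifacts. All numeric output uses fixed formatting and
#' the manifest carries no timestamps, so a rerun with the same config and
#' inputs reproduces every file byte for byte.
#'
#' @param config A `run_config`.
#' @return The manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sp_table <- if (is.null(config$species_table)) {
    default_species()
  } else {
    read_species_table(config$species_table)
  }
  topo <- read_topology(config$input, species_table = sp_table,
                        monomers_per_copy = config$monomers_per_copy)
  traj <- read_trajectory(config$input, topo, dt = config$dt)
  present <- unique(lipid_beads(topo)$species)
  species <- config$species %||% present
  missing_sp <- setdiff(species, present)
  if (length(missing_sp)) {
    stop("stage contacts failed: species not in system: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }

  artifacts <- list()
  counts <- list(n_frames = n_frames(traj),
                 n_beads = n_beads(topo), species = list())
  out <- function(...) file.path(config$output_dir, paste0(...))
  emit_csv <- function(df, path) {
    readr::write_csv(df, path, progress = FALSE)
    path
  }
  emit_json <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    path
  }

  stage <- "rmsf"
  res <- tryCatch({
    if (n_frames(traj) >= 2L) {
      artifacts$rmsf <- emit_csv(rmsf_profile(traj, topo), out("rmsf.csv"))
    }
    for (sp in species) {
      message("[", sp, "] contacts")
      stage <- paste0("contacts:", sp)
      cutoff <- config$cutoffs[[sp]] %||% NULL
      rec <- contact_events(traj, topo, sp, cutoff = cutoff)
      counts$species[[sp]] <- list(n_contacts = nrow(rec))

      stage <- paste0("hotspots:", sp)
      hs <- withCallingHandlers(
        interaction_frequency(rec),
        warning = function(w) invokeRestart("muffleWarning")
      )
      artifacts[[paste0("hotspots_", sp)]] <-
        emit_csv(dplyr::as_tibble(hs), out("hotspots_", sp, ".csv"))
      if (nrow(hs)) {
        artifacts[[paste0("hotspots_pdb_", sp)]] <-
          write_hotspot_pdb(topo, traj, hs, out("hotspots_", sp, ".pdb"))
      }

      stage <- paste0("density:", sp)
      for (lf in c("outer", "inner")) {
        prof <- withCallingHandlers(
          lateral_rdf(traj, topo, sp, lf,
                      bin_width = config$rdf_bin_width),
          warning = function(w) invokeRestart("muffleWarning")
        )
        if (any(prof$n > 0L)) {
          artifacts[[paste0("rdf_", sp, "_", lf)]] <-
            emit_csv(dplyr::as_tibble(prof), out("rdf_", sp, "_", lf, ".csv"))
          enr <- withCallingHandlers(
            shell_enrichment(traj, topo, sp, lf,
                             shell_cutoff = config$shell_cutoff),
            warning = function(w) invokeRestart("muffleWarning")
          )
          artifacts[[paste0("enrichment_", sp, "_", lf)]] <-
            emit_csv(enr, out("enrichment_", sp, "_", lf, ".csv"))
        }
      }

      stage <- paste0("sites:", sp)
      graph <- build_interaction_graph(rec)
      if (nrow(graph) > 0L) {
        artifacts[[paste0("graph_", sp)]] <-
          emit_csv(dplyr::as_tibble(graph), out("graph_", sp, ".csv"))
        parts <- detect_sites(graph, seed = config$seed,
                              resolution = config$resolution,
                              min_weight_fraction = config$min_weight_fraction)
        counts$species[[sp]]$n_sites <- nrow(parts)
        site_json <- lapply(seq_len(nrow(parts)), function(i) {
          list(site_id = parts$site_id[i],
               residues = parts$residues[[i]],
               total_weight = parts$total_weight[i])
        })
        artifacts[[paste0("sites_", sp)]] <- emit_json(
          list(species = sp, seed = config$seed,
               resolution = config$resolution,
               min_weight_fraction = config$min_weight_fraction,
               modularity = attr(parts, "modularity"), sites = site_json),
          out("sites_", sp, ".json")
        )

        stage <- paste0("kinetics:", sp)
        n_fit <- min(nrow(parts), config$max_sites_per_species)
        fits <- list()
        for (i in seq_len(n_fit)) {
          fit <- tryCatch(
            residence_time_for_site(
              rec, parts$residues[[i]],
              gap_tolerance = config$gap_tolerance,
              fit_t_max = config$fit_t_max
            ),
            error = function(e) conditionMessage(e)
          )
          fits[[i]] <- if (is.character(fit)) {
            list(site_id = parts$site_id[i], error = fit)
          } else {
            list(site_id = parts$site_id[i],
                 residence_time_ns = fit$reported_residence_time,
                 sd_ns = fit$sd_theta2, A = fit$A, B = fit$B,
                 theta1 = fit$theta1, theta2 = fit$theta2,
                 sd_theta1 = fit$sd_theta1,
                 exceeds_window = fit$exceeds_window,
                 fit_t_max = fit$fit_t_max, n_lipids = fit$N_j)
          }
        }
        artifacts[[paste0("residence_", sp)]] <-
          emit_json(fits, out("residence_", sp, ".json"))
      } else {
        counts$species[[sp]]$n_sites <- 0L
      }
    }
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) {
    partial <- list(status = "failed", failed_stage = stage,
                    error = conditionMessage(res),
                    artifacts = artifacts)
    emit_json(partial, out("manifest.json"))
    stop("stage '", stage, "' failed: ", conditionMessage(res),
         call. = FALSE)
  }

  manifest <- list(
    status = "ok",
    package_version = as.character(utils::packageVersion("lipidsites")),
    parameters = config[c("species", "dt", "seed", "resolution",
                          "min_weight_fraction", "gap_tolerance",
                          "fit_t_max", "shell_cutoff", "rdf_bin_width",
                          "max_sites_per_species")],
    conventions = list(frames = "0-based", residues = "1-based",
                       lengths = "nm", times = "ns"),
    counts = counts,
    artifacts = lapply(artifacts, basename)
  )
  emit_json(manifest, out("manifest.json"))
  invisible(manifest)
}
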