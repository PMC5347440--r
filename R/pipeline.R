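#' Pipeline configuration
#'
#' End-to-end demonstration run: generate an artificial implant (capillary
#' bed plus penetrating trees, then trimmed to expose deep boundary
#' nodes), apply the labeling corrections, upscale capillary diameters,
#' derive deep boundary pressures by implanting the network into a larger
#' artificial host, run the discrete RBC simulation on the implant, and
#' analyze the recorded trajectories. A single global seed fans out into
#' per-stage seeds as `seed * 100 + stage index`.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global seed.
#' @param stages subset of
#'   `c("generate", "label", "upscale", "assign_bc", "simulate", "analyze")`
#'   to run (in this fixed order).
#' @param implant parameters of the implant: `extent` (um), `depth` (um),
#'   `hex_edge` (um), `n_trees_x`, `n_trees_y`, `tree_spacing` (um),
#'   `trim_side`, `trim_depth_mm`.
#' @param host parameters of the artificial host: `extent`, `depth`,
#'   `hex_edge`, `n_trees_x`, `n_trees_y`, `tree_spacing` (um).
#' @param sim a [simulation_config()] (its seed is overridden by the
#'   stage seed).
#' @param layers an [analysis_layers()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("generate", "label", "upscale",
                                       "assign_bc", "simulate", "analyze"),
                            implant = list(extent = 1000, depth = 1000,
                                           hex_edge = 60,
                                           n_trees_x = 2, n_trees_y = 2,
                                           tree_spacing = 360,
                                           trim_side = 0.125,
                                           trim_depth_mm = 0.9),
                            host = list(extent = 1600, depth = 1100,
                                        hex_edge = 80,
                                        n_trees_x = 4, n_trees_y = 4,
                                        tree_spacing = 380),
                            sim = simulation_config(),
                            layers = analysis_layers()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, implant = implant, host = host,
                 sim = sim, layers = layers),
            class = "pipeline_config")
}

.stage_seed <- function(config, idx) (config$seed * 100L + idx) %% .Machine$integer.max

.provenance_header <- function(stage, seed, params) {
  paste0("# stage: ", stage, "; seed: ", seed, "; mvnflow ",
         as.character(utils::packageVersion("mvnflow")), "; params: ",
         paste(names(params), unlist(lapply(params, paste, collapse = "/")),
               sep = "=", collapse = " "))
}

.write_artifact <- function(df, path, stage, seed, params = list()) {
  con <- file(path, "w")
  writeLines(.provenance_header(stage, seed, params), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

.read_artifact <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

# generate one artificial MVN (bed + trees) from a parameter list
.generate_artificial <- function(p, seed) {
  template_depth <- p$depth / 0.66
  bed <- generate_capillary_bed(p$extent, p$extent, p$depth,
                                hex_edge = p$hex_edge, seed = seed)
  lat <- penetrating_lattice(p$n_trees_x, p$n_trees_y, p$tree_spacing,
                             origin = rep((p$extent -
                                             (p$n_trees_x - 1) *
                                             p$tree_spacing) / 2, 2))
  trees <- lapply(seq_len(nrow(lat)), function(i) {
    generate_penetrating_tree(
      kind = lat$kind[i], template_depth = template_depth,
      root_diameter = if (lat$kind[i] == "DA") 14 else 18,
      seed = seed + i)
  })
  assemble_artificial_mvn(trees, bed, positions = lat)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order, writing every artifact with a
#' provenance header (stage, seed, parameters, package version) under
#' `out_dir`. Stages whose outputs already exist are skipped, making a
#' rerun with unchanged configuration resumable; a rerun with the same
#' seed reproduces identical stochastic outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with the per-stage results that were computed (network,
#'   bcs, simulation, analysis) and the paths of all artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  paths <- list(
    nodes = file.path(config$out_dir, "implant_nodes.csv"),
    edges = file.path(config$out_dir, "implant_edges.csv"),
    bcs = file.path(config$out_dir, "boundary_conditions.csv"),
    events = file.path(config$out_dir, "trajectory_events.csv"),
    layer_summary = file.path(config$out_dir, "layer_summary.csv"),
    pressure_drop = file.path(config$out_dir, "pressure_drop_by_type.csv"),
    run_log = file.path(config$out_dir, "run_log.csv"))
  res <- list(paths = paths)
  stages <- config$stages
  net <- NULL
  load_net <- function(cur) {
    if (!is.null(cur)) return(cur)
    read_network(paths$nodes, paths$edges)
  }

  if ("generate" %in% stages) {
    if (file.exists(paths$nodes) && file.exists(paths$edges) &&
        !any(c("label", "upscale") %in% stages)) {
      say("generate: outputs exist, skipping")
    } else {
      seed <- .stage_seed(config, 1L)
      say("generate: artificial implant")
      net <- .generate_artificial(config$implant, seed)
      net <- trim_network(net, config$implant$trim_side,
                          config$implant$trim_depth_mm)
      write_network(net, paths$nodes, paths$edges)
    }
  }
  if ("label" %in% stages) {
    say("label: applying diameter/angle corrections")
    net <- label_vessels(load_net(net))
    write_network(net, paths$nodes, paths$edges)
  }
  if ("upscale" %in% stages) {
    say("upscale: capillary diameters toward the goal beta distribution")
    net <- upscale_network(load_net(net))
    write_network(net, paths$nodes, paths$edges)
  }
  bcs <- NULL
  if ("assign_bc" %in% stages) {
    if (file.exists(paths$bcs)) {
      say("assign_bc: output exists, skipping")
      bcs <- .read_artifact(paths$bcs)
    } else {
      seed <- .stage_seed(config, 4L)
      say("assign_bc: compound-network steady solve")
      host <- .generate_artificial(config$host, seed)
      net <- load_net(net)
      comp <- build_compound(net, host)
      hp <- hierarchical_pressures(comp)
      bcs <- hp$implant_bcs
      .write_artifact(bcs, paths$bcs, "assign_bc", seed, config$host)
      res$compound <- comp
    }
  }
  sim <- NULL
  if ("simulate" %in% stages) {
    if (file.exists(paths$events)) {
      say("simulate: trajectory events exist, skipping")
    } else {
      seed <- .stage_seed(config, 5L)
      say("simulate: coupled RBC tracking run")
      if (is.null(bcs)) bcs <- .read_artifact(paths$bcs)
      sc <- config$sim
      sc$seed <- seed
      net <- load_net(net)
      sim <- run_simulation(net, bcs, sc,
                            progress = if (quiet) 0 else 200)
      .write_artifact(sim$trajectories$events, paths$events, "simulate",
                      seed, list(dt = sim$dt, turnover = sim$turnover_time))
      .write_artifact(
        data.frame(dt = sim$dt, turnover_time = sim$turnover_time,
                   steps = sim$steps,
                   injected = sim$audit[["injected"]],
                   exited = sim$audit[["exited"]],
                   resident = sim$audit[["resident"]],
                   conservation_ok = sim$conservation_ok,
                   rule_agreement = sim$rule_agreement,
                   timestep_coverage = sim$timestep_coverage),
        paths$run_log, "simulate", seed, list())
      res$simulation <- sim
    }
  }
  if ("analyze" %in% stages) {
    say("analyze: layer-specific trajectory statistics")
    if (is.null(sim)) {
      ev <- .read_artifact(paths$events)
      traj <- structure(list(events = ev,
                             rbcs = data.frame(
                               rbc = unique(ev$rbc),
                               complete = TRUE),
                             network = load_net(net)),
                        class = "rbc_trajectories")
      solution <- NULL
      rec_window <- NULL
    } else {
      traj <- sim$trajectories
      solution <- sim$solution
      rec_window <- config$sim$record_turnovers * sim$turnover_time
    }
    records <- trajectory_records(traj, config$layers)
    stats_ <- transit_and_feeding_stats(traj, config$layers, solution,
                                        records, rec_window)
    .write_artifact(stats_$layer_summary, paths$layer_summary, "analyze",
                    config$seed, list())
    drops <- pressure_drop_by_type(traj, config$layers)
    .write_artifact(drops, paths$pressure_drop, "analyze", config$seed,
                    list())
    res$records <- records
    res$layer_summary <- stats_$layer_summary
    res$feeding <- stats_$feeding
    res$inplane_fit <- stats_$inplane_fit
    res$pressure_drop <- drops
  }
  res$network <- net
  res
}
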