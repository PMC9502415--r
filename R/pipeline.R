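#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages on a synthetic condition (or a supplied
#' trajectory) and writes per-frame CSV series plus one JSON report. The
#' synthetic stages are driven by the generators with known ground truth:
#' `gates`/`conduction` by [simulate_pore_trajectory()], `bridges` by
#' [simulate_bridge_engagement()], `bend` by [simulate_bent_helix()],
#' `axes` by [simulate_axis_pair()] and `network` by
#' [simulate_correlated_walk()].
#'
#' @param config a configuration list or the path of a YAML file. Keys:
#'   `condition` (label), `seed`, `stages` (character vector), `output`
#'   (directory), stage parameter blocks `pore`, `bridges`, `bend`, `axes`,
#'   `network`, and optionally `input` (`structure`, `trajectory`,
#'   `dt_ns`) with `assignment` (chain = subunit pairs) to analyse real
#'   files instead of the pore generator.
#' @param out_dir overrides `config$output`.
#' @return The report list (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("no such config file: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$output %||% stop("no output directory set",
                                                  call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1)
  stages <- config$stages %||% c("gates", "conduction")
  report <- list(condition = config$condition %||% "unnamed", seed = seed)
  log_stage <- function(...) {
    message(format(Sys.time(), "%H:%M:%S"), " [poregate] ", ...)
  }

  ## --- input: synthetic pore or user files -------------------------------
  pore_env <- NULL
  need_pore <- any(c("gates", "conduction") %in% stages)
  if (need_pore) {
    if (!is.null(config$input)) {
      paths <- c(config$input$structure, config$input$trajectory)
      missing <- paths[!file.exists(paths)]
      if (length(missing)) {
        stop("input file not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      s <- read_structure(config$input$structure)
      traj <- read_trajectory(config$input$trajectory, s$topology,
                              dt_ns = config$input$dt_ns %||% 1)
      assignment <- subunit_assignment(unlist(config$assignment))
      pore_env <- list(trajectory = traj, truth = NULL,
                       assignment = assignment,
                       gate_z = config$gate_z)
    } else {
      p <- config$pore %||% list()
      spec <- pore_spec(
        n_ions = p$n_ions %||% 20,
        gate_z = unlist(p$gate_z %||% c(7.5, -7.5)),
        gate_radius = unlist(p$gate_radius %||% c(5, 5)),
        field = p$field %||% -0.06,
        noise_scale = p$noise_scale %||% 0.5,
        n_frames = p$n_frames %||% 2000,
        dt_ns = p$dt_ns %||% 0.1,
        seed = seed)
      sim <- simulate_pore_trajectory(spec)
      pore_env <- list(trajectory = sim$trajectory, truth = sim$truth,
                       assignment = sim$assignment, gate_z = spec$gate_z)
      log_stage("simulated pore: ", spec$n_frames, " frames, ",
                spec$n_ions, " ions, field ", spec$field, " V/nm")
    }
  }

  roles <- default_role_map()

  if ("gates" %in% stages) {
    log_stage("stage gates (occlusion threshold 5.7 A)")
    traj <- pore_env$trajectory
    open_frac <- list()
    for (g in c("HBC", "G-loop")) {
      gs <- gate_spec(g, traj$topology, pore_env$assignment, roles)
      series <- gate_min_distance(traj, gs)
      write_series_csv(series, file.path(out_dir,
                                         paste0("gate_", g, ".csv")))
      open_frac[[g]] <- classify_occlusion(series, gs$occlusion_threshold)
    }
    report$open_fraction <- open_frac
  }

  if ("conduction" %in% stages) {
    log_stage("stage conduction (hysteresis 2 A)")
    traj <- pore_env$trajectory
    ions <- select_atoms(traj$topology, chain = "I")
    if (!length(ions$indices)) {
      ions <- select_atoms(traj$topology, name = "K")
    }
    res <- count_conductions(traj, ions,
                             unlist(pore_env$gate_z %||% c(7.5, -7.5)))
    ev <- res$events
    ev$entry_ns <- traj$times[ev$entry_frame]
    ev$exit_ns <- traj$times[ev$exit_frame]
    utils::write.csv(ev[c("ion", "entry_ns", "exit_ns", "direction")],
                     file.path(out_dir, "conduction_events.csv"),
                     row.names = FALSE)
    report$n_conductions <- res$count
    if (!is.null(pore_env$truth)) {
      report$n_conductions_truth <- nrow(pore_env$truth$traversal_events)
    }
  }

  if ("bridges" %in% stages) {
    b <- config$bridges %||% list()
    log_stage("stage bridges (cutoff 4.0 A)")
    sim <- simulate_bridge_engagement(
      n_frames = b$n_frames %||% 10000,
      engagement_prob = b$engagement_prob %||% 0.5,
      n_pairs = b$n_pairs %||% 3, seed = seed)
    top <- sim$trajectory$topology
    spec <- salt_bridge_spec(
      select_atoms(top, name = "NZ"),
      select_atoms(top, name = PIP2_PHOSPHATE_NAMES))
    series <- salt_bridge_series(sim$trajectory, spec)
    write_series_csv(series, file.path(out_dir, "salt_bridge.csv"))
    nb <- normalized_salt_bridge(series, n_candidates = b$n_pairs %||% 3,
                                 reference = b$reference)
    report$normalized_salt_bridge <- nb$normalized
    report$fold_change <- nb$fold_change
  }

  if ("bend" %in% stages) {
    b <- config$bend %||% list()
    log_stage("stage bend (pivot-centroid segment vectors)")
    traj <- simulate_bent_helix(helix_spec(
      bend_deg = b$bend_deg %||% 170,
      noise_sigma = b$noise_sigma %||% 0.3,
      n_frames = b$n_frames %||% 100, seed = seed))
    series <- bend_angle_series(traj)
    write_series_csv(series, file.path(out_dir, "bend_angle.csv"))
    report$mean_bend_deg <- mean(series$values)
  }

  if ("axes" %in% stages) {
    a <- config$axes %||% list()
    log_stage("stage axes (principal-direction segment axes)")
    traj <- simulate_axis_pair(a$angle_deg %||% 45,
                               noise_sigma = a$noise_sigma %||% 0,
                               n_frames = a$n_frames %||% 20, seed = seed)
    n_res <- max(traj$topology$atoms$resid)
    series <- axis_angle_series(traj,
                                segA = list(chain = "A", resid = c(1, n_res)),
                                segB = list(chain = "B", resid = c(1, n_res)))
    write_series_csv(series, file.path(out_dir, "axis_angle.csv"))
    report$mean_tm1_sh_deg <- mean(series$values)
  }

  if ("network" %in% stages) {
    nw <- config$network %||% list()
    log_stage("stage network (cij cutoff 0.4, -log|cij| weights)")
    n_res <- nw$n_residues %||% 12
    target <- diag(n_res)
    pr <- unlist(nw$pair %||% c(3, 9))
    target[pr[1], pr[2]] <- target[pr[2], pr[1]] <- nw$rho %||% 0.5
    walk <- simulate_correlated_walk(corr_walk_spec(
      n_res, target, n_frames = nw$n_frames %||% 3000, seed = seed))
    dccm <- compute_dccm(walk, superpose = FALSE)
    utils::write.csv(as.data.frame(unclass(dccm)),
                     file.path(out_dir, "dccm.csv"))
    net <- build_residue_network(dccm, cutoff = nw$cutoff %||% 0.4)
    utils::write.csv(net$edges, file.path(out_dir, "network_edges.csv"),
                     row.names = FALSE)
    src <- net$nodes[nw$source %||% pr[1]]
    snk <- net$nodes[nw$sink %||% pr[2]]
    ens <- suboptimal_paths(net, src, snk, k = nw$k %||% 250)
    usage <- edge_usage(ens)
    utils::write.csv(usage, file.path(out_dir, "edge_usage.csv"),
                     row.names = FALSE)
    report$network <- list(n_edges = nrow(net$edges),
                           n_paths = length(ens$paths),
                           optimal_weight = ens$weights[1],
                           recovered_cij = unclass(dccm)[pr[1], pr[2]])
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(report)
}
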