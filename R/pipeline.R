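# Config-driven driver chaining the stages: align/RMSD -> cluster ->
# hydrogen bonds -> pi contacts -> water bridges -> RDF -> energetics.

#' Inclusive frame count for a time range and stride
#'
#' `floor((t_end - t_start)/stride) + 1`: both endpoints included, e.g.
#' 3-30 ns at 100 ps gives 271 frames and at 10 ps gives 2701.
#'
#' @param t_start,t_end range endpoints, ps.
#' @param stride sampling stride, ps.
#' @return integer frame count.
#' @export
frame_count <- function(t_start, t_end, stride) {
  if (stride <= 0) stop("stride must be positive")
  if (t_end < t_start) stop("t_end must be >= t_start")
  as.integer(floor((t_end - t_start) / stride + 1e-9) + 1)
}

#' Subset a trajectory by time range and stride
#'
#' Keeps frames with `t_start <= t <= t_end` and
#' `(t - t_start) mod stride == 0` (inclusive endpoints).
#'
#' @param traj trajectory.
#' @param t_start,t_end range endpoints, ps.
#' @param stride stride in ps; `NULL` keeps every frame in range.
#' @return subset trajectory.
#' @export
select_frames <- function(traj, t_start = -Inf, t_end = Inf, stride = NULL) {
  t <- frame_times(traj)
  keep <- t >= t_start - 1e-9 & t <= t_end + 1e-9
  if (!is.null(stride)) {
    off <- if (is.finite(t_start)) t_start else min(t)
    keep <- keep & abs((t - off) %% stride) < 1e-6 |
      (keep & abs((t - off) %% stride - stride) < 1e-6)
  }
  if (!any(keep)) stop("no frames in the requested range")
  trajectory(traj$topology, traj$frames[keep])
}

#' Default analysis configuration
#'
#' All stage parameters with their defaults; the returned list is the
#' schema [validate_config()] checks against.  Values mirror the
#' package-wide defaults (2.5 A / 120 deg hydrogen bonds, 2.0 A
#' single-linkage cutoff, 0.05 A RDF bins to 12 A, 298.15 K entropy
#' temperature).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    input = list(fixture = "toy_complex", seed = 1, n_frames = 100,
                 structure = NULL, trajectory = NULL, parameters = NULL,
                 dt = 10),
    frame_range = list(start_ps = NULL, end_ps = NULL, stride_ps = NULL),
    stages = list(rmsd = TRUE, cluster = TRUE, hbonds = TRUE, pipi = TRUE,
                  bridges = TRUE, rdf = TRUE, energetics = TRUE),
    rmsd = list(fit = "protein", measure = "ligand"),
    cluster = list(selection = "ligand", cutoff = 2.0),
    hbonds = list(d_cut = 2.5, angle_cut = 120),
    pipi = list(t_theta_min = 60, s_theta_max = 30, r_cen_max = 6.0,
                d_max = 5.0),
    bridges = list(max_waters = 2),
    rdf = list(r_max = 12, dr = 0.05),
    energetics = list(temperature = 298.15, gamma = 0.0227,
                      beta_const = 3.849, eps_in = 1, eps_out = 80,
                      max_frames = 25),
    output_dir = NULL,
    seed = 1)
}

#' Validate an analysis configuration
#'
#' Reports unknown keys, out-of-range parameters and impossible stage
#' settings as findings; nothing is thrown.
#'
#' @param config nested list (see [default_config()]).
#' @return data.frame with columns `path` and `message`; zero rows when
#'   the configuration is clean.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  bad <- list()
  note <- function(path, msg)
    bad[[length(bad) + 1L]] <<- data.frame(path = path, message = msg,
                                           stringsAsFactors = FALSE)
  unknown <- setdiff(names(config), names(ref))
  for (u in unknown) note(u, "unknown configuration key")
  for (k in intersect(names(config), names(ref))) {
    if (is.list(ref[[k]]) && is.list(config[[k]])) {
      for (u in setdiff(names(config[[k]]), names(ref[[k]])))
        note(paste(k, u, sep = "."), "unknown configuration key")
    }
  }
  if (!is.null(config$stages)) {
    for (s in names(config$stages))
      if (!s %in% names(ref$stages))
        note(paste0("stages.", s), "unknown stage name")
  }
  num_checks <- list(
    c("hbonds", "d_cut"), c("hbonds", "angle_cut"),
    c("cluster", "cutoff"), c("rdf", "r_max"), c("rdf", "dr"),
    c("energetics", "temperature"), c("bridges", "max_waters"))
  for (ck in num_checks) {
    v <- config[[ck[1]]][[ck[2]]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      note(paste(ck, collapse = "."), "must be a positive number")
  }
  fr <- config$frame_range
  if (!is.null(fr$start_ps) && !is.null(fr$end_ps) &&
      fr$end_ps < fr$start_ps)
    note("frame_range", "end_ps is before start_ps")
  if (!length(bad))
    return(data.frame(path = character(0), message = character(0)))
  do.call(rbind, bad)
}

.merge_config <- function(user, ref = default_config()) {
  for (k in names(ref)) {
    if (is.list(ref[[k]]) && !is.null(user[[k]])) {
      for (kk in names(ref[[k]]))
        if (is.null(user[[k]][[kk]])) user[[k]][[kk]] <- ref[[k]][[kk]]
    } else if (is.null(user[[k]])) user[[k]] <- ref[[k]]
  }
  user
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

.load_pipeline_input <- function(cfg) {
  inp <- cfg$input
  if (!is.null(inp$fixture)) {
    if (inp$fixture != "toy_complex")
      stop("unknown fixture kind: ", inp$fixture)
    tc <- make_toy_complex(seed = inp$seed, n_frames = inp$n_frames,
                           dt = inp$dt)
    return(tc)
  }
  st <- read_structure(inp$structure)
  traj <- read_trajectory(inp$trajectory, top = st$topology, dt = inp$dt)
  top <- traj$topology
  params <- NULL
  if (!is.null(inp$parameters)) {
    params <- read_parameter_table(inp$parameters)
    top <- assign_parameters(top, params)
  }
  top <- infer_hydrogens(top, traj$frames[[1]])
  traj$topology <- top
  list(topology = top, trajectory = trajectory(top, traj$frames),
       parameter_table = params, sites = NULL, rings = top$rings)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on the configured
#' input (a file set or the built-in toy-complex fixture), applying the
#' frame-range/stride filter first.  A failing stage is recorded as
#' failed in the report; later independent stages still run.
#'
#' @param config nested list (partial; merged over [default_config()]),
#'   or a path to a YAML file.
#' @return list of class `"analysis_report"`: one result table per
#'   enabled stage plus a `provenance` block (config hash, package
#'   version, frame count).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config)
  findings <- validate_config(cfg)
  if (nrow(findings))
    stop("invalid configuration:\n",
         paste(findings$path, findings$message, sep = ": ", collapse = "\n"))
  set.seed(cfg$seed)
  inp <- .load_pipeline_input(cfg)
  traj <- inp$trajectory
  fr <- cfg$frame_range
  if (!is.null(fr$start_ps) || !is.null(fr$end_ps) || !is.null(fr$stride_ps))
    traj <- select_frames(traj, fr$start_ps %||% -Inf, fr$end_ps %||% Inf,
                          fr$stride_ps)
  top <- traj$topology
  crit <- hbond_criteria(d_cut = cfg$hbonds$d_cut,
                         angle_cut = cfg$hbonds$angle_cut)
  report <- list()
  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return()
    report[[name]] <<- tryCatch(fun(), error = function(e)
      structure(list(error = conditionMessage(e)), class = "stage_failure"))
  }

  prot <- select_atoms(top, "protein and not element H")
  lig <- select_atoms(top, "ligand and not element H")

  run_stage("rmsd", function() {
    fit <- select_atoms(top, cfg$rmsd$fit)
    measure <- select_atoms(top, cfg$rmsd$measure)
    vals <- rmsd_series(traj, fit = fit, measure = measure)
    data.frame(series = cfg$rmsd$measure, mean_rmsd_A = mean(vals),
               rmse_A = series_rmse(vals), n_frames = length(vals))
  })
  run_stage("cluster", function() {
    cl <- cluster_trajectory(traj, sel = select_atoms(top, cfg$cluster$selection),
                             cutoff = cfg$cluster$cutoff)
    data.frame(cluster_id = as.integer(names(cl$populations)),
               population = as.integer(cl$populations),
               representative_frame = as.integer(
                 cl$representatives[names(cl$populations)]))
  })
  run_stage("hbonds", function() {
    donors <- which(top$atoms$element %in% c("N", "O") &
                      vapply(seq_len(n_atoms(top)),
                             function(i) length(bound_hydrogens(top, i)) > 0,
                             logical(1)))
    rows <- lapply(seq_len(n_frames(traj)), function(i) {
      ev <- suppressWarnings(detect_hbonds(
        traj$frames[[i]], top, intersect(donors, c(lig, prot)),
        c(lig, prot), crit))
      if (nrow(ev)) cbind(frame = i, ev) else NULL
    })
    ev <- do.call(rbind, rows)
    if (is.null(ev)) data.frame(frame = integer(0)) else ev
  })
  run_stage("pipi", function() {
    rings <- top$rings
    if (length(rings) < 2) return(data.frame())
    prs <- utils::combn(length(rings), 2)
    do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      ra <- rings[[prs[1, k]]]; rb <- rings[[prs[2, k]]]
      tab <- pi_pi_series(traj, ra, rb)
      cats <- vapply(seq_len(nrow(tab)), function(i)
        classify_pipi(list(r_cen = tab$r_cen_A[i], d = tab$d_A[i],
                           theta = tab$theta_deg[i]),
                      cfg$pipi$t_theta_min, cfg$pipi$s_theta_max,
                      cfg$pipi$r_cen_max, cfg$pipi$d_max), character(1))
      data.frame(pair = tab$pair_label[1],
                 mean_r_cen_A = mean(tab$r_cen_A),
                 mean_theta_deg = mean(tab$theta_deg),
                 dominant_category = names(sort(-table(cats)))[1],
                 category_fraction = max(table(cats)) / nrow(tab))
    }))
  })
  run_stage("bridges", function() {
    waters <- select_atoms(top, "water")
    lsite <- if (!is.null(inp$sites$ligand_O)) inp$sites$ligand_O else
      lig[top$atoms$element[lig] == "O"][1]
    psite <- if (!is.null(inp$sites$MET_N)) inp$sites$MET_N else
      prot[top$atoms$element[prot] == "N"][1]
    bs <- bridge_statistics(traj, lsite, psite, waters, crit,
                            cfg$bridges$max_waters)
    data.frame(ligand_site = lsite, protein_site = psite,
               occupancy = bs$occupancy, exchanges = bs$exchanges)
  })
  run_stage("rdf", function() {
    waters <- select_atoms(top, "water and element H")
    refs <- if (length(top$rings)) top$rings else as.list(lig[1])
    do.call(rbind, lapply(seq_along(refs), function(k) {
      r <- compute_rdf(traj, refs[k], waters, r_max = cfg$rdf$r_max,
                       dr = cfg$rdf$dr)
      pk <- first_peak(r)
      nm <- if (inherits(refs[[k]], "ring_spec")) refs[[k]]$label else
        paste0("atom", refs[[k]])
      data.frame(reference = nm, first_peak_A = pk$r_peak,
                 g_peak = pk$g_peak)
    }))
  })
  run_stage("energetics", function() {
    sub <- traj
    mf <- cfg$energetics$max_frames
    if (n_frames(sub) > mf)
      sub <- trajectory(top, sub$frames[round(seq(1, n_frames(sub),
                                                  length.out = mf))])
    es <- interaction_energy_series(sub, prot, lig, top,
                                    cfg$energetics$temperature)
    ie <- interaction_entropy(es, cfg$energetics$temperature)
    radii <- default_vdw_radii()
    f1 <- sub$frames[[1]]
    s_c <- sasa(f1, c(prot, lig), radii, top)$total
    s_r <- sasa(f1, prot, radii, top)$total
    s_l <- sasa(f1, lig, radii, top)$total
    dgsa <- nonpolar_solvation(s_c, s_r, s_l, cfg$energetics$gamma,
                               cfg$energetics$beta_const)
    born <- radii[top$atoms$element] + 0.4
    gb <- gb_polar_surrogate(f1, prot, lig, born, top,
                             eps_in = cfg$energetics$eps_in,
                             eps_out = cfg$energetics$eps_out)
    fe <- mmpbsa_totals(mean(es$E_vdW), mean(es$E_Coul), gb$ddG_polar,
                        dgsa, ie$minus_TdS)
    cbind(free_energy_row(fe),
          data.frame(entropy_converged = ie$converged,
                     n_frames_energy = n_frames(sub)))
  })

  report$provenance <- list(
    config_hash = .config_hash(cfg),
    package_version = as.character(utils::packageVersion("otbind")),
    n_frames_analyzed = n_frames(traj),
    seed = cfg$seed)
  class(report) <- "analysis_report"
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  stages <- setdiff(names(x), "provenance")
  cat("analysis report (", x$provenance$n_frames_analyzed, " frames):\n",
      sep = "")
  for (s in stages) {
    status <- if (inherits(x[[s]], "stage_failure")) "FAILED" else "ok"
    cat("  -", s, ":", status, "\n")
  }
  invisible(x)
}

#' Write an analysis report's tables to an output directory
#'
#' One CSV per tabular stage plus a `provenance.json`.
#'
#' @param report `"analysis_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in setdiff(names(report), "provenance")) {
    if (inherits(report[[s]], "stage_failure")) {
      writeLines(report[[s]]$error, file.path(dir, paste0(s, ".failed.txt")))
    } else if (is.data.frame(report[[s]])) {
      utils::write.csv(report[[s]], file.path(dir, paste0(s, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
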