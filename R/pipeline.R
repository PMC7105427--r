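# End-to-end orchestration: a YAML run configuration pointing at per-case
# field-series manifests is validated, each case is pushed through the WSS,
# disturbance and mechanics stages, and a comparative report plus per-element
# maps and a JSON run manifest are written. make_demo() generates a paired
# synthetic comparison (stiff vs compliant graft material) that exercises the
# full pipeline.

.read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "time") %in% names(df)))
  df$path <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                    file.path(dirname(path), df$path))
  df
}

#' Validate a run configuration
#'
#' Checks the schema and that every referenced file exists, before any
#' computation starts.
#'
#' @param config list (parsed YAML) or path to a YAML file.
#' @return the validated config list (with `config_path` attribute when read
#'   from file).
#' @export
validate_config <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config$cases), length(config$cases) >= 1L,
            !is.null(names(config$cases)))
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$trend_cutoff)) config$trend_cutoff <- 10L
  base <- if (is.null(cfg_path)) "." else dirname(cfg_path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  for (cn in names(config$cases)) {
    case <- config$cases[[cn]]
    if (is.null(case$wss)) stop("case '", cn, "' has no wss manifest")
    for (key in c("wss", "stress", "velocity")) {
      if (!is.null(case[[key]])) {
        path <- resolve(case[[key]])
        if (!file.exists(path))
          stop("case '", cn, "' references missing file: ", path)
        mf <- .read_manifest(path)
        missing <- mf$path[!file.exists(mf$path)]
        if (length(missing))
          stop("case '", cn, "' manifest ", path, " references missing files: ",
               paste(missing, collapse = ", "))
        config$cases[[cn]][[key]] <- path
      }
    }
  }
  if (!is.null(config$centreline)) {
    config$centreline <- resolve(config$centreline)
    if (!file.exists(config$centreline))
      stop("centreline file not found: ", config$centreline)
  }
  attr(config, "config_path") <- cfg_path
  config
}

#' Run the full comparison pipeline from a config
#'
#' Per case: read the WSS series, compute TAWSS / WSS_max / OSI maps (written
#' as VTP cell data), build the graft / vein / anastomotic-sphere regions,
#' optionally run the Reynolds-decomposition disturbance stage on a velocity
#' series and the mechanics stage on a stress+area series, then assemble the
#' comparative report. Outputs are a pure function of (config, inputs, seed):
#' a rerun writes byte-identical CSVs. A JSON run manifest records the config
#' hash, input checksums, per-stage timings and collected warnings.
#'
#' @param config list or YAML path; see `validate_config()`.
#' @return invisible list with `report` (data.frame), `manifest` (list) and
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  cfg_path <- attr(config, "config_path")
  if (!is.null(cfg_path) && !grepl("^(/|[A-Za-z]:)", out_dir))
    out_dir <- file.path(dirname(cfg_path), out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, paste0("[", name, "] ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  checksums <- list()
  cases_out <- list()
  disturbance_rows <- list()
  cl <- NULL
  if (!is.null(config$centreline)) {
    lm <- numeric(0)
    if (!is.null(config$regions$transition_arclength))
      lm <- c(transition = config$regions$transition_arclength)
    cl <- read_centreline_csv(config$centreline, landmarks = lm)
  }
  mesh_ref <- NULL
  regions <- NULL
  for (cn in names(config$cases)) {
    case <- config$cases[[cn]]
    mf <- .read_manifest(case$wss)
    checksums[[basename(case$wss)]] <- unname(tools::md5sum(case$wss))
    loaded <- stage(paste0(cn, ":read_wss"),
                    read_field_series(mf$path, mf$time, "element", "wss",
                                      units = "Pa"))
    mesh <- loaded$mesh
    if (is.null(mesh_ref)) {
      mesh_ref <- mesh
      regions <- stage("regions", {
        regs <- list()
        if (!is.null(cl) && "transition" %in% names(cl$landmarks))
          regs <- label_segments(mesh, cl)
        if (!is.null(config$regions$anastomosis)) {
          roi <- sphere_roi(unlist(config$regions$anastomosis$center),
                            config$regions$anastomosis$radius %||% 0.012)
          regs$anastomosis <- sphere_region(mesh, roi)
        }
        if (!length(regs)) regs <- list(all = whole_surface_region(mesh))
        regs
      })
    } else if (!.same_topology(mesh_ref, mesh)) {
      stop("case '", cn, "' mesh topology differs from the first case")
    }
    maps <- stage(paste0(cn, ":wss_metrics"), {
      window <- loaded$field$window
      list(tawss = compute_tawss(loaded$field, window),
           wss_max = compute_wss_max(loaded$field, window),
           osi = compute_osi(loaded$field, window))
    })
    write_metric_map(mesh, list(TAWSS = maps$tawss, WSS_max = maps$wss_max,
                                OSI = maps$osi),
                     file.path(out_dir, paste0(cn, "_wss_maps.vtp")))
    bundle <- maps
    if (!is.null(case$stress)) {
      mfs <- .read_manifest(case$stress)
      checksums[[basename(case$stress)]] <- unname(tools::md5sum(case$stress))
      mech <- stage(paste0(cn, ":read_stress"), {
        stress <- read_field_series(mfs$path, mfs$time, "element", "stress",
                                    units = "Pa")$field
        first <- read_vtk_xml(mfs$path[1L])
        area0 <- as.numeric(first$cell_data[["area0"]])
        areas <- t(vapply(mfs$path, function(p)
          as.numeric(read_vtk_xml(p)$cell_data[["area"]]),
          numeric(length(area0))))
        list(stress = stress,
             strain = engineering_strain(area0, areas, stress$window))
      })
      bundle$stress <- mech$stress
      bundle$strain <- mech$strain
    }
    if (!is.null(case$velocity) && !is.null(cl)) {
      mfv <- .read_manifest(case$velocity)
      checksums[[basename(case$velocity)]] <- unname(tools::md5sum(case$velocity))
      dist <- stage(paste0(cn, ":disturbance"), {
        vel <- read_field_series(mfv$path, mfv$time, "node", "velocity",
                                 units = "m s-1")
        u <- vel$field
        if (u$kind == "vector3") {
          mag <- vec_magnitude(u)
          u <- field_series(array(mag, dim = c(dim(mag), 1L)), "scalar",
                            "node", u$window, "m s-1")
        }
        dec <- reynolds_decompose(u, u$window,
                                  trend_spec(config$trend_cutoff))
        rms <- perturbation_rms(dec$perturbation)
        s_max <- max(vel$mesh$points[, 3L]) # stations along the tube axis
        st <- if (is.null(config$stations))
          seq(0.2, 0.8, by = 0.3) * s_max else unlist(config$stations)
        cl_vol <- centreline(cbind(0, 0, seq(0, s_max, length.out = 20L)))
        med <- cross_section_median(rms, vel$mesh, cl_vol, st,
                                    config$slab_half_width %||% 1e-3)
        med$case <- cn
        med
      })
      disturbance_rows[[cn]] <- dist
    }
    cases_out[[cn]] <- bundle
  }
  report <- stage("report", build_report(cases_out, regions, mesh_ref))
  write_report_csv(report, file.path(out_dir, "report.csv"))
  if (length(disturbance_rows)) {
    dist_df <- do.call(rbind, disturbance_rows)
    utils::write.csv(dist_df, file.path(out_dir, "disturbance.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    config_hash = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                  else NA_character_,
    package_version = as.character(utils::packageVersion("graftmetrics")),
    seed = config$seed,
    trend_cutoff = config$trend_cutoff,
    input_checksums = checksums,
    timings_s = lapply(timings, function(x) round(x, 3)),
    warnings = warnings_log)
  manifest_path <- file.path(out_dir, "run_manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, manifest_path) # atomic at run end
  invisible(list(report = report, manifest = manifest, output_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the paired synthetic demo dataset and its config
#'
#' Two cases on the same idealised anastomosis surface and inflow waveform,
#' differing only in graft material: "stiff" (ePTFE-like, E = 55 MPa) and
#' "compliant" (ePU-like, E = 1.5 MPa). The compliant graft distends under
#' the 50 mmHg venous working pressure, so its effective lumen is wider and
#' its prescribed quasi-steady WSS magnitude lower (4 mu Q / (pi r^3) with
#' the distended r); its wall strain is larger (1/E scaling of the
#' Laplace-law hoop strain). WSS in the anastomotic sphere is modulated by a
#' zero-mean cycle cosine so the oscillatory-shear rows of the report are
#' exercised. A small tube volume mesh carries a parabolic velocity profile
#' with seeded high-frequency perturbations (stronger for the stiff case).
#'
#' @param out_dir writable output directory.
#' @param seed integer seed for the perturbation phases.
#' @param n_samples time samples over the cycle.
#' @param n_circ mesh resolution of the demo tubes.
#' @return invisible path to the written config YAML.
#' @export
make_demo <- function(out_dir, seed = 7L, n_samples = 24L, n_circ = 16L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gspec <- tube_spec(3e-3, 0.03, 0.63e-3, n_circ = n_circ, n_axial = 10L)
  vspec <- tube_spec(7.14e-3 / 2, 0.075, 0.357e-3, n_circ = n_circ,
                     n_axial = 20L)
  anat <- make_anastomosis_surface(gspec, vspec, angle = pi / 4)
  mesh <- anat$mesh
  wf <- default_waveform()
  fluid <- fluid_spec()
  window <- uniform_window(wf$period_T, n_samples)
  ts <- window$sample_times
  p_mean <- mmhg_to_pa(50)
  p_t <- p_mean + mmhg_to_pa(10) * sin(2 * pi * ts / wf$period_T)
  materials <- list(stiff = 55e6, compliant = 1.5e6)
  vein_E <- 0.445e6
  write_centreline_csv(anat$centreline, file.path(out_dir, "centreline.csv"))

  n_el <- n_elements(mesh)
  is_graft_el <- logical(n_el)
  is_graft_el[anat$truth$graft$element_ids + 1L] <- TRUE
  in_roi <- logical(n_el)
  in_roi[anat$regions$anastomosis$element_ids + 1L] <- TRUE
  axis_vein <- c(1, 0, 0)
  axis_graft <- c(cos(pi / 4), sin(pi / 4), 0)
  q_t <- waveform_eval(wf, ts)

  for (case_name in names(materials)) {
    E_graft <- materials[[case_name]]
    mat <- material_spec(case_name, E_graft, wall_thickness = gspec$wall_thickness)
    d_eff <- tube_distension(mat, 2 * gspec$radius_zero_pressure, p_mean)
    r_graft_eff <- d_eff / 2
    tau_graft <- 4 * fluid$dynamic_viscosity * q_t / (pi * r_graft_eff^3)
    tau_vein <- 4 * fluid$dynamic_viscosity * q_t /
      (pi * vspec$radius_zero_pressure^3)
    # prescribed spatial pattern: jet impingement amplifies WSS inside the
    # anastomotic sphere (x8), shear decays exponentially with distance from
    # the junction along the vein (stagnant upstream segment, recovering
    # downstream flow); oscillation inside the sphere via a zero-mean cosine
    x_cen <- mesh$element_centroid[, 1L]
    decay <- ifelse(is_graft_el, 1,
                    exp(-abs(x_cen - anat$junction[1L]) / 0.012))
    mod <- cos(2 * pi * (ts - window$t_start) / wf$period_T)
    wss_vals <- array(0, dim = c(n_samples, n_el, 3L))
    magmat <- outer(tau_graft, as.numeric(is_graft_el)) +
      outer(tau_vein, as.numeric(!is_graft_el) * decay)
    magmat[, in_roi] <- 8 * magmat[, in_roi] * mod
    for (d in 1:3) {
      ax <- outer(rep(1, n_samples),
                  ifelse(is_graft_el, axis_graft[d], axis_vein[d]))
      wss_vals[, , d] <- magmat * ax
    }
    # Laplace-law wall stress and areas: graft properties on graft elements,
    # vein properties elsewhere
    r_el <- ifelse(is_graft_el, gspec$radius_zero_pressure,
                   vspec$radius_zero_pressure)
    h_el <- ifelse(is_graft_el, gspec$wall_thickness, vspec$wall_thickness)
    E_el <- ifelse(is_graft_el, E_graft, vein_E)
    nrm <- mesh$element_normal
    stress_vals <- array(0, dim = c(n_samples, n_el, 6L))
    axm <- ifelse(matrix(rep(is_graft_el, 3L), ncol = 3L),
                  matrix(axis_graft, n_el, 3L, byrow = TRUE),
                  matrix(axis_vein, n_el, 3L, byrow = TRUE))
    th <- .cross3(axm, nrm)
    th <- th / sqrt(rowSums(th^2))
    s_th_t <- outer(p_t, r_el / h_el)
    s_z_t <- s_th_t / 2
    comp_idx <- list(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(1L, 2L), c(1L, 3L),
                     c(2L, 3L))
    for (ci in seq_along(comp_idx)) {
      i <- comp_idx[[ci]][1L]; j <- comp_idx[[ci]][2L]
      stress_vals[, , ci] <-
        s_th_t * outer(rep(1, n_samples), th[, i] * th[, j]) +
        s_z_t * outer(rep(1, n_samples), axm[, i] * axm[, j])
    }
    hoop_strain <- s_th_t / outer(rep(1, n_samples), E_el) # p r / (E h)
    areas <- outer(rep(1, n_samples), mesh$element_area) * (1 + hoop_strain)

    case_dir <- file.path(out_dir, case_name)
    dir.create(case_dir, showWarnings = FALSE)
    wss_paths <- character(n_samples)
    stress_paths <- character(n_samples)
    for (s in seq_len(n_samples)) {
      wss_paths[s] <- file.path(case_dir, sprintf("wss_%03d.vtp", s))
      write_vtp(mesh, wss_paths[s],
                cell_data = list(wss = wss_vals[s, , ]))
      stress_paths[s] <- file.path(case_dir, sprintf("stress_%03d.vtp", s))
      write_vtp(mesh, stress_paths[s],
                cell_data = list(stress = stress_vals[s, , ],
                                 area = areas[s, ],
                                 area0 = mesh$element_area))
    }
    utils::write.csv(data.frame(path = file.path(case_name,
                                                 basename(wss_paths)),
                                time = ts),
                     file.path(out_dir, paste0(case_name, "_wss.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(path = file.path(case_name,
                                                 basename(stress_paths)),
                                time = ts),
                     file.path(out_dir, paste0(case_name, "_stress.csv")),
                     row.names = FALSE)
    # velocity series on a small vein-calibre volume mesh, 64 samples so the
    # 40-cycle perturbation is resolved
    vol <- make_tube_volume(vspec$radius_zero_pressure, 0.03)
    vwin <- uniform_window(wf$period_T, 64L)
    rho <- sqrt(vol$mesh$points[, 1L]^2 + vol$mesh$points[, 2L]^2)
    q_v <- waveform_eval(wf, vwin$sample_times)
    u_center <- 2 * q_v / (pi * vspec$radius_zero_pressure^2)
    base_mag <- outer(u_center, 1 - (rho / vspec$radius_zero_pressure)^2)
    base <- field_series(array(base_mag, dim = c(dim(base_mag), 1L)),
                         "scalar", "node", vwin, "m s-1")
    eps_case <- if (case_name == "stiff") 0.06 else 0.04
    pert <- disturbed_velocity_series(base, eps_case, 40 / wf$period_T,
                                      seed = seed + match(case_name,
                                                          names(materials)))
    vel_paths <- character(64L)
    for (s in seq_len(64L)) {
      vel_paths[s] <- file.path(case_dir, sprintf("vel_%03d.vtu", s))
      write_vtu(vol$mesh, vel_paths[s],
                point_data = list(velocity = pert$values[s, , 1L]))
    }
    utils::write.csv(data.frame(path = file.path(case_name,
                                                 basename(vel_paths)),
                                time = vwin$sample_times),
                     file.path(out_dir, paste0(case_name, "_velocity.csv")),
                     row.names = FALSE)
  }
  config <- list(
    seed = seed,
    trend_cutoff = 10L,
    output_dir = "pipeline_out",
    centreline = "centreline.csv",
    regions = list(
      anastomosis = list(center = as.numeric(anat$junction), radius = 0.012),
      transition_arclength = anat$centreline$landmarks[["transition"]]),
    cases = list(
      stiff = list(wss = "stiff_wss.csv", stress = "stiff_stress.csv",
                   velocity = "stiff_velocity.csv"),
      compliant = list(wss = "compliant_wss.csv",
                       stress = "compliant_stress.csv",
                       velocity = "compliant_velocity.csv")))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
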