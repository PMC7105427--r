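# Region-of-interest construction (spherical anastomotic ROI, centreline-based
# graft/vein segmentation) and assembly of the comparative report: per case
# and region, the four WSS exposure rows plus the mechanics summary rows.

#' Spherical region of interest
#'
#' The anastomotic ROI: all surface elements within a sphere around the
#' junction. The default radius is 1.2 cm; the centre is a required input
#' (the idealised anastomosis generator supplies its junction point).
#'
#' @param center xyz centre (m).
#' @param radius sphere radius (m), default 0.012.
#' @return object of class `sphere_roi`.
#' @export
sphere_roi <- function(center, radius = 0.012) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "sphere_roi")
}

#' Elements inside a spherical ROI
#'
#' Membership is by element centroid strictly inside the sphere: unambiguous
#' and consistent with area-weighted statistics. An empty result warns and
#' returns an empty mask.
#'
#' @param mesh a [surface_mesh()].
#' @param roi a [sphere_roi()].
#' @return [region_mask()] labelled "anastomosis".
#' @export
sphere_region <- function(mesh, roi) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(roi, "sphere_roi"))
  d <- sqrt(rowSums((mesh$element_centroid -
                       matrix(roi$center, n_elements(mesh), 3L,
                              byrow = TRUE))^2))
  ids <- which(d < roi$radius) - 1L
  if (!length(ids)) warning("spherical ROI contains no element centroids")
  region_mask(ids, mesh, "anastomosis")
}

#' Graft / vein segmentation by nearest centreline point
#'
#' Assigns every element to the nearest point of the centreline polyline
#' (dense resampling of its segments) and labels it "graft" if that point's
#' arclength is below the `transition` landmark, else "vein". The two masks
#' are disjoint and cover the mesh.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [centreline()] whose landmarks contain `transition` (m).
#' @param resolution approximate spacing (m) of the centreline resampling.
#' @return named list of [region_mask()]s: `graft`, `vein`.
#' @export
label_segments <- function(mesh, cl, resolution = 5e-4) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(cl, "centreline"))
  if (!("transition" %in% names(cl$landmarks)))
    stop("centreline landmarks must include 'transition'")
  trans <- cl$landmarks[["transition"]]
  total <- cl$arclength[length(cl$arclength)]
  s_dense <- seq(0, total, by = resolution)
  dense <- t(vapply(s_dense, function(s) centreline_at(cl, s)$point,
                    numeric(3L)))
  cen <- mesh$element_centroid
  nearest_arc <- vapply(seq_len(nrow(cen)), function(i) {
    d2 <- rowSums((dense - matrix(cen[i, ], nrow(dense), 3L, byrow = TRUE))^2)
    s_dense[which.min(d2)]
  }, numeric(1L))
  is_graft <- nearest_arc < trans
  out <- list(graft = region_mask(which(is_graft) - 1L, mesh, "graft"),
              vein = region_mask(which(!is_graft) - 1L, mesh, "vein"))
  stopifnot(length(out$graft$element_ids) + length(out$vein$element_ids) ==
              n_elements(mesh))
  out
}

#' Comparative report across cases, regions and metrics
#'
#' For each named case (a bundle of metric maps and optional stress/strain
#' series) and each region: the four WSS exposure area fractions, and, when
#' mechanics series are present, the mechanics summary rows. Cell ordering is
#' deterministic (cases, then regions, then metrics, in the order supplied),
#' so a repeated run yields a byte-identical CSV.
#'
#' @param cases named list; each case is a list with elements `tawss`,
#'   `wss_max`, `osi` (metric_maps), and optionally `stress`
#'   (sym_tensor3 or precomputed von Mises `field_series`) and `strain`
#'   (scalar `field_series`).
#' @param regions named list of [region_mask()]s shared by all cases.
#' @param mesh the shared [surface_mesh()].
#' @param thresholds named list of [threshold_spec()]s; defaults to
#'   [default_wss_thresholds()].
#' @return data.frame with columns case, region, metric, value, units.
#' @export
build_report <- function(cases, regions, mesh,
                         thresholds = default_wss_thresholds()) {
  stopifnot(length(cases) > 0, !is.null(names(cases)),
            length(regions) > 0, !is.null(names(regions)))
  map_for <- function(case, metric_name) {
    key <- switch(metric_name, TAWSS = "tawss", WSS_max = "wss_max",
                  OSI = "osi", stop("unknown metric ", metric_name))
    m <- case[[key]]
    if (is.null(m)) stop("case is missing metric map '", key, "'")
    if (length(m$values) != n_elements(mesh))
      stop("metric map '", key, "' is inconsistent with the shared mesh")
    m
  }
  rows <- list()
  for (cn in names(cases)) {
    case <- cases[[cn]]
    for (rn in names(regions)) {
      for (tn in names(thresholds)) {
        th <- thresholds[[tn]]
        map <- map_for(case, th$metric_name)
        lbl <- sprintf("%s %s %.3g", th$metric_name,
                       if (th$direction == "above") ">" else "<", th$bound)
        rows[[length(rows) + 1L]] <- data.frame(
          case = cn, region = rn, metric = lbl,
          value = area_fraction(map, th, regions[[rn]], mesh),
          units = "%", stringsAsFactors = FALSE)
      }
    }
    if (!is.null(case$stress) || !is.null(case$strain)) {
      mech <- mechanics_report(case$stress, case$strain, regions, mesh)
      for (i in seq_len(nrow(mech))) {
        for (col in c("median", "median_pulsatility", "robust_max",
                      "max_pulsatility")) {
          rows[[length(rows) + 1L]] <- data.frame(
            case = cn, region = mech$region[i],
            metric = paste(mech$quantity[i], col),
            value = mech[[col]][i], units = mech$units[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  if (anyDuplicated(report[, c("case", "region", "metric")]))
    stop("duplicate (case, region, metric) cells in report")
  report
}

#' Write a comparison report as CSV
#'
#' @param report data.frame from [build_report()].
#' @param path output CSV path.
#' @return invisible `path`.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
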