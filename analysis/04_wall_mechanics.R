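#!/usr/bin/env Rscript
# Step 4: wall-mechanics summary per case and region.
#
# Reads each case's Cauchy stress + element-area series, computes von Mises
# stress, area-based engineering strain and their cycle pulsatility, and
# tabulates per region: area-weighted median, median pulsatility, robust
# (top-1%-omitted) maximum and maximum pulsatility. Stress in kPa, strain in
# %. Writes results/mechanics.csv.

suppressPackageStartupMessages(library(graftmetrics))

demo <- file.path("results", "demo")
cfg <- yaml::read_yaml(file.path(demo, "config.yaml"))

tabs <- list()
for (cn in names(cfg$cases)) {
  mf <- utils::read.csv(file.path(demo, cfg$cases[[cn]]$stress))
  paths <- file.path(demo, mf$path)
  stress <- read_field_series(paths, mf$time, "element", "stress",
                              units = "Pa")
  first <- read_vtk_xml(paths[1])
  area0 <- as.numeric(first$cell_data$area0)
  areas <- t(vapply(paths, function(p)
    as.numeric(read_vtk_xml(p)$cell_data$area), numeric(length(area0))))
  strain <- engineering_strain(area0, areas, stress$field$window)

  mesh <- stress$mesh
  cl <- read_centreline_csv(
    file.path(demo, cfg$centreline),
    landmarks = c(transition = cfg$regions$transition_arclength))
  regions <- label_segments(mesh, cl)
  regions$anastomosis <- sphere_region(
    mesh, sphere_roi(unlist(cfg$regions$anastomosis$center),
                     cfg$regions$anastomosis$radius))
  tab <- mechanics_report(stress$field, strain, regions, mesh)
  tab <- cbind(case = cn, tab)
  tabs[[cn]] <- tab
}
mech <- do.call(rbind, tabs)
utils::write.csv(mech, file.path("results", "mechanics.csv"),
                 row.names = FALSE)
cat("wrote results/mechanics.csv\n\n")
print(mech[mech$region == "graft", ], row.names = FALSE)
cat("\nThe compliant graft carries lower wall stress but strains more;\n")
cat("the stiff graft barely strains (rigid wall) at high stress.\n")
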