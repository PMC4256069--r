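#' Run the full synthetic mapping pipeline
#'
#' Orchestrates: synthetic-system generation (or ensemble input), the
#' insertion free-energy map, the explicit-ligand density map, and the
#' landscape analysis, writing all artifacts plus a manifest with input
#' settings and file checksums. Rerunning with the same configuration
#' reproduces identical outputs (the manifest records md5 sums so this is
#' checkable).
#'
#' @param config a nested list, or the path of a YAML file holding one.
#'   Recognized top-level entries (all optional except \code{output_dir}):
#'   \describe{
#'     \item{seed}{integer master seed (default 1).}
#'     \item{output_dir}{directory for artifacts (created if needed).}
#'     \item{stages}{character vector out of \code{c("synth", "ils",
#'       "density", "landscape")}; default all.}
#'     \item{input}{\code{ensemble}/\code{lj_table} paths to read instead
#'       of synthesizing.}
#'     \item{synth}{\code{open_fraction} (default 1), \code{n_frames}
#'       (default 20), \code{explicit_steps} (default 200000).}
#'     \item{ils}{\code{grid} = list(origin, spacing, dims) and any
#'       \code{\link{ils_settings}} fields.}
#'     \item{density}{\code{iso_level} (default 0.00015).}
#'     \item{landscape}{\code{cutoff} (default 20), \code{connectivity}
#'       (default 26), \code{cutoff_mode} (default "voxel").}
#'   }
#' @return the run manifest (invisibly): files written, checksums, counts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  .assert(is.list(config), "config must be a list or a YAML file path")
  .assert(!is.null(config$output_dir), "config$output_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages)) stages <- c("synth", "ils", "density", "landscape")
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # validate referenced inputs before any compute
  if (!is.null(config$input$ensemble)) {
    .assert(file.exists(config$input$ensemble),
            paste("input ensemble not found:", config$input$ensemble))
    lj <- if (!is.null(config$input$lj_table)) config$input$lj_table else
      paste0(config$input$ensemble, ".lj")
    .assert(file.exists(lj), paste("input LJ table not found:", lj))
  }

  manifest <- list(config = config, seed = seed, files = list(),
                   counts = list(),
                   versions = list(gasmap =
                                     as.character(utils::packageVersion("gasmap")),
                                   R = paste(R.version$major,
                                             R.version$minor, sep = ".")))
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste("pipeline aborted in stage:", name, "--",
                       conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[gasmap] stage %-9s done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  probe <- do.call(probe_spec, if (is.null(config$probe)) list() else
    config$probe)
  synth_cfg <- config$synth
  n_frames <- if (is.null(synth_cfg$n_frames)) 20L else
    as.integer(synth_cfg$n_frames)

  ensemble <- NULL
  if (!is.null(config$input$ensemble)) {
    ensemble <- run_stage("input", function()
      read_ensemble(config$input$ensemble,
                    if (!is.null(config$input$lj_table))
                      config$input$lj_table else
                        paste0(config$input$ensemble, ".lj")))
  } else if ("synth" %in% stages) {
    ensemble <- run_stage("synth", function() {
      of <- if (is.null(synth_cfg$open_fraction)) 1 else
        synth_cfg$open_fraction
      spec <- make_channel_system(of, seed = seed)
      ens <- make_fluctuating_ensemble(spec, n_frames)
      write_ensemble(ens, file.path(out, "ensemble.pdb"))
      ens
    })
    manifest$files$ensemble <- file.path(out, "ensemble.pdb")
    manifest$counts$frames <- ensemble$n_frames
    manifest$counts$sites <- ensemble$n_sites
  }

  map <- NULL
  if ("ils" %in% stages) {
    map <- run_stage("ils", function() {
      .assert(!is.null(ensemble), "ils stage needs an ensemble")
      ic <- config$ils
      gspec <- ic$grid
      grid <- if (is.null(gspec)) {
        scalar_grid3d(origin = c(1, 2, 2), spacing = 1,
                      dims = c(19, 11, 11))
      } else scalar_grid3d(gspec$origin, gspec$spacing, gspec$dims)
      sfields <- intersect(names(ic), names(formals(ils_settings)))
      settings <- do.call(ils_settings,
                          c(ic[sfields],
                            if (!"seed" %in% sfields) list(seed = seed)))
      m <- compute_ils_map(ensemble, probe, grid, settings)
      write_grid(m$grid, file.path(out, "map.dx"))
      message(sprintf("[gasmap]   %d of %d voxels capped", sum(m$capped),
                      n_voxels(grid)))
      m
    })
    manifest$files$map <- file.path(out, "map.dx")
    manifest$counts$voxels_capped <- sum(map$capped)
  }

  if ("density" %in% stages) {
    dens <- run_stage("density", function() {
      .assert(!is.null(ensemble), "density stage needs an ensemble")
      steps <- if (is.null(synth_cfg$explicit_steps)) 200000L else
        as.integer(synth_cfg$explicit_steps)
      traj <- sample_explicit_ligand(ensemble, probe, n_steps = steps,
                                     seed = seed + 1L, record_stride = 5L)
      grid <- if (!is.null(map)) map$grid else
        scalar_grid3d(origin = c(1, 2, 2), spacing = 1, dims = c(19, 11, 11))
      d <- compute_density_map(traj, grid)
      write_grid(d, file.path(out, "density.dx"))
      lvl <- if (is.null(config$density$iso_level)) 0.00015 else
        config$density$iso_level
      iso <- isosurface_report(d, lvl)
      utils::write.csv(data.frame(frame = seq_along(traj$positions[, 1, 1]),
                                  x = traj$positions[, 1, 1]),
                       file.path(out, "ligand_x.csv"), row.names = FALSE)
      list(density = d, iso = iso)
    })
    manifest$files$density <- file.path(out, "density.dx")
    manifest$counts$iso_voxels <- dens$iso$n_voxels
    manifest$counts$iso_components <- dens$iso$n_components
  }

  if ("landscape" %in% stages) {
    net <- run_stage("landscape", function() {
      .assert(!is.null(map), "landscape stage needs the ils stage")
      lc <- config$landscape
      cutoff <- if (is.null(lc$cutoff)) 20 else lc$cutoff
      conn <- if (is.null(lc$connectivity)) 26 else lc$connectivity
      mode <- if (is.null(lc$cutoff_mode)) "voxel" else lc$cutoff_mode
      net <- analyze_landscape(map, cutoff, conn, mode)
      write_network_json(net, file.path(out, "network.json"))
      net
    })
    manifest$files$network <- file.path(out, "network.json")
    manifest$counts$minima <- nrow(net$nodes)
    manifest$counts$edges <- nrow(net$edges)
  }

  files <- unlist(manifest$files)
  ck <- tools::md5sum(files)
  names(ck) <- names(files)
  manifest$checksums <- as.list(ck)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Write a pathway network as JSON
#'
#' Nodes (id, position, energy, exterior flag) and edges (basin pair,
#' saddle energy and voxel, both barriers, polyline of voxel positions).
#'
#' @param network a \code{pathway_network}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_network_json <- function(network, path) {
  nodes <- network$nodes
  ed <- network$edges
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    list(basin_a = ed$basin_a[i], basin_b = ed$basin_b[i],
         voxel = ed$voxel[i], energy = ed$energy[i],
         barrier_ab = ed$barrier_ab[i], barrier_ba = ed$barrier_ba[i],
         path = apply(voxel_position(network$grid, ed$path[[i]]), 1,
                      function(r) as.list(r)))
  })
  jsonlite::write_json(list(cutoff = network$cutoff,
                            connectivity = network$connectivity,
                            nodes = nodes, edges = edges),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Quick internal consistency check
#'
#' Runs a handful of fast invariants of the pipeline: the ideal-gas limit
#' of the insertion map (exactly zero everywhere), density-map
#' normalization, tessellation partitioning and saddle dominance on a
#' random grid, and bit-reproducibility of the ensemble generator.
#'
#' @param verbose print per-check results.
#' @return TRUE if all checks pass (invisibly), otherwise stops.
#' @export
run_selftest <- function(verbose = TRUE) {
  say <- function(...) if (verbose) message("[selftest] ", ...)
  spec <- toy_system_spec(c(8, 8, 8),
                          data.frame(x = c(3, 5), y = 4, z = 4,
                                     epsilon = 0.5, sigma = 3.2,
                                     thermal_sigma = 0.2), seed = 7)
  ens <- make_fluctuating_ensemble(spec, 3)
  stopifnot(identical(ens$coords,
                      make_fluctuating_ensemble(spec, 3)$coords))
  say("ensemble generation is reproducible")
  g <- scalar_grid3d(c(2, 2, 2), 1, c(4, 4, 4))
  m0 <- compute_ils_map(ens, probe_spec(epsilon = 0), g,
                        ils_settings(n_insertions_per_voxel = 8, seed = 3))
  stopifnot(all(m0$grid$values == 0))
  say("ideal-gas probe gives an identically zero map")
  set.seed(11)
  traj <- ligand_trajectory(matrix(runif(300 * 3, 0, 8), ncol = 3), c(8, 8, 8))
  d <- compute_density_map(traj, g)
  inside <- sum(!is.na(position_to_voxel(g, matrix(traj$positions, ncol = 3))))
  stopifnot(isTRUE(all.equal(sum(d$values) * prod(g$spacing),
                             inside / traj$n_frames)))
  say("density map normalization is exact")
  set.seed(12)
  rg <- scalar_grid3d(c(0, 0, 0), 1, c(6, 6, 6), stats::runif(216, -5, 5))
  tess <- tessellate(rg, 26, cutoff = 10)
  stopifnot(sum(table(tess$labels)) == sum(!is.na(tess$labels)))
  sad <- find_saddles(rg, tess)
  lo <- pmax(tess$minima$energy[sad$basin_a],
             tess$minima$energy[sad$basin_b])
  stopifnot(all(sad$energy >= lo))
  say("tessellation partitions; saddles dominate their minima")
  say("all checks passed")
  invisible(TRUE)
}
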