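#' 15N orientational shift restraint
#'
#' A measured oriented-sample \eqn{^{15}}N chemical shift for one labeled
#' residue, with an acceptance half-width: a helix orientation is
#' compatible with the restraint when the forward-computed averaged shift
#' falls within \code{observed +/- error}.
#'
#' @param residue 1-based residue index of the labeled amide.
#' @param observed measured shift in ppm.
#' @param error acceptance half-width in ppm (> 0).
#' @return Object of class \code{shift_restraint}.
#' @examples
#' shift_restraint(11, 80.0, 2.5)
#' shift_restraint(12, 70.0, 4.0)
#' @export
shift_restraint <- function(residue, observed, error) {
  if (!(error > 0)) stop("restraint error must be > 0")
  structure(list(residue = as.integer(residue), observed = observed,
                 error = error), class = "shift_restraint")
}

new_compatibility_map <- function(tilt_grid, pitch_grid, mask, shifts,
                                  restraint_ids) {
  structure(list(tilt_grid = tilt_grid, pitch_grid = pitch_grid,
                 mask = mask, shifts = shifts,
                 restraint_ids = restraint_ids),
            class = "compatibility_map")
}

#' @export
print.compatibility_map <- function(x, ...) {
  cat(sprintf(
    "Tilt/pitch compatibility map: %d x %d cells, %d compatible (%.1f%%)\n",
    length(x$tilt_grid), length(x$pitch_grid), sum(x$mask),
    100 * mean(x$mask)))
  cat("  restraints:", paste(x$restraint_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Scan a restraint over the tilt/pitch grid
#'
#' Forward-computes the motionally averaged \eqn{^{15}}N shift of the
#' restrained residue at every orientation on a regular tilt/pitch grid
#' and marks the orientations whose shift falls within the restraint's
#' acceptance band. Tilt covers [0, 180] and pitch [0, 360) degrees; the
#' pitch axis is periodic.
#'
#' @param model a \code{\link{build_ideal_helix}} model containing the
#'   restrained residue.
#' @param tensor a \code{\link{csa_tensor}}.
#' @param motion a \code{\link{motion_model}}.
#' @param restraint a \code{\link{shift_restraint}}.
#' @param grid_step grid spacing in degrees (must divide 180 and 360).
#' @return A \code{compatibility_map}: tilt/pitch grids, logical mask
#'   (rows = tilt, cols = pitch), the forward-shift surface, and the
#'   contributing restraint id.
#' @export
scan_restraint <- function(model, tensor, motion, restraint, grid_step = 1) {
  stopifnot(inherits(model, "helix_model"),
            inherits(restraint, "shift_restraint"))
  n_res <- nchar(model$sequence)
  if (restraint$residue < 2 || restraint$residue > n_res)
    stop("restraint residue ", restraint$residue, " not in model (2..",
         n_res, ")")
  if (abs(180 / grid_step - round(180 / grid_step)) > 1e-9 ||
      abs(360 / grid_step - round(360 / grid_step)) > 1e-9)
    stop("grid_step must divide 180 and 360")
  tilt_grid <- seq(0, 180, by = grid_step)
  pitch_grid <- seq(0, 360 - grid_step, by = grid_step)
  frame <- amide_frame(model, restraint$residue)
  S <- tensor_in_helix_frame(frame, tensor)
  shifts <- averaged_shift_grid(S, tilt_grid, pitch_grid, motion)
  mask <- abs(shifts - restraint$observed) <= restraint$error
  new_compatibility_map(tilt_grid, pitch_grid, mask, shifts,
                        sprintf("res%d:%.1f+/-%.1fppm", restraint$residue,
                                restraint$observed, restraint$error))
}

#' Intersect compatibility maps
#'
#' Cell-wise logical AND of maps on identical grids: the orientations
#' compatible with every contributing restraint simultaneously.
#'
#' @param maps list of \code{compatibility_map} objects on one grid.
#' @return A \code{compatibility_map} with concatenated restraint ids
#'   (the forward-shift surface is dropped, as it is restraint-specific).
#' @export
intersect_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  mask <- ref$mask
  ids <- ref$restraint_ids
  for (m in maps[-1]) {
    if (!identical(m$tilt_grid, ref$tilt_grid) ||
        !identical(m$pitch_grid, ref$pitch_grid))
      stop("compatibility maps are on different grids")
    mask <- mask & m$mask
    ids <- c(ids, m$restraint_ids)
  }
  new_compatibility_map(ref$tilt_grid, ref$pitch_grid, mask, NULL, ids)
}

# circular mean of angles in degrees
circ_mean_deg <- function(a) {
  r <- deg2rad(a)
  (rad2deg(atan2(mean(sin(r)), mean(cos(r))))) %% 360
}

#' Connected solution regions of a compatibility map
#'
#' Labels the connected components (8-connectivity, with wrap-around on
#' the periodic pitch axis) of the compatible set, discards components
#' smaller than \code{min_area} cells, and returns them sorted by area
#' descending, labeled I, II, ...
#'
#' @param map a \code{compatibility_map}.
#' @param min_area minimum component size in grid cells (default 3).
#' @return List of \code{solution_region} objects, each with
#'   \code{label}, \code{cells} (data frame of tilt/pitch), \code{centroid}
#'   (\code{\link{orientation}} with circular-mean pitch), \code{area_deg2}
#'   and \code{n_cells}.
#' @export
find_regions <- function(map, min_area = 3) {
  stopifnot(inherits(map, "compatibility_map"))
  idx <- which(map$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  nt <- length(map$tilt_grid); np <- length(map$pitch_grid)
  cell_id <- (idx[, 1] - 1L) * np + idx[, 2]  # row-major ids of true cells
  pos <- integer(nt * np); pos[cell_id] <- seq_len(nrow(idx))
  # 8-neighbour edges among true cells, pitch (column) wraps around
  edges <- NULL
  for (dr in c(-1L, 0L, 1L)) {
    for (dc in c(-1L, 0L, 1L)) {
      if (dr == 0L && dc == 0L) next
      r2 <- idx[, 1] + dr
      c2 <- ((idx[, 2] - 1L + dc) %% np) + 1L
      ok <- r2 >= 1L & r2 <= nt
      if (!any(ok)) next
      id2 <- (r2[ok] - 1L) * np + c2[ok]
      nb <- pos[id2]
      hit <- nb > 0L
      if (any(hit))
        edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  step_t <- if (nt > 1) diff(map$tilt_grid[1:2]) else 1
  step_p <- if (np > 1) diff(map$pitch_grid[1:2]) else 1
  cell_area <- step_t * step_p
  regions <- lapply(seq_len(max(comp)), function(k) {
    sel <- comp == k
    if (sum(sel) < min_area) return(NULL)
    cells <- data.frame(tilt = map$tilt_grid[idx[sel, 1]],
                        pitch = map$pitch_grid[idx[sel, 2]])
    list(cells = cells,
         centroid = orientation(mean(cells$tilt), circ_mean_deg(cells$pitch)),
         n_cells = sum(sel), area_deg2 = sum(sel) * cell_area)
  })
  regions <- Filter(Negate(is.null), regions)
  if (length(regions) == 0) return(list())
  regions <- regions[order(-vapply(regions, `[[`, 0, "area_deg2"))]
  roman <- as.character(utils::as.roman(seq_along(regions)))
  mapply(function(r, lab) {
    r$label <- lab
    structure(r, class = "solution_region")
  }, regions, roman, SIMPLIFY = FALSE)
}

#' @export
print.solution_region <- function(x, ...) {
  cat(sprintf(
    "Solution region %s: centroid tilt %.1f deg, pitch %.1f deg, area %.0f deg^2 (%d cells)\n",
    x$label, x$centroid$tilt, x$centroid$pitch, x$area_deg2, x$n_cells))
  invisible(x)
}

#' Classify a solution region's membrane topology
#'
#' Classifies by the centroid tilt angle: in-plane (surface-parallel) when
#' tilt falls within the in-plane band (default [75, 105] degrees),
#' transmembrane when within \code{tm} degrees of 0 or 180 (default 30),
#' otherwise tilted.
#'
#' @param region a \code{solution_region}.
#' @param in_plane length-2 tilt bounds (degrees) of the in-plane class.
#' @param tm half-width (degrees) of the transmembrane class at each pole.
#' @return One of \code{"in-plane"}, \code{"transmembrane"},
#'   \code{"tilted"}.
#' @export
classify_topology <- function(region, in_plane = c(75, 105), tm = 30) {
  stopifnot(inherits(region, "solution_region"))
  t <- region$centroid$tilt
  if (t >= in_plane[1] && t <= in_plane[2]) return("in-plane")
  if (t <= tm || t >= 180 - tm) return("transmembrane")
  "tilted"
}

#' Full tilt/pitch restriction analysis
#'
#' Convenience driver: scans every restraint on a common grid, intersects
#' the compatibility maps, extracts connected solution regions and
#' classifies each. Reports the shift-under-field-inversion degeneracy
#' (the observed shift is invariant under reversing the field direction,
#' i.e. under tilt -> 180 - tilt with pitch -> pitch + 180), so solutions
#' typically appear as symmetry-related pairs; all are returned.
#'
#' @param model,tensor,motion as in \code{\link{scan_restraint}}.
#' @param restraints list of \code{\link{shift_restraint}} objects.
#' @param grid_step grid spacing in degrees.
#' @param min_area minimum region size in cells.
#' @return List with \code{maps} (per restraint), \code{intersection},
#'   \code{regions}, and \code{table} (a data frame: label, centroid tilt
#'   and pitch, area, n_cells, class).
#' @export
run_topology_analysis <- function(restraints, model = NULL,
                                  tensor = csa_tensor(),
                                  motion = motion_model(),
                                  grid_step = 1, min_area = 3) {
  if (is.null(model))
    model <- build_ideal_helix(SAAP148, -65, -45)
  if (inherits(restraints, "shift_restraint")) restraints <- list(restraints)
  maps <- lapply(restraints, function(r)
    scan_restraint(model, tensor, motion, r, grid_step))
  inter <- intersect_maps(maps)
  regions <- find_regions(inter, min_area)
  tab <- if (length(regions) == 0) {
    data.frame(label = character(), tilt = numeric(), pitch = numeric(),
               area_deg2 = numeric(), n_cells = integer(),
               class = character())
  } else {
    do.call(rbind, lapply(regions, function(r)
      data.frame(label = r$label, tilt = r$centroid$tilt,
                 pitch = r$centroid$pitch, area_deg2 = r$area_deg2,
                 n_cells = r$n_cells, class = classify_topology(r))))
  }
  list(model = model, maps = maps, intersection = inter,
       regions = regions, table = tab)
}

#' Plot a compatibility map
#'
#' Base-graphics image of a tilt/pitch compatibility mask (or of an
#' intersection), tilt on the vertical axis as in the usual restriction
#' plots.
#'
#' @param x a \code{compatibility_map}.
#' @param ... passed to \code{graphics::image}.
#' @export
plot.compatibility_map <- function(x, ...) {
  graphics::image(x$pitch_grid, x$tilt_grid, t(x$mask * 1),
                  xlab = "pitch (deg)", ylab = "tilt (deg)",
                  col = c("white", "steelblue"), useRaster = TRUE, ...)
  graphics::box()
}
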