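#' Structure roster for head-and-neck phantoms
#'
#' The fixed set of structures used throughout the package: up to three
#' clinical target volumes (CTV1 primary, CTV2 secondary, CTV3 tertiary)
#' and twelve organs at risk typical of head-and-neck planning.
#'
#' @return A data.frame with columns `name` and `role` (`"CTV1"`, `"CTV2"`,
#'   `"CTV3"` or `"OAR"`).
#' @export
structure_roster <- function() {
  data.frame(
    name = c("CTV1", "CTV2", "CTV3",
             "BRS", "SC", "MAN", "LAR", "PHY", "PARL", "PARR",
             "COCHL", "COCHR", "SMGL", "SMGR", "ESO"),
    role = c("CTV1", "CTV2", "CTV3", rep("OAR", 12)),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Describes a synthetic voxelized anatomy: grid geometry, spherical
#' structures (position and radius in mm) and per-target prescription doses.
#' The default is a 64 x 64 single-slice grid at 2 mm spacing carrying all
#' three CTVs and twelve OARs, with prescriptions of 70 / 59.85 / 53.90 GyRBE
#' for CTV1/2/3.
#'
#' @param grid_shape integer triple, voxels per axis. A trailing dimension of
#'   1 gives a planar (single-slice) phantom.
#' @param spacing numeric triple, mm per voxel along each axis.
#' @param structures data.frame with columns `name`, `role`, `x`, `y`, `z`
#'   (center, mm; may be `NA` with `placement = "random"`) and `radius` (mm).
#'   Defaults to the full 15-structure roster laid out around a central tumor.
#' @param prescriptions named numeric vector of prescribed doses (GyRBE),
#'   one entry per CTV-role structure.
#' @param placement `"fixed"` (use the configured centers) or `"random"`
#'   (draw centers uniformly inside the grid, seeded by `generate_phantom`).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 1L),
                           spacing = c(2, 2, 2),
                           structures = default_structures(),
                           prescriptions = c(CTV1 = 70, CTV2 = 59.85, CTV3 = 53.90),
                           placement = c("fixed", "random")) {
  placement <- match.arg(placement)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0))
  roster <- structure_roster()
  if (!all(structures$name %in% roster$name))
    stop("unknown structure name(s): ",
         paste(setdiff(structures$name, roster$name), collapse = ", "))
  ctvs <- structures$name[structures$role != "OAR"]
  if (!"CTV1" %in% ctvs)
    stop("configuration must include CTV1")
  if (!all(ctvs %in% names(prescriptions)))
    stop("prescription missing for: ",
         paste(setdiff(ctvs, names(prescriptions)), collapse = ", "))
  pres <- prescriptions[intersect(c("CTV1", "CTV2", "CTV3"), ctvs)]
  if (any(diff(pres) > 1e-9))
    stop("prescriptions must be non-increasing CTV1 >= CTV2 >= CTV3")
  out <- list(grid_shape = grid_shape, spacing = as.numeric(spacing),
              structures = structures, prescriptions = prescriptions,
              placement = placement)
  class(out) <- "phantom_config"
  out
}

#' Default structure layout
#'
#' Spherical stand-ins for the 15-structure head-and-neck roster on a
#' 128 x 128 mm axial field of view: a central primary target, a larger
#' overlapping secondary target, a smaller tertiary target, and twelve OARs
#' placed at anatomically motivated bearings (midline brainstem/cord behind
#' the target, bilateral parotids/cochleae/submandibular glands, midline
#' larynx/pharynx/esophagus in front, mandible between target and larynx).
#'
#' @return data.frame of structure placements (mm) and radii (mm).
#' @export
default_structures <- function() {
  data.frame(
    name   = c("CTV1", "CTV2", "CTV3",
               "BRS", "SC", "MAN", "LAR", "PHY", "PARL", "PARR",
               "COCHL", "COCHR", "SMGL", "SMGR", "ESO"),
    role   = c("CTV1", "CTV2", "CTV3", rep("OAR", 12)),
    x      = c(64, 60, 86, 64, 64, 64, 64, 64, 30, 98, 26, 102, 42, 86, 64),
    y      = c(64, 68, 52, 22, 10, 44, 94, 80, 60, 60, 30, 30, 88, 92, 110),
    z      = rep(0, 15),
    radius = c(14, 20, 9, 8, 4, 7, 7, 6, 8, 8, 3, 3, 6, 6, 5),
    stringsAsFactors = FALSE
  )
}

voxel_centers_axis <- function(n, sp) (seq_len(n) - 0.5) * sp

#' Generate a synthetic phantom anatomy
#'
#' Builds binary voxel masks for every configured structure, the stand-in for
#' a contoured planning CT. Deterministic for a given `(config, seed)` pair.
#'
#' @param config a [phantom_config()].
#' @param seed integer; fixes random placement (unused but still honored for
#'   fixed placement, so the call is always reproducible).
#' @return An object of class `phantom` with fields `grid_shape`, `spacing`,
#'   `voxel_volume` (cc), `masks` (named list of logical arrays),
#'   `structure_roles`, and `prescriptions`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  sp <- config$spacing
  extent <- gs * sp
  st <- config$structures

  if (any(2 * st$radius > min(extent[gs > 1L])))
    stop("grid too small to contain structure(s): ",
         paste(st$name[2 * st$radius > min(extent[gs > 1L])], collapse = ", "))

  if (config$placement == "random") {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    for (i in seq_len(nrow(st))) {
      r <- st$radius[i]
      cen <- vapply(1:3, function(a) {
        if (gs[a] == 1L) return(extent[a] / 2)
        stats::runif(1, min = r, max = extent[a] - r)
      }, numeric(1))
      st$x[i] <- cen[1]; st$y[i] <- cen[2]; st$z[i] <- cen[3]
    }
  }

  cx <- voxel_centers_axis(gs[1], sp[1])
  cy <- voxel_centers_axis(gs[2], sp[2])
  cz <- voxel_centers_axis(gs[3], sp[3])

  masks <- vector("list", nrow(st))
  names(masks) <- st$name
  for (i in seq_len(nrow(st))) {
    dx2 <- (cx - st$x[i])^2
    dy2 <- (cy - st$y[i])^2
    # singleton axes are treated as in-plane: no distance penalty
    dz2 <- if (gs[3] == 1L) rep(0, gs[3]) else (cz - st$z[i])^2
    m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= st$radius[i]^2
    dim(m) <- gs
    if (!any(m))
      stop("structure ", st$name[i], " produced an empty mask; ",
           "check its placement against the grid")
    masks[[i]] <- m
  }

  roles <- st$role
  names(roles) <- st$name
  out <- list(grid_shape = gs, spacing = sp,
              voxel_volume = prod(sp) / 1000,
              masks = masks, structure_roles = roles,
              prescriptions = config$prescriptions[names(config$prescriptions) %in%
                                                     st$name[st$role != "OAR"]])
  class(out) <- "phantom"
  out
}

# Save/restore the global RNG state around a seeded block.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

ctv_names <- function(geom) names(geom$structure_roles)[geom$structure_roles != "OAR"]
oar_names <- function(geom) names(geom$structure_roles)[geom$structure_roles == "OAR"]

# Offsets (voxels) of a discrete ball with per-axis radii; singleton axes get
# radius 0 so planar grids erode/dilate in-plane only.
ball_offsets <- function(radii) {
  rx <- radii[1]; ry <- radii[2]; rz <- radii[3]
  g <- expand.grid(dx = -rx:rx, dy = -ry:ry, dz = -rz:rz)
  keep <- (g$dx / max(rx, 1))^2 + (g$dy / max(ry, 1))^2 + (g$dz / max(rz, 1))^2 <= 1
  g[keep, , drop = FALSE]
}

shift_mask <- function(mask, d) {
  gs <- dim(mask)
  out <- array(FALSE, gs)
  sx <- seq_len(gs[1]); sy <- seq_len(gs[2]); sz <- seq_len(gs[3])
  fx <- sx + d[1]; fy <- sy + d[2]; fz <- sz + d[3]
  okx <- fx >= 1 & fx <= gs[1]; oky <- fy >= 1 & fy <= gs[2]; okz <- fz >= 1 & fz <= gs[3]
  out[fx[okx], fy[oky], fz[okz]] <- mask[sx[okx], sy[oky], sz[okz]]
  out
}

dilate_mask <- function(mask, radii) {
  off <- ball_offsets(radii)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, c(off$dx[i], off$dy[i], off$dz[i]))
  out
}

erode_mask <- function(mask, radii) {
  off <- ball_offsets(radii)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(off))) {
    # voxel survives iff every ball neighbour is inside the mask; neighbours
    # falling off the grid count as outside (masks are compact, never touch edges)
    sh <- shift_mask(mask, c(-off$dx[i], -off$dy[i], -off$dz[i]))
    out <- out & sh
  }
  out
}

#' Simulate anatomical change by margin expansion or contraction
#'
#' Emulates tumor progression (CTV contours morphologically dilated) or
#' regression (eroded) by a physical margin, the way augmented training
#' anatomies are produced from a baseline planning anatomy. OAR masks are
#' left untouched. The structuring element is a discrete ball with per-axis
#' voxel radius `round(margin / spacing)`.
#'
#' @param geom a `phantom`.
#' @param mode `"progression"` (dilate, default margin 2 mm) or
#'   `"regression"` (erode, default margin 3 mm).
#' @param margin positive margin in mm; defaults depend on `mode`.
#' @param margin_mm optional per-axis numeric triple overriding `margin`
#'   for anisotropic change (used e.g. for replan-anatomy stand-ins).
#' @return A new `phantom`; the input is not modified.
#' @export
augment_anatomy <- function(geom, mode = c("progression", "regression"),
                            margin = NULL, margin_mm = NULL) {
  stopifnot(inherits(geom, "phantom"))
  mode <- match.arg(mode)
  if (is.null(margin)) margin <- if (mode == "progression") 2 else 3
  if (is.null(margin_mm)) margin_mm <- rep(margin, 3)
  stopifnot(all(margin_mm >= 0), any(margin_mm > 0))
  radii <- round(margin_mm / geom$spacing)
  radii[geom$grid_shape == 1L] <- 0
  out <- geom
  for (nm in ctv_names(geom)) {
    m <- if (mode == "progression") dilate_mask(geom$masks[[nm]], radii)
         else erode_mask(geom$masks[[nm]], radii)
    if (!any(m))
      stop("regression margin erodes ", nm, " to an empty mask")
    out$masks[[nm]] <- m
  }
  out
}

#' Shift a single structure mask
#'
#' Rigidly translates one structure by a physical offset (rounded to whole
#' voxels). Used to construct evaluation ("replan") anatomies whose changes
#' differ from the training augmentations.
#'
#' @param geom a `phantom`; @param structure structure name;
#' @param shift_mm numeric triple, mm along each axis.
#' @return A new `phantom`.
#' @export
shift_structure <- function(geom, structure, shift_mm) {
  stopifnot(inherits(geom, "phantom"), structure %in% names(geom$masks))
  d <- round(shift_mm / geom$spacing)
  d[geom$grid_shape == 1L] <- 0
  m <- shift_mask(geom$masks[[structure]], d)
  if (!any(m)) stop("shift moves ", structure, " entirely off the grid")
  geom$masks[[structure]] <- m
  geom
}

#' @export
print.phantom <- function(x, ...) {
  nv <- vapply(x$masks, sum, numeric(1))
  cat("Synthetic phantom anatomy\n")
  cat(sprintf("  grid: %s voxels at %s mm (%.4f cc/voxel)\n",
              paste(x$grid_shape, collapse = " x "),
              paste(format(x$spacing), collapse = " x "), x$voxel_volume))
  cat(sprintf("  structures: %d (%d targets, %d OARs)\n", length(x$masks),
              length(ctv_names(x)), length(oar_names(x))))
  for (nm in names(x$masks)) {
    rx <- if (nm %in% names(x$prescriptions))
      sprintf("  Rx %.2f GyRBE", x$prescriptions[[nm]]) else ""
    cat(sprintf("    %-6s %-4s %5d voxels (%.2f cc)%s\n", nm,
                x$structure_roles[[nm]], nv[[nm]], nv[[nm]] * x$voxel_volume, rx))
  }
  invisible(x)
}
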