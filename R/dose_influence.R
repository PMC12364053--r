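#' Beam configuration
#'
#' Parallel-ray pencil-beam arrangement used to build the dose-influence
#' matrix: a set of coplanar gantry angles, each carrying a row of beamlets
#' offset laterally about the isocenter (grid center). Each beamlet deposits
#' a Bragg-like depth dose along its ray with Gaussian lateral falloff.
#'
#' @param gantry_angles beam directions in degrees (0 = +x axis).
#' @param beamlets_per_beam lateral spot positions per gantry angle.
#' @param beamlet_spacing lateral spacing between adjacent spots, mm.
#' @param lateral_sigma Gaussian lateral falloff sigma, mm.
#' @param range depths of the Bragg peak from the grid entry plane, mm; a
#'   vector gives one energy layer per entry, so each gantry angle carries
#'   `beamlets_per_beam * length(range)` beamlets (lateral spots x layers),
#'   the spot-scanning degrees of freedom of IMPT.
#' @param entrance entrance-plateau dose as a fraction of the peak.
#' @param peak_sigma proximal Gaussian width of the peak, mm.
#' @param distal_sigma distal falloff width, mm (smaller = sharper distal edge).
#' @param dose_cutoff per-column fraction of the column maximum below which
#'   contributions are zeroed before sparse storage; in `[0, 1)`.
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(gantry_angles = c(0, 72, 144, 216, 288),
                        beamlets_per_beam = 13L,
                        beamlet_spacing = 4,
                        lateral_sigma = 3,
                        range = seq(36, 92, by = 7),
                        entrance = 0.35,
                        peak_sigma = 5,
                        distal_sigma = 2,
                        dose_cutoff = 0.005) {
  stopifnot(length(gantry_angles) >= 1, beamlets_per_beam >= 1,
            lateral_sigma > 0, beamlet_spacing > 0, all(range > 0),
            entrance >= 0, entrance < 1, peak_sigma > 0, distal_sigma > 0,
            dose_cutoff >= 0, dose_cutoff < 1)
  out <- list(gantry_angles = as.numeric(gantry_angles),
              beamlets_per_beam = as.integer(beamlets_per_beam),
              beamlet_spacing = beamlet_spacing,
              lateral_sigma = lateral_sigma,
              range = range, entrance = entrance,
              peak_sigma = peak_sigma, distal_sigma = distal_sigma,
              dose_cutoff = dose_cutoff)
  class(out) <- "beam_config"
  out
}

#' Bragg-like depth-dose profile
#'
#' A parameterized pristine-Bragg-curve stand-in: a low entrance plateau
#' rising to a Gaussian peak of unit height at `range`, with a sharper
#' Gaussian distal falloff beyond it. Smooth, nonnegative, and peaked at
#' depth = `range` whenever `entrance < 1`.
#'
#' @param depth depth(s) from the entry plane, mm.
#' @param range Bragg-peak depth, mm.
#' @param entrance entrance plateau as a fraction of the peak.
#' @param peak_sigma proximal peak width, mm.
#' @param distal_sigma distal falloff width, mm.
#' @return Relative dose value(s) in `[0, 1]`.
#' @export
bragg_curve <- function(depth, range = 64, entrance = 0.35,
                        peak_sigma = 6, distal_sigma = 2.5) {
  prox <- entrance + (1 - entrance) * exp(-(depth - range)^2 / (2 * peak_sigma^2))
  dist <- exp(-(depth - range)^2 / (2 * distal_sigma^2))
  ifelse(depth <= range, prox, dist)
}

#' Compute a sparse dose-influence matrix
#'
#' Builds the linear operator D mapping beamlet intensities to voxel doses:
#' column j holds the dose per unit intensity of beamlet j at every voxel,
#' modeled as (depth dose along the ray) x (lateral Gaussian falloff).
#' Entries below `dose_cutoff` x column maximum are zeroed and the matrix is
#' stored sparse. Beamlets whose rays miss the grid give all-zero columns
#' (kept, with a warning, so beamlet indexing is stable across anatomies).
#'
#' @param geom a `phantom`.
#' @param beams a [beam_config()].
#' @return An object of class `dose_influence`: `matrix` (dgCMatrix,
#'   voxels x beamlets), `structure_rows` (named list of flattened-grid row
#'   indices per structure), `n_beamlets`, `grid_shape`.
#' @export
compute_dose_influence <- function(geom, beams = beam_config()) {
  stopifnot(inherits(geom, "phantom"), inherits(beams, "beam_config"))
  gs <- geom$grid_shape
  sp <- geom$spacing
  extent <- gs * sp
  center <- extent / 2

  cx <- voxel_centers_axis(gs[1], sp[1])
  cy <- voxel_centers_axis(gs[2], sp[2])
  cz <- voxel_centers_axis(gs[3], sp[3])
  # flattened-grid voxel coordinates, x varying fastest (R array order)
  px <- rep(cx, times = gs[2] * gs[3])
  py <- rep(rep(cy, each = gs[1]), times = gs[3])
  pz <- rep(cz, each = gs[1] * gs[2])
  nvox <- prod(gs)

  corners <- as.matrix(expand.grid(c(0, extent[1]), c(0, extent[2]), c(0, extent[3])))

  nb <- beams$beamlets_per_beam
  offsets <- (seq_len(nb) - (nb + 1) / 2) * beams$beamlet_spacing
  layers <- beams$range
  n_beamlets <- length(beams$gantry_angles) * nb * length(layers)

  cols_i <- vector("list", n_beamlets)
  cols_x <- vector("list", n_beamlets)
  col <- 0L
  missed <- 0L
  for (ang in beams$gantry_angles) {
    th <- ang * pi / 180
    u <- c(cos(th), sin(th), 0)       # beam direction
    v <- c(-sin(th), cos(th), 0)      # in-plane lateral axis
    entry <- min(corners %*% u)       # entry plane offset along u
    depth <- px * u[1] + py * u[2] + pz * u[3] - entry
    lat0 <- (px - center[1]) * v[1] + (py - center[2]) * v[2]
    zoff <- pz - center[3]
    for (ob in offsets) {
      lat2 <- (lat0 - ob)^2 + if (gs[3] == 1L) 0 else zoff^2
      latf <- exp(-lat2 / (2 * beams$lateral_sigma^2))
      for (rg in layers) {
        col <- col + 1L
        d <- bragg_curve(depth, rg, beams$entrance,
                         beams$peak_sigma, beams$distal_sigma) * latf
        mx <- max(d)
        if (mx <= 0) { missed <- missed + 1L; next }
        keep <- which(d > beams$dose_cutoff * mx)
        cols_i[[col]] <- keep
        cols_x[[col]] <- d[keep]
      }
    }
  }
  if (missed > 0)
    warning(missed, " beamlet ray(s) miss the grid; zero columns retained")

  nnz <- lengths(cols_i)
  mat <- Matrix::sparseMatrix(
    i = unlist(cols_i),
    j = rep.int(seq_len(n_beamlets), nnz),
    x = unlist(cols_x),
    dims = c(nvox, n_beamlets)
  )

  structure_rows <- lapply(geom$masks, function(m) which(as.vector(m)))
  out <- list(matrix = mat, structure_rows = structure_rows,
              n_beamlets = n_beamlets, grid_shape = gs)
  class(out) <- "dose_influence"
  out
}

#' Per-structure view of a dose-influence matrix
#'
#' @param dinf a `dose_influence`; @param structure structure name.
#' @return The row-subset sparse matrix for that structure's voxels.
#' @export
structure_view <- function(dinf, structure) {
  stopifnot(inherits(dinf, "dose_influence"),
            structure %in% names(dinf$structure_rows))
  dinf$matrix[dinf$structure_rows[[structure]], , drop = FALSE]
}

#' @export
print.dose_influence <- function(x, ...) {
  cat("Dose-influence matrix\n")
  cat(sprintf("  %d voxels x %d beamlets, %d nonzeros (%.1f%% dense)\n",
              nrow(x$matrix), x$n_beamlets, Matrix::nnzero(x$matrix),
              100 * Matrix::nnzero(x$matrix) / prod(dim(x$matrix))))
  invisible(x)
}
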