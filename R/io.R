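# Plain-text persistence for configs, masks, dose-influence matrices and
# episode traces. Matrices use MatrixMarket; masks use run-length encoding
# over the flattened grid; everything else is JSON/YAML/CSV.

#' Read a phantom configuration from YAML or JSON
#'
#' The file mirrors [phantom_config()]: fields `grid_shape`, `spacing`,
#' `placement`, `prescriptions` (name: dose map) and `structures` (list of
#' name/role/x/y/z/radius records). Missing fields fall back to the package
#' defaults.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A `phantom_config`.
#' @export
read_phantom_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  structures <- if (is.null(cfg$structures)) default_structures()
                else as.data.frame(cfg$structures, stringsAsFactors = FALSE)
  for (col in c("x", "y", "z", "radius"))
    if (col %in% names(structures)) structures[[col]] <- as.numeric(structures[[col]])
  phantom_config(
    grid_shape = cfg$grid_shape %||% c(64L, 64L, 1L),
    spacing = cfg$spacing %||% c(2, 2, 2),
    structures = structures,
    prescriptions = unlist(cfg$prescriptions) %||%
      c(CTV1 = 70, CTV2 = 59.85, CTV3 = 53.90),
    placement = cfg$placement %||% "fixed"
  )
}

#' Write a dose-influence matrix to disk
#'
#' MatrixMarket sparse format plus a JSON sidecar holding the grid shape,
#' beamlet count and per-structure row indices.
#'
#' @param dinf a `dose_influence`; @param path basename; writes
#'   `<path>.mtx` and `<path>.json`.
#' @export
write_dose_influence <- function(dinf, path) {
  stopifnot(inherits(dinf, "dose_influence"))
  Matrix::writeMM(dinf$matrix, paste0(path, ".mtx"))
  jsonlite::write_json(
    list(grid_shape = dinf$grid_shape, n_beamlets = dinf$n_beamlets,
         structure_rows = dinf$structure_rows),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a dose-influence matrix written by [write_dose_influence()]
#' @param path the basename used at write time.
#' @return A `dose_influence`.
#' @export
read_dose_influence <- function(path) {
  mat <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  out <- list(matrix = mat,
              structure_rows = lapply(meta$structure_rows, as.integer),
              n_beamlets = as.integer(meta$n_beamlets),
              grid_shape = as.integer(meta$grid_shape))
  class(out) <- "dose_influence"
  out
}

# Run-length encode a logical vector: (lengths, starting value FALSE).
rle_encode <- function(v) {
  r <- rle(as.logical(v))
  if (length(r$lengths) == 0) return(integer(0))
  if (r$values[1]) c(0L, r$lengths) else r$lengths
}

rle_decode <- function(lengths, n) {
  vals <- rep(c(FALSE, TRUE), length.out = length(lengths))
  out <- rep(vals, times = lengths)
  length(out) <- n
  out[is.na(out)] <- FALSE
  out
}

#' Persist phantom masks as run-length-encoded text
#'
#' Writes `<path>.json`: a manifest with grid shape, spacing, roles,
#' prescriptions, and per-structure run-length encodings of the flattened
#' masks. Plain text, compact, lossless.
#'
#' @param geom a `phantom`; @param path basename.
#' @export
write_masks <- function(geom, path) {
  stopifnot(inherits(geom, "phantom"))
  enc <- lapply(geom$masks, function(m) rle_encode(as.vector(m)))
  jsonlite::write_json(
    list(grid_shape = geom$grid_shape, spacing = geom$spacing,
         structure_roles = as.list(geom$structure_roles),
         prescriptions = as.list(geom$prescriptions),
         masks_rle = enc),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a phantom written by [write_masks()]
#' @param path the basename used at write time.
#' @return A `phantom`.
#' @export
read_masks <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  gs <- as.integer(meta$grid_shape)
  masks <- lapply(meta$masks_rle, function(lens) {
    m <- rle_decode(as.integer(lens), prod(gs))
    dim(m) <- gs
    m
  })
  out <- list(grid_shape = gs, spacing = as.numeric(meta$spacing),
              voxel_volume = prod(as.numeric(meta$spacing)) / 1000,
              masks = masks,
              structure_roles = unlist(meta$structure_roles),
              prescriptions = unlist(meta$prescriptions))
  class(out) <- "phantom"
  out
}

#' Write an episode trace to CSV
#' @param env a `planning_env` after an episode; @param path output file.
#' @export
write_episode_trace <- function(env, path) {
  utils::write.csv(episode_trace(env), path, row.names = FALSE)
  invisible(path)
}

#' Write a clinical-goal table to YAML
#' @param goals a [clinical_goals()] table; @param path output `.yaml` file.
#' @export
write_goals <- function(goals, path) {
  yaml::write_yaml(lapply(seq_len(nrow(goals)), function(i) as.list(goals[i, ])),
                   path)
  invisible(path)
}

#' Read a clinical-goal table from YAML or JSON
#' @param path file written by [write_goals()] (or hand-authored with the
#'   same fields).
#' @return A `clinical_goals` data.frame.
#' @export
read_goals <- function(path) {
  rows <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = FALSE)
  g <- do.call(rbind, lapply(rows, function(r)
    data.frame(structure = r$structure, metric = r$metric,
               param = if (is.null(r$param) || is.na(r$param)) NA_real_ else r$param,
               goal = r$goal, direction = r$direction,
               max_points = r$max_points, label = r$label,
               zero_level = r$zero_level, stringsAsFactors = FALSE)))
  class(g) <- c("clinical_goals", "data.frame")
  g
}
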