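#' Default clinical-goal table (150-point allocation)
#'
#' The head-and-neck planning objectives used for plan scoring: coverage
#' goals V_dRx >= 98% for each target, a CTV1 hot-spot goal D0% <= 110% of
#' prescription, and twelve OAR limits (near-maximum dose D0.03cc for
#' brainstem and spinal cord, V70 volume limit for the mandible, mean-dose
#' limits elsewhere). Points: 15 per target objective (4 objectives) and 7.5
#' per OAR objective (12 objectives), summing to 150. The zero-score level
#' of each piecewise-linear scoring ramp defaults to goal x (1 + beta) for
#' upper limits and goal - delta percentage points for coverage.
#'
#' @param prescriptions named numeric vector of target prescriptions (GyRBE).
#' @param beta relative overshoot at which an upper-limit goal scores zero.
#' @param delta coverage shortfall (percentage points) at which a coverage
#'   goal scores zero.
#' @param ctv_points,oar_points maximum points per target / OAR objective.
#' @return data.frame of class `clinical_goals`, one row per objective, with
#'   columns `structure`, `metric` (`"Vd"`, `"Dcc"`, `"Dpct"`, `"Dmean"`),
#'   `param` (dose for Vd, volume in cc for Dcc, volume percent for Dpct),
#'   `goal` (the limit, % volume or GyRBE), `direction`, `max_points`,
#'   `zero_level`, and `label`.
#' @export
clinical_goals <- function(prescriptions = c(CTV1 = 70, CTV2 = 59.85, CTV3 = 53.90),
                           beta = 0.25, delta = 5,
                           ctv_points = 15, oar_points = 7.5) {
  rxn <- names(prescriptions)
  rows <- list()
  add <- function(structure, metric, param, goal, direction, max_points, label) {
    rows[[length(rows) + 1]] <<- data.frame(
      structure = structure, metric = metric, param = param, goal = goal,
      direction = direction, max_points = max_points, label = label,
      stringsAsFactors = FALSE)
  }
  for (s in intersect(c("CTV1", "CTV2", "CTV3"), rxn)) {
    rx <- prescriptions[[s]]
    add(s, "Vd", rx, 98, "at_least", ctv_points,
        sprintf("V%.2f >= 98%%", rx))
  }
  if ("CTV1" %in% rxn)
    add("CTV1", "Dpct", 0, 1.10 * prescriptions[["CTV1"]], "at_most", ctv_points,
        sprintf("D0%% <= %.1f GyRBE", 1.10 * prescriptions[["CTV1"]]))
  add("BRS",   "Dcc",   0.03, 30, "at_most", oar_points, "D0.03cc <= 30 GyRBE")
  add("SC",    "Dcc",   0.03, 30, "at_most", oar_points, "D0.03cc <= 30 GyRBE")
  add("MAN",   "Vd",    70,   10, "at_most", oar_points, "V70 <= 10%")
  add("LAR",   "Dmean", NA,   45, "at_most", oar_points, "Dmean <= 45 GyRBE")
  add("PHY",   "Dmean", NA,   50, "at_most", oar_points, "Dmean <= 50 GyRBE")
  add("PARL",  "Dmean", NA,   26, "at_most", oar_points, "Dmean <= 26 GyRBE")
  add("PARR",  "Dmean", NA,   26, "at_most", oar_points, "Dmean <= 26 GyRBE")
  add("COCHL", "Dmean", NA,   35, "at_most", oar_points, "Dmean <= 35 GyRBE")
  add("COCHR", "Dmean", NA,   35, "at_most", oar_points, "Dmean <= 35 GyRBE")
  add("SMGL",  "Dmean", NA,   35, "at_most", oar_points, "Dmean <= 35 GyRBE")
  add("SMGR",  "Dmean", NA,   35, "at_most", oar_points, "Dmean <= 35 GyRBE")
  add("ESO",   "Dmean", NA,   40, "at_most", oar_points, "Dmean <= 40 GyRBE")
  g <- do.call(rbind, rows)
  g$zero_level <- ifelse(g$direction == "at_most", g$goal * (1 + beta),
                         g$goal - delta)
  class(g) <- c("clinical_goals", "data.frame")
  g
}

#' Compute a cumulative dose-volume histogram
#'
#' Row s, bin b holds the fraction of structure s's voxels receiving at
#' least `dose_axis[b]` GyRBE. This M x N matrix, flattened, is the state
#' observed by the RL agents.
#'
#' @param dose a `dose_distribution` (or numeric vector over the grid).
#' @param geom a `phantom`.
#' @param n_bins number of dose bins (>= 2); default 100.
#' @param dose_max top of the dose axis; default 1.2 x the highest
#'   prescription.
#' @return Object of class `dvh_state`: `matrix` (structures x bins,
#'   values in `[0, 1]`), `dose_axis` (bin edges, GyRBE),
#'   `structure_order`, `empty` (logical per structure; empty masks give
#'   all-zero rows).
#' @export
compute_dvh <- function(dose, geom, n_bins = 100L, dose_max = NULL) {
  stopifnot(inherits(geom, "phantom"), n_bins >= 2)
  if (is.null(dose_max)) dose_max <- 1.2 * max(geom$prescriptions)
  stopifnot(dose_max > 0)
  d <- as.numeric(dose)
  axis <- seq(0, dose_max, length.out = n_bins)
  sn <- names(geom$masks)
  m <- matrix(0, nrow = length(sn), ncol = n_bins,
              dimnames = list(sn, NULL))
  empty <- logical(length(sn)); names(empty) <- sn
  for (i in seq_along(sn)) {
    idx <- which(as.vector(geom$masks[[sn[i]]]))
    if (length(idx) == 0L) { empty[i] <- TRUE; next }
    ds <- sort(d[idx])
    n <- length(ds)
    # fraction with dose >= t, via binary search on the sorted doses
    m[i, ] <- (n - findInterval(axis, ds, left.open = TRUE)) / n
  }
  out <- list(matrix = m, dose_axis = axis, structure_order = sn, empty = empty)
  class(out) <- "dvh_state"
  out
}

#' @export
print.dvh_state <- function(x, ...) {
  cat(sprintf("DVH state: %d structures x %d dose bins (0 to %.1f GyRBE)\n",
              nrow(x$matrix), ncol(x$matrix), max(x$dose_axis)))
  invisible(x)
}

#' Plot DVH curves
#' @param x a `dvh_state`; @param structures subset to draw (default all);
#' @param lty,col usual graphics overrides; @param ... passed to `matplot`.
#' @export
plot.dvh_state <- function(x, structures = x$structure_order,
                           lty = 1, col = NULL, ...) {
  m <- t(x$matrix[structures, , drop = FALSE]) * 100
  if (is.null(col)) col <- grDevices::hcl.colors(length(structures), "Dark 3")
  graphics::matplot(x$dose_axis, m, type = "l", lty = lty, col = col,
                    xlab = "Dose [GyRBE]", ylab = "Volume [%]", ylim = c(0, 100), ...)
  graphics::legend("topright", legend = structures, col = col, lty = lty, cex = 0.6)
  invisible(x)
}

#' Evaluate one dosimetric metric
#'
#' Supported metrics: `Vd` (percent of the structure receiving at least
#' `param` GyRBE), `Dcc` (minimum dose of the hottest `param` cc, i.e. the
#' descending-sorted dose at rank `ceil(param / voxel_volume)`), `Dpct`
#' (minimum dose of the hottest `param` percent of the volume; `D0%` is the
#' structure maximum), and `Dmean` (arithmetic mean).
#'
#' @param dose a `dose_distribution`; @param geom a `phantom`;
#' @param goal one row of a [clinical_goals()] table (or a list with
#'   `structure`, `metric`, `param`).
#' @return Scalar metric value (percent volume for `Vd`, GyRBE otherwise).
#' @export
metric_value <- function(dose, geom, goal) {
  s <- goal$structure
  idx <- which(as.vector(geom$masks[[s]]))
  if (length(idx) == 0L) stop("structure ", s, " is empty")
  ds <- as.numeric(dose)[idx]
  switch(goal$metric,
    Vd    = 100 * mean(ds >= goal$param),
    Dcc   = {
      rank <- min(length(ds), max(1L, ceiling(goal$param / geom$voxel_volume)))
      sort(ds, decreasing = TRUE)[rank]
    },
    Dpct  = {
      if (goal$param <= 0) max(ds)
      else {
        rank <- min(length(ds), max(1L, ceiling(goal$param / 100 * length(ds))))
        sort(ds, decreasing = TRUE)[rank]
      }
    },
    Dmean = mean(ds),
    stop("unknown metric: ", goal$metric)
  )
}

#' Score one clinical goal
#'
#' Piecewise-linear scoring ramp: full points when the goal is met or
#' bettered, zero at or beyond the zero-score level, linear in between, and
#' monotone in the clinically favorable direction.
#'
#' @param value metric value in the goal's units.
#' @param goal one row of a [clinical_goals()] table.
#' @return Awarded points in `[0, max_points]`.
#' @export
score_goal <- function(value, goal) {
  g <- goal$goal; z <- goal$zero_level; mp <- goal$max_points
  if (goal$direction == "at_most") {
    if (z <= g) stop("zero-score level must exceed the goal for at_most metrics")
    if (value <= g) return(mp)
    if (value >= z) return(0)
    mp * (z - value) / (z - g)
  } else {
    if (z >= g) stop("zero-score level must lie below the goal for at_least metrics")
    if (value >= g) return(mp)
    if (value <= z) return(0)
    mp * (value - z) / (g - z)
  }
}

#' Score a treatment plan
#'
#' Evaluates every clinical goal on the dose distribution and sums the
#' per-goal points into the total plan-quality score (0-150 under the
#' default goal table). The per-step change of this score is the RL reward.
#'
#' @param dose a `dose_distribution`; @param geom a `phantom`;
#' @param goals a [clinical_goals()] table.
#' @return Object of class `plan_score`: `per_goal` (data.frame with
#'   structure, label, value, points, max_points) and `total`.
#' @export
score_plan <- function(dose, geom, goals = clinical_goals(geom$prescriptions)) {
  vals <- numeric(nrow(goals))
  pts <- numeric(nrow(goals))
  for (i in seq_len(nrow(goals))) {
    vals[i] <- metric_value(dose, geom, goals[i, ])
    pts[i] <- score_goal(vals[i], goals[i, ])
  }
  out <- list(per_goal = data.frame(structure = goals$structure,
                                    label = goals$label,
                                    value = vals, points = pts,
                                    max_points = goals$max_points,
                                    stringsAsFactors = FALSE),
              total = sum(pts))
  class(out) <- "plan_score"
  out
}

#' @export
print.plan_score <- function(x, digits = 2, ...) {
  cat(sprintf("Plan quality score: %.2f / %.1f\n", x$total, sum(x$per_goal$max_points)))
  df <- x$per_goal
  df$value <- round(df$value, digits)
  df$points <- round(df$points, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mean dose recovered from a DVH row (trapezoidal)
#'
#' Integrates a cumulative DVH row over the dose axis, the standard identity
#' `Dmean = integral of V(d) dd`. Used as an internal consistency check
#' against the voxelwise mean (agreement within one bin width).
#'
#' @param dvh a `dvh_state`; @param structure structure name.
#' @return Approximate mean dose, GyRBE.
#' @export
dvh_mean_dose <- function(dvh, structure) {
  v <- dvh$matrix[structure, ]
  x <- dvh$dose_axis
  sum(diff(x) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}
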