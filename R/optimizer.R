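#' Default treatment-planning priorities
#'
#' One weight per rostered structure: the treatment-planning priorities
#' (TPPs) that balance target coverage against OAR sparing in the weighted
#' planning loss. Weights live in `[0, 1]`; the environment's actions move
#' them in clipped increments.
#'
#' @param geom a `phantom`.
#' @param ctv,oar initial weight for target / OAR structures.
#' @return Named numeric vector over the phantom's structures.
#' @export
default_priorities <- function(geom, ctv = 0.8, oar = 0.2) {
  w <- ifelse(geom$structure_roles == "OAR", oar, ctv)
  names(w) <- names(geom$structure_roles)
  w
}

#' Optimizer settings
#'
#' @param max_iterations iteration cap for projected gradient descent.
#' @param relative_tolerance stop when the relative objective decrease over
#'   one iteration falls below this.
#' @param step_rule `"fixed_lipschitz"` (step 1/L, L from power iteration on
#'   the weighted normal operator) or `"backtracking"` (Armijo halving).
#' @param warm_start start re-optimizations from the previous fluence.
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(max_iterations = 200L,
                               relative_tolerance = 1e-5,
                               step_rule = c("fixed_lipschitz", "backtracking"),
                               warm_start = TRUE) {
  step_rule <- match.arg(step_rule)
  stopifnot(max_iterations >= 1, relative_tolerance > 0)
  out <- list(max_iterations = as.integer(max_iterations),
              relative_tolerance = relative_tolerance,
              step_rule = step_rule, warm_start = isTRUE(warm_start))
  class(out) <- "optimizer_settings"
  out
}

# Aggregate the structure-indexed quadratic into per-voxel coefficients:
# sum_s w_s ||D_s x - t_s||^2 = sum_i wv_i d_i^2 - 2 sum_i tgt_i d_i + const,
# with d = D x. Voxels in several structures accumulate every membership.
voxel_weights <- function(dinf, w, rx) {
  nvox <- nrow(dinf$matrix)
  wv <- numeric(nvox)
  tgt <- numeric(nvox)
  const <- 0
  for (s in names(dinf$structure_rows)) {
    ws <- w[[s]]
    if (is.null(ws) || ws == 0) next
    rows <- dinf$structure_rows[[s]]
    wv[rows] <- wv[rows] + ws
    if (s %in% names(rx)) {
      t_s <- rx[[s]]
      tgt[rows] <- tgt[rows] + ws * t_s
      const <- const + ws * length(rows) * t_s^2
    }
  }
  list(wv = wv, tgt = tgt, const = const)
}

#' Weighted multi-objective planning loss
#'
#' The quadratic inverse-planning objective: for each target m,
#' `w_m * ||D_m x - dRx_m||^2` (squared deviation from the uniform
#' prescription over target voxels), plus `w_k * ||D_k x||^2` for each OAR k.
#' Always nonnegative. Voxels belonging to several structures contribute to
#' every term they index.
#'
#' @param x nonnegative fluence (beamlet-intensity) vector.
#' @param dinf a `dose_influence`.
#' @param w named priority vector (see [default_priorities()]).
#' @param rx named prescriptions (GyRBE), one per target structure.
#' @return Scalar objective value.
#' @export
plan_objective <- function(x, dinf, w, rx) {
  stopifnot(length(x) == dinf$n_beamlets)
  d <- as.numeric(dinf$matrix %*% x)
  obj <- 0
  for (s in names(dinf$structure_rows)) {
    ws <- w[[s]]
    if (is.null(ws) || ws == 0) next
    ds <- d[dinf$structure_rows[[s]]]
    t_s <- if (s %in% names(rx)) rx[[s]] else 0
    obj <- obj + ws * sum((ds - t_s)^2)
  }
  obj
}

#' Map fluence to dose
#'
#' The elementary dose model: voxel dose is the dose-influence matrix applied
#' to the beamlet intensities, `d = D x`.
#'
#' @param dinf a `dose_influence`; @param x nonnegative fluence vector.
#' @return Numeric vector of per-voxel dose (GyRBE), class `dose_distribution`
#'   with the grid shape attached.
#' @export
compute_dose <- function(dinf, x) {
  stopifnot(length(x) == dinf$n_beamlets)
  d <- as.numeric(dinf$matrix %*% x)
  attr(d, "grid_shape") <- dinf$grid_shape
  class(d) <- "dose_distribution"
  d
}

#' Dose within one structure
#' @param dose a `dose_distribution`; @param dinf the `dose_influence` (or a
#'   `phantom`) carrying structure voxel indices; @param structure name.
#' @return Numeric vector of that structure's voxel doses.
#' @export
structure_dose <- function(dose, dinf, structure) {
  rows <- if (inherits(dinf, "phantom")) which(as.vector(dinf$masks[[structure]]))
          else dinf$structure_rows[[structure]]
  if (is.null(rows)) stop("unknown structure: ", structure)
  as.numeric(dose)[rows]
}

# Largest eigenvalue of t(D) diag(wv) D by power iteration (deterministic start).
normal_operator_lmax <- function(D, wv, iters = 30L) {
  n <- ncol(D)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (k in seq_len(iters)) {
    u <- as.numeric(D %*% v)
    z <- as.numeric(Matrix::crossprod(D, wv * u))
    nz <- sqrt(sum(z^2))
    if (nz == 0) return(0)
    lam <- nz
    v <- z / nz
  }
  lam
}

#' Optimize a treatment plan by projected gradient descent
#'
#' Minimizes the weighted planning loss over nonnegative fluence by
#' iterating `x <- pmax(x - eta * grad, 0)`. The default step is `1/L` with
#' `L` the Lipschitz constant of the gradient estimated by power iteration;
#' a monotonicity safeguard halves the step if an iteration fails to
#' decrease the objective, so the objective sequence is non-increasing under
#' either step rule.
#'
#' @param dinf a `dose_influence`.
#' @param w named priority vector.
#' @param rx named prescriptions per target.
#' @param settings an [optimizer_settings()].
#' @param x0 starting fluence (nonnegative); zeros if `NULL`.
#' @return list with `x` (optimal fluence), `report` (iterations,
#'   initial/final objective, converged flag, step size, and `trace`, the
#'   objective value after every accepted iteration).
#' @export
optimize_plan <- function(dinf, w, rx, settings = optimizer_settings(),
                          x0 = NULL) {
  n <- dinf$n_beamlets
  if (is.null(x0)) x0 <- numeric(n)
  stopifnot(length(x0) == n, all(x0 >= 0))
  agg <- voxel_weights(dinf, w, rx)
  D <- dinf$matrix

  obj_of <- function(d) sum(agg$wv * d^2) - 2 * sum(agg$tgt * d) + agg$const
  grad_of <- function(d) 2 * as.numeric(Matrix::crossprod(D, agg$wv * d - agg$tgt))

  x <- x0
  d <- as.numeric(D %*% x)
  f <- obj_of(d)
  f0 <- f
  if (!is.finite(f)) stop("non-finite objective at iteration 0")

  if (all(agg$wv == 0)) {
    return(list(x = x, report = list(iterations = 0L, initial_objective = f0,
                                     final_objective = f, converged = TRUE,
                                     step = NA_real_, trace = f0)))
  }

  L <- 2 * normal_operator_lmax(D, agg$wv)
  eta <- if (L > 0) 1 / L else 1
  it <- 0L
  converged <- FALSE
  trace <- numeric(settings$max_iterations + 1L)
  trace[1] <- f0
  for (it in seq_len(settings$max_iterations)) {
    g <- grad_of(d)
    if (any(!is.finite(g)))
      stop("non-finite gradient at iteration ", it)
    if (settings$step_rule == "backtracking") {
      step <- if (L > 0) 2 / L else 1
      repeat {
        xn <- pmax(x - step * g, 0)
        dn <- as.numeric(D %*% xn)
        fn <- obj_of(dn)
        dx <- xn - x
        if (fn <= f + sum(g * dx) + sum(dx^2) / (2 * step) + 1e-12 || step < 1e-16)
          break
        step <- step / 2
      }
    } else {
      step <- eta
      repeat {
        xn <- pmax(x - step * g, 0)
        dn <- as.numeric(D %*% xn)
        fn <- obj_of(dn)
        if (fn <= f + 1e-12 * max(1, abs(f)) || step < 1e-16) break
        step <- step / 2   # safeguard: enforce monotone descent
      }
    }
    if (!is.finite(fn)) stop("non-finite objective at iteration ", it)
    rel <- abs(f - fn) / max(abs(f), .Machine$double.eps)
    x <- xn; d <- dn; f <- fn
    trace[it + 1L] <- f
    if (rel < settings$relative_tolerance) { converged <- TRUE; break }
  }
  list(x = x,
       report = list(iterations = it, initial_objective = f0,
                     final_objective = f, converged = converged, step = eta,
                     trace = trace[seq_len(it + 1L)]))
}
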