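# Shared fixtures (computed once per test file) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function() {
  if (is.null(.fixtures$geom))
    .fixtures$geom <- generate_phantom(phantom_config(), seed = 7)
  .fixtures$geom
}

fixture_dinf <- function() {
  if (is.null(.fixtures$dinf))
    .fixtures$dinf <- compute_dose_influence(fixture_phantom(), beam_config())
  .fixtures$dinf
}

fixture_env <- function(...) {
  planning_env(fixture_phantom(), fixture_dinf(), ...)
}

# A phantom whose structures are pairwise disjoint (well-separated small
# spheres on a large grid), so a dose meeting every clinical goal at once
# exists by construction.
disjoint_phantom <- function() {
  if (!is.null(.fixtures$disjoint)) return(.fixtures$disjoint)
  st <- default_structures()
  st$radius <- 3
  pos <- expand.grid(x = seq(12, 116, by = 26), y = seq(12, 116, by = 26))
  st$x <- pos$x[seq_len(nrow(st))]
  st$y <- pos$y[seq_len(nrow(st))]
  .fixtures$disjoint <- generate_phantom(phantom_config(structures = st), seed = 1)
  .fixtures$disjoint
}

# Hand-built dose-influence object from a dense matrix (voxel space is the
# rows themselves; structures index rows directly).
manual_dinf <- function(D, structure_rows) {
  out <- list(matrix = Matrix::Matrix(D, sparse = TRUE),
              structure_rows = structure_rows,
              n_beamlets = ncol(D),
              grid_shape = c(nrow(D), 1L, 1L))
  class(out) <- "dose_influence"
  out
}

# Brute-force nonnegative least-squares oracle: enumerate every active set,
# solve the free subsystem of the normal equations, keep the best feasible
# candidate. Independent of the projected-gradient path.
nnls_oracle <- function(D, wv, tgt) {
  n <- ncol(D)
  Q <- 2 * t(D) %*% (wv * D)
  cvec <- -2 * t(D) %*% tgt
  obj <- function(x) {
    d <- as.numeric(D %*% x)
    sum(wv * d^2) - 2 * sum(tgt * d)
  }
  best_x <- numeric(n)
  best_f <- obj(best_x)
  for (k in seq_len(n)) {
    for (free in utils::combn(n, k, simplify = FALSE)) {
      x <- numeric(n)
      sol <- tryCatch(solve(Q[free, free, drop = FALSE], -cvec[free]),
                      error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol)) || any(sol < 0)) next
      x[free] <- sol
      f <- obj(x)
      if (f < best_f) { best_f <- f; best_x <- x }
    }
  }
  list(x = best_x, objective = best_f)
}

# Aggregated per-voxel weights/targets for a manual problem expressed as
# structures with weights w and prescriptions rx (mirrors the objective's
# definition, used to express the oracle in the same quadratic form).
aggregate_problem <- function(dinf, w, rx) {
  nvox <- nrow(dinf$matrix)
  wv <- numeric(nvox); tgt <- numeric(nvox); const <- 0
  for (s in names(dinf$structure_rows)) {
    ws <- w[[s]]
    if (is.null(ws) || ws == 0) next
    rows <- dinf$structure_rows[[s]]
    wv[rows] <- wv[rows] + ws
    t_s <- if (s %in% names(rx)) rx[[s]] else 0
    tgt[rows] <- tgt[rows] + ws * t_s
    const <- const + ws * length(rows) * t_s^2
  }
  list(wv = wv, tgt = tgt, const = const)
}

# Direct double-sum evaluation of the generalized advantage estimate,
# independent of the recursive implementation.
gae_double_sum <- function(rewards, values, dones, gamma, lambda) {
  T_ <- length(rewards)
  delta <- numeric(T_)
  for (t in seq_len(T_)) {
    vnext <- if (dones[t]) 0 else values[t + 1]
    delta[t] <- rewards[t] + gamma * vnext - values[t]
  }
  # episode boundary after step t: advantages do not look past a done
  adv <- numeric(T_)
  for (t in seq_len(T_)) {
    acc <- 0
    for (l in 0:(T_ - t)) {
      tt <- t + l
      if (tt > T_) break
      acc <- acc + (gamma * lambda)^l * delta[tt]
      if (dones[tt]) break
    }
    adv[t] <- acc
  }
  adv
}
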