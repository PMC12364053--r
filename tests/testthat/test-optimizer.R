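test_that("objective has its closed forms at zero fluence and zero weights", {
  g <- fixture_phantom()
  di <- fixture_dinf()
  w <- default_priorities(g)
  rx <- g$prescriptions
  x0 <- numeric(di$n_beamlets)
  expected <- sum(vapply(names(rx), function(s)
    w[[s]] * sum(g$masks[[s]]) * rx[[s]]^2, numeric(1)))
  expect_equal(plan_objective(x0, di, w, rx), expected)

  wz <- w * 0
  set.seed(2)
  xr <- runif(di$n_beamlets)
  expect_identical(plan_objective(xr, di, wz, rx), 0)
  expect_gte(plan_objective(xr, di, w, rx), 0)
})

test_that("one-voxel one-beamlet problem recovers the calculus optimum", {
  cc <- 0.8
  di <- manual_dinf(matrix(cc, 1, 1), list(CTV1 = 1L))
  w <- c(CTV1 = 1)
  rx <- c(CTV1 = 60)
  res <- optimize_plan(di, w, rx, optimizer_settings(relative_tolerance = 1e-10))
  expect_equal(res$x, rx[["CTV1"]] / cc, tolerance = 1e-5)
  expect_lt(res$report$final_objective, 1e-6)
})

test_that("active constraints match the nonnegative-quadratic oracle", {
  # a problem whose unconstrained optimum has a negative component
  D <- matrix(c(1, 0.9,
                0.9, 1), 2, 2, byrow = TRUE)
  di <- manual_dinf(D, list(CTV1 = 1L, OAR1 = 2L))
  w <- c(CTV1 = 1, OAR1 = 5)
  rx <- c(CTV1 = 50)
  agg <- aggregate_problem(di, w, rx)
  unc <- solve(2 * t(D) %*% (agg$wv * D), 2 * t(D) %*% agg$tgt)
  expect_true(any(unc < 0))
  res <- optimize_plan(di, w, rx, optimizer_settings(1000, 1e-12))
  oracle <- nnls_oracle(D, agg$wv, agg$tgt)
  expect_equal(res$x[2], 0, tolerance = 1e-8)
  expect_equal(plan_objective(res$x, di, w, rx),
               oracle$objective + agg$const, tolerance = 1e-6)
})

test_that("projected gradient matches brute-force enumeration on random tiny problems", {
  set.seed(42)
  for (i in 1:30) {
    nv <- sample(2:5, 1)
    nb <- sample(1:3, 1)
    D <- matrix(runif(nv * nb), nv, nb)
    split <- sample(1:(nv - 1), 1)
    rows <- list(CTV1 = 1:split, OAR1 = (split + 1):nv)
    di <- manual_dinf(D, rows)
    w <- c(CTV1 = runif(1, 0.2, 1), OAR1 = runif(1, 0, 1))
    rx <- c(CTV1 = runif(1, 30, 70))
    res <- optimize_plan(di, w, rx, optimizer_settings(2000, 1e-12))
    agg <- aggregate_problem(di, w, rx)
    oracle <- nnls_oracle(D, agg$wv, agg$tgt)
    f_pg <- plan_objective(res$x, di, w, rx)
    f_or <- oracle$objective + agg$const
    expect_equal(f_pg, f_or, tolerance = 1e-4 * max(1, abs(f_or)),
                 label = sprintf("problem %d", i))
  }
})

test_that("objective decreases monotonically along accepted iterations", {
  di <- fixture_dinf()
  g <- fixture_phantom()
  for (rule in c("fixed_lipschitz", "backtracking")) {
    res <- optimize_plan(di, default_priorities(g), g$prescriptions,
                         optimizer_settings(60, 1e-12, step_rule = rule))
    expect_true(all(diff(res$report$trace) <= 1e-9), label = rule)
  }
})

test_that("warm starting at the optimum satisfies tolerance within one iteration", {
  set.seed(10)
  D <- matrix(runif(6 * 2, 0.5, 1), 6, 2)
  di <- manual_dinf(D, list(CTV1 = 1:4, OAR1 = 5:6))
  w <- c(CTV1 = 1, OAR1 = 0.2)
  rx <- c(CTV1 = 60)
  res <- optimize_plan(di, w, rx, optimizer_settings(5000, 1e-9))
  expect_true(res$report$converged)
  res2 <- optimize_plan(di, w, rx, optimizer_settings(5000, 1e-9), x0 = res$x)
  expect_lte(res2$report$iterations, 1L)
  expect_true(res2$report$converged)
})

test_that("raising an OAR weight does not raise its squared-dose term at the optimum", {
  set.seed(11)
  D <- matrix(runif(8 * 3), 8, 3)
  di <- manual_dinf(D, list(CTV1 = 1:4, OAR1 = 5:8))
  rx <- c(CTV1 = 60)
  oar_term <- function(w_oar) {
    w <- c(CTV1 = 1, OAR1 = w_oar)
    res <- optimize_plan(di, w, rx, optimizer_settings(5000, 1e-13))
    sum(as.numeric(D[5:8, ] %*% res$x)^2)
  }
  terms <- vapply(c(0.1, 0.5, 1, 2), oar_term, numeric(1))
  expect_true(all(diff(terms) <= 1e-6))
})

test_that("scaling all weights leaves the minimizer unchanged", {
  set.seed(12)
  D <- matrix(runif(6 * 3), 6, 3)
  di <- manual_dinf(D, list(CTV1 = 1:3, OAR1 = 4:6))
  rx <- c(CTV1 = 55)
  w <- c(CTV1 = 0.7, OAR1 = 0.3)
  r1 <- optimize_plan(di, w, rx, optimizer_settings(5000, 1e-13))
  r2 <- optimize_plan(di, 10 * w, rx, optimizer_settings(5000, 1e-13))
  expect_equal(r1$x, r2$x, tolerance = 1e-4)
  expect_equal(plan_objective(r2$x, di, 10 * w, rx),
               10 * plan_objective(r1$x, di, w, rx), tolerance = 1e-6)
})
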