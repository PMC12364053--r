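make_dose <- function(g, value = 0) {
  d <- rep(value, prod(g$grid_shape))
  class(d) <- "dose_distribution"
  d
}

# dose vector that meets every default goal on the disjoint phantom:
# each CTV uniformly at its prescription, zero elsewhere
perfect_dose <- function(g) {
  d <- numeric(prod(g$grid_shape))
  for (nm in c("CTV3", "CTV2", "CTV1"))
    d[as.vector(g$masks[[nm]])] <- g$prescriptions[[nm]]
  class(d) <- "dose_distribution"
  d
}

test_that("DVH rows are monotone, normalized, and match direct counting", {
  g <- fixture_phantom()
  set.seed(5)
  d <- make_dose(g)
  d[] <- runif(length(d), 0, 80)
  dvh <- compute_dvh(d, g)
  expect_identical(dim(dvh$matrix), c(15L, 100L))
  expect_true(all(dvh$matrix >= 0 & dvh$matrix <= 1))
  expect_true(all(apply(dvh$matrix, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(dvh$matrix[, 1] == 1))          # V(0) = 1
  # direct count oracle at arbitrary bins
  for (nm in c("CTV1", "PARR", "ESO")) {
    ds <- structure_dose(d, g, nm)
    for (b in c(1, 37, 80))
      expect_equal(unname(dvh$matrix[nm, b]), mean(ds >= dvh$dose_axis[b]))
  }
  # trapezoidal mean from the DVH agrees with the voxelwise mean
  bw <- diff(dvh$dose_axis[1:2])
  for (nm in c("CTV2", "LAR"))
    expect_lt(abs(dvh_mean_dose(dvh, nm) - mean(structure_dose(d, g, nm))), bw)
})

test_that("degenerate doses give the expected DVH limits", {
  g <- fixture_phantom()
  dvh0 <- compute_dvh(make_dose(g, 0), g)
  expect_true(all(dvh0$matrix[, 1] == 1))
  expect_true(all(dvh0$matrix[, -1] == 0))
  # uniform dose exactly at prescription: full coverage
  d <- make_dose(g, 0)
  d[as.vector(g$masks$CTV1)] <- g$prescriptions[["CTV1"]]
  goal <- clinical_goals(g$prescriptions)[1, ]
  expect_equal(metric_value(d, g, goal), 100)
})

test_that("dosimetric metrics match sort-and-rank oracles", {
  st <- default_structures()[1:3, ]
  g <- generate_phantom(phantom_config(structures = st,
                                       prescriptions = c(CTV1 = 70, CTV2 = 60, CTV3 = 50)))
  idx <- which(as.vector(g$masks$CTV3))[1:4]
  d <- make_dose(g, 0)
  d[idx] <- c(10, 20, 30, 40)
  sub <- g
  sub$masks$CTV3 <- array(FALSE, g$grid_shape)
  sub$masks$CTV3[idx] <- TRUE
  expect_equal(metric_value(d, sub, list(structure = "CTV3", metric = "Dmean")), 25)
  expect_equal(metric_value(d, sub, list(structure = "CTV3", metric = "Dpct", param = 0)), 40)
  expect_equal(metric_value(d, sub, list(structure = "CTV3", metric = "Vd", param = 25)), 50)

  # D_0.03cc with 0.008 cc voxels: rank ceil(0.03/0.008) = 4
  set.seed(9)
  big <- which(as.vector(g$masks$CTV2))
  d2 <- make_dose(g, 0)
  d2[big] <- runif(length(big), 0, 70)
  v <- metric_value(d2, g, list(structure = "CTV2", metric = "Dcc", param = 0.03))
  expect_equal(v, sort(d2[big], decreasing = TRUE)[4])
  expect_equal(ceiling(0.03 / g$voxel_volume), 4)
})

test_that("goal scoring is piecewise linear with the documented anchors", {
  goals <- clinical_goals()
  parl <- goals[goals$structure == "PARL", ]
  expect_equal(score_goal(26, parl), 7.5)          # at the goal: full points
  expect_equal(score_goal(32.5, parl), 0)          # at goal x 1.25: zero
  expect_equal(score_goal(29.25, parl), 3.75)      # halfway: half points
  cov <- goals[goals$structure == "CTV2", ]
  expect_equal(score_goal(100, cov), 15)           # better than goal
  expect_equal(score_goal(98, cov), 15)
  expect_equal(score_goal(93, cov), 0)
  expect_equal(score_goal(95.5, cov), 7.5)
  bad <- parl; bad$zero_level <- 20
  expect_error(score_goal(25, bad), "zero-score level")
})

test_that("the default allocation sums to 150 and a goal-meeting dose scores 150", {
  goals <- clinical_goals()
  expect_equal(sum(goals$max_points), 150)
  expect_equal(nrow(goals), 16L)
  g <- disjoint_phantom()
  ps <- score_plan(perfect_dose(g), g)
  expect_equal(ps$total, 150)
  expect_true(all(ps$per_goal$points == ps$per_goal$max_points))
})

test_that("zero dose scores full OAR points and zero coverage points", {
  g <- fixture_phantom()
  ps <- score_plan(make_dose(g, 0), g)
  pg <- ps$per_goal
  cov <- grepl(">=", pg$label)
  expect_true(all(pg$points[cov] == 0))
  expect_true(all(pg$points[!cov] == pg$max_points[!cov]))
})

test_that("plan score is monotone in the clinically favorable direction", {
  g <- fixture_phantom()
  set.seed(21)
  d <- make_dose(g, 0)
  d[] <- runif(length(d), 20, 60)
  base <- score_plan(d, g)$total
  # decreasing every OAR voxel dose never decreases the score
  d_less <- d
  for (nm in names(g$structure_roles)[g$structure_roles == "OAR"])
    d_less[as.vector(g$masks[[nm]])] <- d_less[as.vector(g$masks[[nm]])] * 0.8
  expect_gte(score_plan(d_less, g)$total, base)
  # raising CTV dose toward the prescription never decreases the score
  # (outside OAR overlaps, where coverage and sparing genuinely compete)
  d_cov <- d_less
  in_oar <- Reduce(`|`, lapply(names(g$structure_roles)[g$structure_roles == "OAR"],
                               function(nm) as.vector(g$masks[[nm]])))
  raise <- as.vector(g$masks$CTV1) & !in_oar
  d_cov[raise] <- pmin(d_cov[raise] + 20, 70)
  expect_gte(score_plan(d_cov, g)$total, score_plan(d_less, g)$total)
})
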