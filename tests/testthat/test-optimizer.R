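test_that("activation profiles average pooled predictions per layer", {
  grid <- expand.grid(muscle = emg_muscles(), movement_code = 0:3,
                      rep = 1:3, stringsAsFactors = FALSE)
  # constant field
  grid$predicted <- 0.5
  prof <- activation_profile(grid)
  expect_equal(prof$s, rep(0.5, 4))
  expect_equal(prof$d, rep(0.5, 4))
  # superficial 1 / deep 0 for one exercise
  lm <- muscle_layer_map()
  grid$predicted <- ifelse(grid$movement_code == 2,
                           ifelse(lm[grid$muscle] == "superficial", 1, 0),
                           0.5)
  prof2 <- activation_profile(grid)
  expect_equal(prof2$s[3], 1)
  expect_equal(prof2$d[3], 0)
  # predictions outside [0, 1] are clamped before averaging
  grid$predicted <- 1.7
  expect_equal(activation_profile(grid)$s, rep(1, 4))
  # an empty (muscle, movement) cell is an error
  expect_error(activation_profile(grid[grid$movement_code != 1, ]),
               "movement code 1")
})

test_that("profiles from a planted cohort rank scaption-dominant superficial gains first", {
  g <- make_default_gain_table()
  # make scaption clearly dominant for the superficial layer
  g[c("medial_deltoid", "posterior_deltoid", "trapezius"), "scaption"] <- 1.5
  cfg <- cohort_config(n_subjects = 3, n_sessions = 2,
                       duration_per_trial = 4, gain_table = g, seed = 29)
  tab <- build_feature_table(generate_cohort(cfg))
  preds <- loso_predict_all(tab, model_spec("xgb", seed = 1))
  prof <- activation_profile(preds)
  expect_identical(which.max(prof$s), 1L) # scaption has code 0, row 1
})

test_that("the objective matches hand computations in both sign modes", {
  cons <- allocation_constraints()
  w <- allocation_weights(1, 0)
  zero <- make_activation_profile(rep(0, 4), rep(0, 4))
  ones <- make_activation_profile(rep(1, 4), rep(0, 4))
  expect_equal(allocation_objective(rep(15, 4), zero, w, cons), 0)
  expect_equal(allocation_objective(rep(15, 4), ones, w, cons), -60)
  # Var((30,10,10,10)) = (15^2 + 3 * 5^2) / 4 = 75
  x <- c(30, 10, 10, 10)
  expect_equal(allocation_objective(x, ones, w, cons), -60 + 0.1 * 75)
  expect_equal(allocation_objective(x, ones, w, cons, "literal"),
               -60 - 0.1 * 75)
  expect_error(allocation_objective(rep(15, 3), ones, w, cons), "entries")
})

test_that("analytic gradient agrees with finite differences", {
  p <- random_profile(3)
  w <- allocation_weights(0.7, 0.3)
  cons <- allocation_constraints()
  x <- c(12, 18, 14, 16)
  for (mode in c("goal-consistent", "literal")) {
    g <- emgdose:::allocation_gradient(x, p, w, cons, mode)
    num <- vapply(1:4, function(i) {
      h <- 1e-6; e <- replace(rep(0, 4), i, h)
      (allocation_objective(x + e, p, w, cons, mode) -
         allocation_objective(x - e, p, w, cons, mode)) / (2 * h)
    }, 0)
    expect_equal(g, num, tolerance = 1e-6)
  }
})

test_that("symmetric profiles give the equal split", {
  p <- make_activation_profile(rep(0.6, 4), rep(0.3, 4))
  plan <- solve_allocation(p, allocation_weights(0.7, 0.3))
  expect_equal(unname(plan$x), rep(15, 4), tolerance = 1e-6)
  g <- grid_oracle(p, allocation_weights(0.7, 0.3))
  expect_equal(unname(g$x), rep(15, 4))
})

test_that("a dominant variance penalty forces the equal split", {
  p <- random_profile(8)
  cons <- allocation_constraints(variance_penalty = 1000)
  plan <- solve_allocation(p, allocation_weights(0.7, 0.3), cons)
  expect_equal(unname(plan$x), rep(15, 4), tolerance = 0.1)
})

test_that("solutions are invariant to permuting the exercises", {
  p <- random_profile(12)
  w <- allocation_weights(0.5, 0.5)
  perm <- c(3, 1, 4, 2)
  pp <- make_activation_profile(p$s[perm], p$d[perm])
  a <- solve_allocation(p, w)
  b <- solve_allocation(pp, w)
  expect_equal(unname(b$x), unname(a$x)[perm], tolerance = 1e-5)
})

test_that("interior solutions respond monotonically to superficial activation", {
  # small s-differences keep the optimum strictly inside the bounds
  base <- c(0.50, 0.52, 0.48, 0.51)
  w <- allocation_weights(1, 0)
  xs <- sapply(c(0.50, 0.55, 0.60), function(s1) {
    p <- make_activation_profile(replace(base, 1, s1), rep(0.5, 4))
    plan <- solve_allocation(p, w)
    expect_true(all(plan$x > 5 + 1e-6 & plan$x < 30 - 1e-6))
    plan$x[1]
  })
  expect_true(all(diff(xs) > 0))
})

test_that("the solution is independent of the starting point", {
  p <- random_profile(21)
  w <- allocation_weights(0.3, 0.7)
  ref <- solve_allocation(p, w)
  set.seed(99)
  for (i in 1:10) {
    # random feasible start: bounded Dirichlet-ish point summing to 60
    x0 <- 5 + runif(4)
    x0 <- 5 + (x0 / sum(x0)) * 40 # in (5, 30), sums to 60
    alt <- solve_allocation(p, w, x0 = x0)
    expect_equal(unname(alt$x), unname(ref$x), tolerance = 0.1)
  }
})

test_that("proportional superficial and deep profiles make the cases coincide", {
  s <- c(0.8, 0.3, 0.5, 0.6)
  p <- make_activation_profile(s, 0.5 * s)
  # without the variance penalty the three cases minimize positive scalar
  # multiples of the same linear objective, so the plans are identical
  cons0 <- allocation_constraints(variance_penalty = 0)
  plans0 <- run_cases(p, cons0)
  expect_named(plans0, c("70/30", "50/50", "30/70"))
  for (pl in plans0) expect_equal(sum(pl$x), 60, tolerance = 1e-6)
  expect_equal(unname(plans0[["50/50"]]$x), unname(plans0[["70/30"]]$x),
               tolerance = 1e-4)
  expect_equal(unname(plans0[["30/70"]]$x), unname(plans0[["70/30"]]$x),
               tolerance = 1e-4)
  # with the penalty the absolute scale of the activation term matters,
  # but the exercise ranking is preserved across cases
  plans <- run_cases(p)
  for (pl in plans) {
    expect_equal(sum(pl$x), 60, tolerance = 1e-6)
    expect_identical(order(unname(pl$x)), order(s))
  }
})

test_that("rounded minutes are integers preserving the session total", {
  for (seed in 1:5) {
    p <- random_profile(seed + 100)
    plan <- solve_allocation(p, allocation_weights(0.7, 0.3))
    r <- plan$minutes_rounded
    expect_identical(sum(r), 60)
    expect_true(all(r == round(r)))
    expect_true(all(r >= 5 & r <= 30))
    expect_true(all(abs(r - plan$x) <= 1))
  }
})

test_that("infeasible constraint sets are rejected before solving", {
  expect_error(allocation_constraints(total_minutes = 10, lower_bound = 5,
                                      n_exercises = 4), "infeasible")
  expect_error(allocation_constraints(total_minutes = 200,
                                      upper_bound = 30, n_exercises = 4),
               "infeasible")
})

test_that("the literal sign mode rewards uneven allocations", {
  # with a flat activation field the literal form is maximized-variance:
  # the optimizer should leave the equal split, the goal-consistent form
  # should keep it
  p <- make_activation_profile(rep(0.5, 4), rep(0.5, 4))
  w <- allocation_weights(0.5, 0.5)
  lit <- grid_oracle(p, w, sign_mode = "literal")
  gc <- grid_oracle(p, w, sign_mode = "goal-consistent")
  expect_equal(unname(gc$x), rep(15, 4))
  expect_gt(emgdose:::pop_var(lit$x), 50) # pushed to the bounds
})
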