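#' Per-exercise superficial and deep activation profile
#'
#' Averages pooled out-of-fold predicted normalized RMS values into one
#' `(s_i, d_i)` pair per exercise: `s_i` is the mean over the three
#' superficial muscles of each muscle's mean predicted activation during
#' exercise `i`, and `d_i` the analogue over the three deep muscles.
#' Predictions are clamped to `[0, 1]` (normalized activations are
#' physically bounded) before averaging.
#'
#' @param predictions Data frame of pooled predictions with columns
#'   `muscle`, `movement_code` (or `movement`) and `predicted`, e.g. from
#'   [loso_predict_all()].
#' @param layer_map Named muscle -> layer map.
#' @param movements Movement names in code order.
#' @return Object of class `activation_profile`: data.frame with columns
#'   `movement`, `movement_code`, `s`, `d` (4 rows, in code order).
#' @export
activation_profile <- function(predictions, layer_map = muscle_layer_map(),
                               movements = emg_movements()) {
  stopifnot(all(c("muscle", "predicted") %in% names(predictions)))
  if (!"movement_code" %in% names(predictions))
    predictions$movement_code <- encode_movement(predictions$movement)
  predictions$predicted <- pmin(pmax(predictions$predicted, 0), 1)

  sup <- names(layer_map)[layer_map == "superficial"]
  dee <- names(layer_map)[layer_map == "deep"]
  cell_mean <- function(mov_code, muscle) {
    v <- predictions$predicted[predictions$movement_code == mov_code &
                                 predictions$muscle == muscle]
    if (!length(v))
      stop("no predictions for muscle '", muscle, "' during movement code ",
           mov_code, call. = FALSE)
    mean(v)
  }
  prof <- data.frame(
    movement = movements,
    movement_code = seq_along(movements) - 1L,
    s = vapply(seq_along(movements) - 1L,
               function(i) mean(vapply(sup, cell_mean, 0, mov_code = i)), 0),
    d = vapply(seq_along(movements) - 1L,
               function(i) mean(vapply(dee, cell_mean, 0, mov_code = i)), 0)
  )
  structure(prof, class = c("activation_profile", "data.frame"))
}

#' @export
print.activation_profile <- function(x, digits = 3, ...) {
  cat("Per-exercise activation profile (mean predicted normalized RMS)\n")
  print.data.frame(format(as.data.frame(x), digits = digits),
                   row.names = FALSE)
  invisible(x)
}

#' Construct an activation profile from known values
#'
#' Direct constructor for a per-exercise `(s, d)` profile, for use when
#' the mean activations come from a source other than pooled LOSO
#' predictions (a published table, a planted scenario, a sensitivity
#' sweep).
#'
#' @param s,d Superficial and deep mean activations, one per exercise,
#'   each in `[0, 1]`.
#' @param movements Movement names, in code order.
#' @return An `activation_profile`.
#' @examples
#' make_activation_profile(s = c(1, 0, 0, 0), d = rep(0, 4))
#' @export
make_activation_profile <- function(s, d, movements = emg_movements()) {
  stopifnot(length(s) == length(movements), length(d) == length(movements),
            all(s >= 0 & s <= 1), all(d >= 0 & d <= 1))
  structure(data.frame(movement = movements,
                       movement_code = seq_along(movements) - 1L,
                       s = as.numeric(s), d = as.numeric(d)),
            class = c("activation_profile", "data.frame"))
}

#' Allocation weights and constraints
#'
#' `allocation_weights()` sets the superficial/deep emphasis; the three
#' named clinical cases are 70/30, 50/50 and 30/70.
#' `allocation_constraints()` fixes the session structure: total time
#' (60 min), per-exercise bounds (5-30 min) and the variance-penalty
#' coefficient (0.1).
#'
#' @param ws,wd Nonnegative superficial and deep weights.
#' @param total_minutes Session length (default 60).
#' @param lower_bound,upper_bound Per-exercise bounds in minutes
#'   (defaults 5 and 30).
#' @param variance_penalty Coefficient of the allocation-variance term
#'   (default 0.1).
#' @param n_exercises Number of exercises (default 4).
#' @return Lists of class `allocation_weights` / `allocation_constraints`.
#' @export
allocation_weights <- function(ws, wd) {
  stopifnot(ws >= 0, wd >= 0, ws + wd > 0)
  label <- if (isTRUE(all.equal(ws + wd, 1)))
    sprintf("%d/%d", round(100 * ws), round(100 * wd)) else "custom"
  structure(list(ws = ws, wd = wd, case_label = label),
            class = "allocation_weights")
}

#' @rdname allocation_weights
#' @export
allocation_constraints <- function(total_minutes = 60, lower_bound = 5,
                                   upper_bound = 30, variance_penalty = 0.1,
                                   n_exercises = 4L) {
  stopifnot(variance_penalty >= 0, lower_bound <= upper_bound)
  if (n_exercises * lower_bound > total_minutes ||
      n_exercises * upper_bound < total_minutes)
    stop("infeasible constraints: need n*lower <= total <= n*upper",
         call. = FALSE)
  structure(list(total_minutes = total_minutes, lower_bound = lower_bound,
                 upper_bound = upper_bound,
                 variance_penalty = variance_penalty,
                 n_exercises = as.integer(n_exercises)),
            class = "allocation_constraints")
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Allocation objective
#'
#' The weighted activation-time objective to be minimized. In the default
#' `"goal-consistent"` mode the value is
#' `-ws * sum(x * s) - wd * sum(x * d) + lambda * Var(x)`
#' (population variance over the four minutes), so concentrating time in
#' one exercise is penalized; `"literal"` flips the variance term's sign
#' (`- lambda * Var(x)`), which under minimization rewards uneven
#' allocations.
#'
#' @param x Minutes per exercise (length `n_exercises`).
#' @param profile An [activation_profile()].
#' @param weights An [allocation_weights()].
#' @param constraints An [allocation_constraints()].
#' @param sign_mode `"goal-consistent"` (default) or `"literal"`.
#' @return Scalar objective value.
#' @examples
#' p <- make_activation_profile(s = c(1, 1, 1, 1), d = rep(0, 4))
#' allocation_objective(rep(15, 4), p, allocation_weights(1, 0),
#'                      allocation_constraints())
#' @export
allocation_objective <- function(x, profile, weights, constraints,
                                 sign_mode = c("goal-consistent", "literal")) {
  sign_mode <- match.arg(sign_mode)
  if (length(x) != constraints$n_exercises)
    stop("x must have ", constraints$n_exercises, " entries", call. = FALSE)
  lam <- constraints$variance_penalty
  act <- -weights$ws * sum(x * profile$s) - weights$wd * sum(x * profile$d)
  if (sign_mode == "goal-consistent") act + lam * pop_var(x)
  else act - lam * pop_var(x)
}

allocation_gradient <- function(x, profile, weights, constraints, sign_mode) {
  n <- length(x)
  g_act <- -weights$ws * profile$s - weights$wd * profile$d
  g_var <- 2 * (x - mean(x)) / n
  if (sign_mode == "goal-consistent")
    g_act + constraints$variance_penalty * g_var
  else g_act - constraints$variance_penalty * g_var
}

new_allocation_plan <- function(x, objective_value, weights, constraints,
                                sign_mode, method, diagnostics,
                                movements = emg_movements()) {
  structure(list(
    x = stats::setNames(as.numeric(x), movements),
    minutes_rounded = round_preserving_sum(x,
                                           constraints$total_minutes,
                                           constraints),
    objective_value = objective_value,
    weights = weights, constraints = constraints, sign_mode = sign_mode,
    method = method, diagnostics = diagnostics
  ), class = "allocation_plan")
}

# Largest-remainder integer rounding that preserves the total and bounds.
round_preserving_sum <- function(x, total, constraints) {
  f <- floor(x)
  rem <- total - sum(f)
  o <- order(x - f, decreasing = TRUE)
  out <- f
  i <- 1L
  while (rem > 0 && i <= length(x)) {
    j <- o[i]
    if (out[j] + 1 <= constraints$upper_bound) {
      out[j] <- out[j] + 1
      rem <- rem - 1
    }
    i <- i + 1L
    if (i > length(x) && rem > 0) i <- 1L # second pass if bounds blocked
  }
  out
}

#' @export
print.allocation_plan <- function(x, digits = 2, ...) {
  cat(sprintf("Allocation plan (%s, %s mode, %s)\n",
              x$weights$case_label, x$sign_mode, x$method))
  df <- data.frame(exercise = names(x$x),
                   minutes = round(unname(x$x), digits),
                   rounded = unname(x$minutes_rounded))
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("  total %.4f min, objective %.4f\n", sum(x$x),
              x$objective_value))
  invisible(x)
}

#' Solve the constrained time-allocation problem
#'
#' Minimizes [allocation_objective()] subject to the equality constraint
#' `sum(x) = total_minutes` and per-exercise bounds, using a
#' derivative-based sequential-quadratic-programming solver (SLSQP via
#' nloptr) with analytic gradients, started from the equal split. The
#' returned plan satisfies the constraints to within 1e-6 and its
#' objective never exceeds the equal-split value.
#'
#' @inheritParams allocation_objective
#' @param x0 Optional start (default: equal split).
#' @return An `allocation_plan`: minutes per exercise (raw and
#'   sum-preserving integer rounding), objective value, weights,
#'   constraints and solver diagnostics.
#' @seealso [grid_oracle()] for the exhaustive lattice check.
#' @export
solve_allocation <- function(profile, weights, constraints = allocation_constraints(),
                             sign_mode = c("goal-consistent", "literal"),
                             x0 = NULL) {
  sign_mode <- match.arg(sign_mode)
  n <- constraints$n_exercises
  stopifnot(nrow(profile) == n)
  if (is.null(x0)) x0 <- rep(constraints$total_minutes / n, n)
  fn <- function(x) allocation_objective(x, profile, weights, constraints,
                                         sign_mode)
  gr <- function(x) allocation_gradient(x, profile, weights, constraints,
                                        sign_mode)
  res <- nloptr::slsqp(
    x0, fn = fn, gr = gr,
    lower = rep(constraints$lower_bound, n),
    upper = rep(constraints$upper_bound, n),
    heq = function(x) sum(x) - constraints$total_minutes,
    heqjac = function(x) matrix(1, 1, n),
    control = list(xtol_rel = 1e-10, ftol_abs = 1e-12, maxeval = 2000))
  x <- pmin(pmax(res$par, constraints$lower_bound), constraints$upper_bound)
  # re-project the (tiny) residual of the equality constraint
  x <- x + (constraints$total_minutes - sum(x)) / n
  viol <- abs(sum(x) - constraints$total_minutes)
  if (viol > 1e-6)
    stop("solver failed to satisfy the total-time constraint (violation ",
         signif(viol, 3), " min)", call. = FALSE)
  plan <- new_allocation_plan(
    x, fn(x), weights, constraints, sign_mode, method = "slsqp",
    diagnostics = list(iterations = res$iter, convergence = res$convergence,
                       message = res$message, constraint_violation = viol),
    movements = as.character(profile$movement))
  eq_val <- fn(rep(constraints$total_minutes / n, n))
  if (plan$objective_value > eq_val + 1e-8)
    warning("solver returned a worse objective than the equal split")
  plan
}

#' Exhaustive grid oracle for the allocation problem
#'
#' Enumerates the full lattice of feasible allocations at the given
#' resolution (all combinations of the first `n - 1` coordinates, the last
#' determined by the total-time equality) and returns the lattice
#' minimizer of the objective. Intended as an independent verification
#' oracle for [solve_allocation()].
#'
#' @inheritParams allocation_objective
#' @param resolution Lattice spacing in minutes (default 0.5).
#' @return An `allocation_plan` holding the lattice optimum.
#' @export
grid_oracle <- function(profile, weights, constraints = allocation_constraints(),
                        sign_mode = c("goal-consistent", "literal"),
                        resolution = 0.5) {
  sign_mode <- match.arg(sign_mode)
  n <- constraints$n_exercises
  vals <- seq(constraints$lower_bound, constraints$upper_bound,
              by = resolution)
  grid <- as.matrix(do.call(expand.grid, rep(list(vals), n - 1L)))
  last <- constraints$total_minutes - rowSums(grid)
  keep <- last >= constraints$lower_bound - 1e-9 &
    last <= constraints$upper_bound + 1e-9
  if (!any(keep)) stop("empty lattice at this resolution", call. = FALSE)
  X <- cbind(grid[keep, , drop = FALSE], last[keep])

  lam <- constraints$variance_penalty
  coefs <- -weights$ws * profile$s - weights$wd * profile$d
  act <- as.numeric(X %*% coefs)
  v <- rowMeans(X^2) - rowMeans(X)^2  # population variance, vectorized
  obj <- if (sign_mode == "goal-consistent") act + lam * v else act - lam * v
  best <- which.min(obj)
  new_allocation_plan(
    X[best, ], obj[best], weights, constraints, sign_mode,
    method = sprintf("grid oracle (%.2f-min lattice, %d points)",
                     resolution, nrow(X)),
    diagnostics = list(lattice_points = nrow(X)),
    movements = as.character(profile$movement))
}

#' Solve the three clinical weighting cases
#'
#' Runs [solve_allocation()] for superficial/deep emphases 70/30, 50/50
#' and 30/70 on one activation profile.
#'
#' @inheritParams allocation_objective
#' @param cases List of `c(ws, wd)` pairs; default the three named cases.
#' @return Named list of `allocation_plan`s (`"70/30"`, `"50/50"`,
#'   `"30/70"`).
#' @export
run_cases <- function(profile, constraints = allocation_constraints(),
                      sign_mode = c("goal-consistent", "literal"),
                      cases = list(c(0.7, 0.3), c(0.5, 0.5), c(0.3, 0.7))) {
  sign_mode <- match.arg(sign_mode)
  plans <- lapply(cases, function(w)
    solve_allocation(profile, allocation_weights(w[1], w[2]), constraints,
                     sign_mode))
  stats::setNames(plans, vapply(plans, function(p) p$weights$case_label, ""))
}
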