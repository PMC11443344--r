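#' Dung beetle optimizer configuration
#'
#' Box-constrained minimization with three behavioral roles updated each
#' iteration: rollers (sun-navigation drift away from the worst position),
#' brood balls (a spawning region contracted around the current local best
#' by `R = 1 - t / Tmax`) and foragers (a feeding region around the global
#' best). Role proportions default to 0.3 / 0.3 / 0.4 of the population.
#'
#' @param pop_size population size (at least 4); default 20.
#' @param max_iter number of iterations `Tmax`; default 8.
#' @param k roller deflection coefficient in `(0, 0.2]`.
#' @param b_roll roller light-intensity constant in `(0, 1)`.
#' @param role_fractions fractions (rollers, brood, foragers) summing to 1.
#' @param lower,upper numeric per-dimension bounds, `lower < upper`.
#' @param seed integer seed; the trajectory is deterministic given it.
#' @param include_thief also run the off-by-default thief (stealing) role,
#'   replacing part of the forager share; disabled by default because the
#'   core update set is rolling / brooding / foraging.
#' @return Named list of class `dbo_config`.
#' @export
dboConfig <- function(pop_size = 20L, max_iter = 8L, k = 0.1, b_roll = 0.3,
                      role_fractions = c(0.3, 0.3, 0.4),
                      lower, upper, seed = 1L, include_thief = FALSE) {
  stopifnot(pop_size >= 4, max_iter >= 0, k > 0, k <= 0.2,
            b_roll > 0, b_roll < 1,
            length(role_fractions) == 3, all(role_fractions >= 0),
            abs(sum(role_fractions) - 1) < 1e-9,
            length(lower) == length(upper), all(lower < upper))
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), k = k, b_roll = b_roll,
                 role_fractions = role_fractions,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 seed = as.integer(seed), include_thief = include_thief),
            class = "dbo_config")
}

#' Roller position update
#'
#' `x(t+1) = x(t) + alpha * k * x(t-1) + b * |x(t) - x_worst|` (componentwise
#' absolute value), clipped to the box.
#'
#' @param x_t,x_prev current and previous positions (numeric vectors).
#' @param x_worst global worst position.
#' @param k deflection coefficient; `b_roll` light constant; `alpha` +1 or
#'   -1 (natural coefficient).
#' @param b_roll,alpha see above.
#' @param lower,upper box bounds.
#' @return Updated position.
#' @export
dboRollUpdate <- function(x_t, x_prev, x_worst, k, b_roll, alpha,
                          lower, upper) {
  stopifnot(alpha %in% c(-1, 1))
  clip(x_t + alpha * k * x_prev + b_roll * abs(x_t - x_worst), lower, upper)
}

#' Brood-ball position update
#'
#' Spawning region around the current local best `X*`:
#' `Lb* = max(X* (1 - R), Lb)`, `Ub* = min(X* (1 - R), Ub)` (componentwise,
#' as printed in the source update rules — both bounds carry `(1 - R)`, so
#' the region is a point or inverted). A proper interval is kept; an
#' inverted one collapses to the box-clipped `X*`. The update
#' `B(t+1) = X* + b1 (B(t) - Lb*) + b2 (B(t) - Ub*)` with
#' `b1, b2 ~ U(0,1)^D` is then clipped into the (possibly collapsed)
#' region.
#'
#' @param B_t current brood-ball position.
#' @param x_best_local current local best `X*`.
#' @param R shrink factor `1 - t / Tmax` in `[0, 1]`.
#' @param lower,upper box bounds.
#' @param b1,b2 optional fixed random vectors (drawn `U(0,1)^D` when NULL;
#'   exposing them keeps seeded replays exact and tests deterministic).
#' @return Updated position.
#' @export
dboBroodUpdate <- function(B_t, x_best_local, R, lower, upper,
                           b1 = NULL, b2 = NULL) {
  stopifnot(R >= 0, R <= 1)
  D <- length(B_t)
  v <- x_best_local * (1 - R)
  lb <- pmax(v, lower)
  ub <- pmin(v, upper)
  bad <- lb > ub
  pt <- clip(x_best_local, lower, upper)
  lb[bad] <- pt[bad]; ub[bad] <- pt[bad]
  if (is.null(b1)) b1 <- stats::runif(D)
  if (is.null(b2)) b2 <- stats::runif(D)
  clip(x_best_local + b1 * (B_t - lb) + b2 * (B_t - ub), lb, ub)
}

#' Forager position update
#'
#' Feeding region around the global best `Xb`:
#' `Lbb = max(Xb (1 + R), Lb)`, `Ubb = min(Xb (1 + R), Ub)` (componentwise,
#' both bounds carrying `(1 + R)` as printed in the source update rules).
#' Update `x(t+1) = x(t) + C1 (x(t) - Lbb) + C2 (x(t) - Ubb)` with scalar
#' `C1 ~ N(0, 1)` and `C2 ~ U(0,1)^D`, clipped to the global box.
#'
#' @param x_t current position; `x_best_global` the global best `Xb`.
#' @param x_best_global,R,lower,upper see above.
#' @param C1,C2 optional fixed draws (for deterministic replay).
#' @return Updated position.
#' @export
dboForageUpdate <- function(x_t, x_best_global, R, lower, upper,
                            C1 = NULL, C2 = NULL) {
  stopifnot(R >= 0, R <= 1)
  D <- length(x_t)
  v <- x_best_global * (1 + R)
  lbb <- pmax(v, lower)
  ubb <- pmin(v, upper)
  if (is.null(C1)) C1 <- stats::rnorm(1)
  if (is.null(C2)) C2 <- stats::runif(D)
  clip(x_t + C1 * (x_t - lbb) + C2 * (x_t - ubb), lower, upper)
}

# thief update (off by default): jump around the global best scaled by the
# spread to local and global bests
dboThiefUpdate <- function(x_t, x_best_local, x_best_global, lower, upper,
                           S = 0.5) {
  g <- stats::rnorm(length(x_t))
  clip(x_best_global +
         S * g * (abs(x_t - x_best_local) + abs(x_t - x_best_global)),
       lower, upper)
}

#' Run the dung beetle optimizer
#'
#' Initializes the population uniformly in the box, then iterates the role
#' updates, re-evaluates, and tracks the current local best `X*`, the
#' global best-so-far `Xb` (ties keep the earlier incumbent) and the
#' current worst `Xw`. Position replacement is unconditional (the
#' metaheuristic's moves are not greedy); the best-so-far record is what
#' is guaranteed monotone.
#'
#' @param objective function mapping a D-vector to a finite numeric value.
#' @param config a [dboConfig()].
#' @return List: `best_position`, `best_fitness`, `history` (best-so-far
#'   fitness per iteration, length `max_iter`), `population`, `fitness`.
#' @export
dboOptimize <- function(objective, config) {
  stopifnot(inherits(config, "dbo_config"))
  D <- length(config$lower)
  np <- config$pop_size
  set.seed(config$seed)

  evalPos <- function(x) {
    f <- objective(x)
    if (!is.finite(f))
      stop(sprintf("non-finite objective at (%s)",
                   paste(signif(x, 6), collapse = ", ")))
    f
  }

  pos <- matrix(stats::runif(np * D, rep(config$lower, each = np),
                             rep(config$upper, each = np)), np, D)
  prev <- pos
  fit <- apply(pos, 1, evalPos)

  n_roll <- round(config$role_fractions[1] * np)
  n_brood <- round(config$role_fractions[2] * np)
  n_thief <- if (config$include_thief)
    max(0L, min(np - n_roll - n_brood, round(0.25 * np))) else 0L
  roles <- rep("forage", np)
  if (n_roll > 0) roles[seq_len(n_roll)] <- "roll"
  if (n_brood > 0) roles[n_roll + seq_len(n_brood)] <- "brood"
  if (n_thief > 0) roles[np - seq_len(n_thief) + 1L] <- "thief"

  ib <- which.min(fit)
  best_pos <- pos[ib, ]; best_fit <- fit[ib]
  history <- numeric(0)

  for (t in seq_len(config$max_iter)) {
    R <- 1 - t / config$max_iter
    x_star <- pos[which.min(fit), ]      # current local best
    x_worst <- pos[which.max(fit), ]     # current worst
    newpos <- pos
    for (i in seq_len(np)) {
      newpos[i, ] <- switch(roles[i],
        roll = dboRollUpdate(pos[i, ], prev[i, ], x_worst, config$k,
                             config$b_roll, sample(c(-1, 1), 1),
                             config$lower, config$upper),
        brood = dboBroodUpdate(pos[i, ], x_star, R, config$lower,
                               config$upper),
        forage = dboForageUpdate(pos[i, ], best_pos, R, config$lower,
                                 config$upper),
        thief = dboThiefUpdate(pos[i, ], x_star, best_pos, config$lower,
                               config$upper))
    }
    prev <- pos
    pos <- newpos
    fit <- apply(pos, 1, evalPos)
    ib <- which.min(fit)
    if (fit[ib] < best_fit) {  # strict: ties keep the earlier incumbent
      best_fit <- fit[ib]; best_pos <- pos[ib, ]
    }
    history <- c(history, best_fit)
  }

  list(best_position = best_pos, best_fitness = best_fit,
       history = history, population = pos, fitness = fit)
}

#' Write an optimizer history CSV
#'
#' @param result a [dboOptimize()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDBOHistory <- function(result, path) {
  df <- data.frame(iteration = seq_along(result$history),
                   best_fitness = result$history)
  bp <- matrix(result$best_position, nrow(df), length(result$best_position),
               byrow = TRUE)
  colnames(bp) <- paste0("best_x", seq_len(ncol(bp)))
  utils::write.csv(cbind(df, bp), path, row.names = FALSE)
  invisible(path)
}
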