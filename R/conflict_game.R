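#' Solve one instance of the intergenerational reproduction game
#'
#' The package's main entry point. Constructs and fully solves the
#' parent/adolescent reproduction game at one parameter point: all eight
#' conditional payoffs, the four critical survival ratios, the sequential
#' outcome under each move order, each actor's fitness loss to moving second,
#' the conflict zone, and the predicted winner.
#'
#' @param s Survival ratio of a co-resident infant relative to a sole infant,
#'   in `[0, 1]`.
#' @param c Parental continuity (probability the parent's next infant is the
#'   adolescent's full sibling), in `[0, 1]`. Default `0`.
#' @param y Youth benefit (relative fitness of the adolescent's infant),
#'   `> 0`. Default `1` (no senescence).
#' @param tol Absolute tolerance for indifference decisions; defaults to
#'   [kc_tol()].
#'
#' @return An object of class `"conflict_game"` with components `params`,
#'   `payoffs` (a [payoff_table()]), `thresholds`
#'   ([conflict_thresholds()]), `parent_first` and `adolescent_first`
#'   ([sequential_outcome()] objects), `analysis` (a
#'   [predict_winner()] result) and `tol`.
#' @examples
#' g <- conflict_game(s = 0.2, c = 0, y = 1)
#' g
#' coef(g)
#' summary(g)
#' @seealso [predict.conflict_game()], [simulate.conflict_game()],
#'   [plot.conflict_game()]
#' @export
conflict_game <- function(s, c = 0, y = 1, tol = kc_tol()) {
  p <- game_params(s, c, y)
  structure(
    list(
      params = p,
      payoffs = payoff_table(p),
      thresholds = conflict_thresholds(p),
      parent_first = sequential_outcome("parent", p, tol = tol),
      adolescent_first = sequential_outcome("adolescent", p, tol = tol),
      analysis = predict_winner(p, tol = tol),
      tol = tol
    ),
    class = "conflict_game"
  )
}

#' @export
print.conflict_game <- function(x, digits = 4, ...) {
  a <- x$analysis
  p <- x$params
  cat("Intergenerational reproductive conflict game\n")
  cat(sprintf("  s = %g (survival ratio), c = %g (parental continuity), y = %g (youth benefit)\n",
              p$s, p$c, p$y))
  cat(sprintf("  zone %d; losses to moving second: parent %.*f, adolescent %.*f\n",
              a$zone, digits, a$loss_parent, digits, a$loss_adolescent))
  cat(sprintf("  predicted winner: %s\n", a$winner))
  invisible(x)
}

#' Model parameters of a solved game
#'
#' @param object A `"conflict_game"` object.
#' @param ... Unused.
#' @return Named numeric vector `(s, c, y)`.
#' @export
coef.conflict_game <- function(object, ...) {
  unlist(object$params)
}

#' @export
summary.conflict_game <- function(object, ...) {
  structure(list(game = object), class = "summary.conflict_game")
}

#' @export
print.summary.conflict_game <- function(x, digits = 4, ...) {
  g <- x$game
  p <- g$params
  print(g, digits = digits)
  cat("\nPayoffs:\n")
  print(g$payoffs, digits = digits)
  cat("\nCritical survival ratios:\n")
  th <- g$thresholds
  for (nm in names(th)) {
    cat(sprintf("  %-31s %.*f\n", nm, digits, th[[nm]]))
  }
  cat("\nSequential outcomes:\n")
  print(g$parent_first, digits = digits)
  print(g$adolescent_first, digits = digits)
  cat("\nSole-reproducer preferences: parent -> ")
  cat(sole_reproducer_preference("parent", p, tol = g$tol))
  cat(", adolescent -> ")
  cat(sole_reproducer_preference("adolescent", p, tol = g$tol))
  cat("\n\n")
  print(g$analysis, digits = digits)
  invisible(x)
}

#' Predict conflict outcomes on new parameter points
#'
#' Evaluates the solved-game summaries (thresholds, losses, zone, winner) on
#' a data frame of new parameter values, defaulting any missing column to the
#' fitted game's own value. Equivalent to [conflict_sweep()] on explicit
#' points.
#'
#' @param object A `"conflict_game"` object.
#' @param newdata Data frame with any of columns `s`, `c`, `y`. If `NULL`,
#'   the game's own parameter point is used.
#' @param ... Unused.
#' @return A data frame, one row per parameter point (see
#'   [conflict_sweep()] for the columns).
#' @examples
#' g <- conflict_game(0.2, 0, 1)
#' predict(g, newdata = data.frame(s = c(0.1, 0.4, 0.9)))
#' @export
predict.conflict_game <- function(object, newdata = NULL, ...) {
  p <- object$params
  if (is.null(newdata)) {
    newdata <- data.frame(s = p$s)
  }
  newdata <- as.data.frame(newdata)
  for (nm in c("s", "c", "y")) {
    if (is.null(newdata[[nm]])) newdata[[nm]] <- p[[nm]]
  }
  sweep_points(newdata[, c("s", "c", "y"), drop = FALSE], tol = object$tol)
}

#' Simulate realised inclusive-fitness payoffs from a solved game
#'
#' Draws per-replicate realised payoffs from the stochastic household model
#' (see [simulate_payoffs()]) at the game's parameter point. By default the
#' actors play the equilibrium actions of the parent-first sequential
#' outcome.
#'
#' @param object A `"conflict_game"` object.
#' @param nsim Number of replicate households.
#' @param seed Integer seed for the simulation's own RNG stream; the global
#'   RNG state is left untouched. `NULL` draws one from the current state.
#' @param actions Length-2 character vector `(parent, adolescent)` of `"R"`
#'   or `"N"`; default: the equilibrium actions when the parent moves first.
#' @param ... Unused.
#' @return A data frame with `nsim` rows and columns `payoff_parent`,
#'   `payoff_adolescent`, carrying the seed used as attribute `"seed"`.
#' @examples
#' g <- conflict_game(0.8, 0.5, 2)
#' colMeans(simulate(g, nsim = 2000, seed = 1))
#' @export
simulate.conflict_game <- function(object, nsim = 10000, seed = NULL,
                                   actions = NULL, ...) {
  if (is.null(actions)) {
    actions <- c(object$parent_first$first_action,
                 object$parent_first$second_action)
  }
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  draws <- household_draws(object$params, actions, n_reps = nsim, seed = seed)
  out <- data.frame(payoff_parent = draws$parent,
                    payoff_adolescent = draws$adolescent)
  attr(out, "seed") <- seed
  attr(out, "actions") <- actions
  out
}

#' Plot fitness-loss curves through a solved game's parameter point
#'
#' Draws each actor's loss to moving second as a function of the survival
#' ratio `s`, holding the game's `c` and `y` fixed, with the zone bounds as
#' vertical lines and the game's own `s` marked.
#'
#' @param x A `"conflict_game"` object.
#' @param s_grid Grid of survival ratios for the curves.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.conflict_game <- function(x, s_grid = seq(0, 1, by = 0.005), ...) {
  p <- x$params
  lp <- vapply(s_grid, function(s)
    loss_to_second("parent", game_params(s, p$c, p$y), tol = x$tol), 0)
  la <- vapply(s_grid, function(s)
    loss_to_second("adolescent", game_params(s, p$c, p$y), tol = x$tol), 0)
  graphics::matplot(
    s_grid, cbind(lp, la), type = "l", lty = c(1, 3), col = c(1, 2),
    xlab = "survival ratio s", ylab = "fitness loss to moving second",
    main = sprintf("c = %g, y = %g", p$c, p$y), ...
  )
  graphics::abline(h = 0, col = "grey70")
  graphics::abline(v = x$analysis$zone_bounds, lty = 2, col = "grey50")
  graphics::points(p$s, x$analysis$loss_parent, pch = 19)
  graphics::points(p$s, x$analysis$loss_adolescent, pch = 21, col = 2)
  graphics::legend("topright", legend = c("parent", "adolescent"),
                   lty = c(1, 3), col = c(1, 2), bty = "n")
  invisible(x)
}
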