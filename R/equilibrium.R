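#' Closed-form critical survival ratios
#'
#' The four threshold values of the survival ratio `s` that govern second-mover
#' behaviour and preferences:
#' \describe{
#'   \item{`adolescent_adds_second`}{`(1 + c) / (2 y + 1 + c)`: above this the
#'     adolescent reproduces even though the parent already has
#'     (`V2(R|R) > V2(N|R)`).}
#'   \item{`parent_wants_adolescent_second`}{`2 / (y + 2)`: above this the
#'     parent, having reproduced, wants the adolescent to add a second infant
#'     (`V1(R|R) > V1(R|N)`).}
#'   \item{`parent_adds_second`}{`y / (y + 2)`: above this the parent
#'     reproduces even though the adolescent already has
#'     (`V1(R|R) > V1(N|R)`).}
#'   \item{`adolescent_wants_parent_second`}{`2 y / (2 y + 1 + c)`: above this
#'     the adolescent, having reproduced, wants the parent to add a second
#'     infant (`V2(R|R) > V2(R|N)`).}
#' }
#' All four lie strictly inside `(0, 1)` for any valid parameters. The value
#' of `s` inside `params` is ignored.
#'
#' @inheritParams payoff
#' @return Named list of the four critical `s` values.
#' @examples
#' conflict_thresholds(game_params(0.5, 0, 1))$adolescent_adds_second  # 1/3
#' @export
conflict_thresholds <- function(params) {
  p <- as_game_params(params)
  y <- p$y
  cc <- p$c
  list(
    adolescent_adds_second = (1 + cc) / (2 * y + 1 + cc),
    parent_wants_adolescent_second = 2 / (y + 2),
    parent_adds_second = y / (y + 2),
    adolescent_wants_parent_second = 2 * y / (2 * y + 1 + cc)
  )
}

#' Second-mover best response
#'
#' Given the other actor's action, return this actor's payoff-maximising
#' action. Reproduction is chosen iff its payoff strictly exceeds the payoff
#' from abstaining (the model's preference conditions are strict
#' inequalities); exact indifference, judged at the package tolerance,
#' resolves to `"N"` with the tie flag set.
#'
#' @inheritParams payoff
#' @param other_action The already-chosen action of the other actor.
#' @param tol Absolute tolerance for indifference; defaults to [kc_tol()].
#' @return List with `action` (`"R"` or `"N"`) and logical `tie`.
#' @examples
#' best_response("adolescent", "R", game_params(0.9, 0, 1))  # R: s > 1/3
#' best_response("adolescent", "R", game_params(0.2, 0, 1))  # N: s < 1/3
#' @export
best_response <- function(role, other_action, params, tol = kc_tol()) {
  role <- match_role(role)
  other_action <- match_action(other_action, "other_action")
  p <- as_game_params(params)
  diff <- payoff(role, "R", other_action, p) - payoff(role, "N", other_action, p)
  if (abs(diff) <= tol) {
    list(action = "N", tie = TRUE)
  } else {
    list(action = if (diff > 0) "R" else "N", tie = FALSE)
  }
}

new_sequential_outcome <- function(first_mover, first_action, second_action,
                                   payoff_parent, payoff_adolescent,
                                   second_tie = FALSE,
                                   first_mover_abstains = NA) {
  structure(
    list(
      first_mover = first_mover,
      first_action = first_action,
      second_action = second_action,
      n_infants = sum(c(first_action, second_action) == "R"),
      payoff_parent = payoff_parent,
      payoff_adolescent = payoff_adolescent,
      second_tie = second_tie,
      first_mover_abstains = first_mover_abstains
    ),
    class = "sequential_outcome"
  )
}

#' @export
print.sequential_outcome <- function(x, digits = 4, ...) {
  second <- other_role(x$first_mover)
  cat(sprintf(
    "sequential outcome: %s moves first (%s), %s responds (%s); %d infant(s)\n",
    x$first_mover, x$first_action, second, x$second_action, x$n_infants
  ))
  cat(sprintf("  payoff parent     = %.*f\n", digits, x$payoff_parent))
  cat(sprintf("  payoff adolescent = %.*f\n", digits, x$payoff_adolescent))
  if (isTRUE(x$second_tie)) {
    cat("  (second mover exactly indifferent; resolved to N)\n")
  }
  if (isTRUE(x$first_mover_abstains)) {
    cat("  (first mover would voluntarily abstain)\n")
  }
  invisible(x)
}

#' Outcome of the sequential game for a given first mover
#'
#' The first mover reproduces (the convention of the piecewise sequential
#' payoffs: a first mover who has not reproduced leaves the second mover the
#' trivial sole-reproducer choice) and the second mover best-responds. With
#' the parent first, the realised payoffs are `V1(R|R), V2(R|R)` when
#' `s > (1+c)/(2y+1+c)` and `V1(R|N) = 0.5, V2(N|R) = 0.25(1+c)` otherwise;
#' with the adolescent first they are `V1(R|R), V2(R|R)` when `s > y/(y+2)`
#' and `V1(N|R) = 0.25 y, V2(R|N) = 0.5 y` otherwise. Use
#' [bruteforce_solve()] to let the first mover optimise its own action too.
#'
#' @inheritParams best_response
#' @param first_mover `"parent"` or `"adolescent"`.
#' @return An object of class `"sequential_outcome"`: `first_mover`,
#'   `first_action`, `second_action`, `n_infants`, `payoff_parent`,
#'   `payoff_adolescent`, `second_tie`.
#' @examples
#' sequential_outcome("parent", game_params(0.2, 0, 1))  # (R, N): 0.5 / 0.25
#' sequential_outcome("parent", game_params(0.9, 0, 1))  # (R, R)
#' @export
sequential_outcome <- function(first_mover, params, tol = kc_tol()) {
  first_mover <- match_role(first_mover)
  p <- as_game_params(params)
  second <- other_role(first_mover)
  br <- best_response(second, "R", p, tol = tol)
  actions <- list()
  actions[[first_mover]] <- "R"
  actions[[second]] <- br$action
  new_sequential_outcome(
    first_mover = first_mover,
    first_action = "R",
    second_action = br$action,
    payoff_parent = payoff("parent", actions$parent, actions$adolescent, p),
    payoff_adolescent = payoff("adolescent", actions$adolescent, actions$parent, p),
    second_tie = br$tie
  )
}

#' Brute-force backward induction over the full two-stage tree
#'
#' Independent oracle for [sequential_outcome()]: enumerates all four action
#' profiles using only the tabulated payoffs ([payoff_table()]), computes the
#' second mover's best response to each possible first move, and then lets the
#' first mover choose its own action by comparing the induced payoffs — rather
#' than assuming the first mover reproduces. When the first mover's optimal
#' action is `"N"` (e.g. a parent facing a very large youth benefit, `y > 2`,
#' prefers the adolescent to be the sole reproducer), `first_mover_abstains`
#' is `TRUE` and the returned actions reflect the abstention.
#'
#' @inheritParams sequential_outcome
#' @return A `"sequential_outcome"` object with `first_mover_abstains` set.
#' @examples
#' bruteforce_solve("parent", game_params(0.2, 0, 3))    # parent abstains
#' bruteforce_solve("parent", game_params(0.2, 0, 1.9))  # parent reproduces
#' @export
bruteforce_solve <- function(first_mover, params, tol = kc_tol()) {
  first_mover <- match_role(first_mover)
  p <- as_game_params(params)
  second <- other_role(first_mover)
  tab <- payoff_table(p)

  respond <- function(first_action) {
    vR <- pt_lookup(tab, second, "R", first_action)
    vN <- pt_lookup(tab, second, "N", first_action)
    if (abs(vR - vN) <= tol) {
      list(action = "N", tie = TRUE)
    } else {
      list(action = if (vR > vN) "R" else "N", tie = FALSE)
    }
  }

  value_to_first <- function(first_action, response) {
    pt_lookup(tab, first_mover, first_action, response$action)
  }

  br_R <- respond("R")
  br_N <- respond("N")
  vR <- value_to_first("R", br_R)
  vN <- value_to_first("N", br_N)
  # same strict-inequality convention as everywhere else: ties resolve to N
  first_action <- if (vR > vN + tol) "R" else "N"
  response <- if (first_action == "R") br_R else br_N

  actions <- list()
  actions[[first_mover]] <- first_action
  actions[[second]] <- response$action
  new_sequential_outcome(
    first_mover = first_mover,
    first_action = first_action,
    second_action = response$action,
    payoff_parent = pt_lookup(tab, "parent", actions$parent, actions$adolescent),
    payoff_adolescent = pt_lookup(tab, "adolescent", actions$adolescent, actions$parent),
    second_tie = response$tie,
    first_mover_abstains = first_action == "N"
  )
}

#' Fitness loss to moving second
#'
#' An actor's payoff when it reproduces first minus its payoff when the other
#' actor reproduces first (both from [sequential_outcome()], so the second
#' mover always best-responds). Positive losses measure how much the actor
#' should be willing to invest to win the first-mover position; negative
#' losses mean the actor actually prefers to choose after the other
#' (endogenous timing).
#'
#' @inheritParams sequential_outcome
#' @param role The actor whose loss is computed.
#' @return A single number (may be negative).
#' @examples
#' loss_to_second("parent", game_params(0.2, 0, 1))      # 0.25
#' loss_to_second("adolescent", game_params(0.2, 1, 1))  # 0: indifferent
#' loss_to_second("parent", game_params(0.9, 0, 1))      # 0: both reproduce
#' @export
loss_to_second <- function(role, params, tol = kc_tol()) {
  role <- match_role(role)
  p <- as_game_params(params)
  mine <- sequential_outcome(role, p, tol = tol)
  theirs <- sequential_outcome(other_role(role), p, tol = tol)
  field <- paste0("payoff_", role)
  mine[[field]] - theirs[[field]]
}

#' Classify a parameter point into the three conflict zones
#'
#' The parameter space splits at the two critical values
#' `(1 + c)/(2 y + 1 + c)` (the adolescent's add-a-second threshold) and
#' `y/(y + 2)` (the parent's): zone 1 (`s` below both) where only one actor
#' reproduces, zone 2 (strictly between them) where the infant count depends
#' on who moves first, and zone 3 (`s` above both) where both reproduce
#' regardless of order. Which bound is lower flips at `y = sqrt(1 + c)`;
#' exactly there the bounds coincide and zone 2 is empty. Points lying on a
#' bound (within tolerance) are assigned to the adjacent lower-numbered zone
#' and flagged via `on_boundary`.
#'
#' @inheritParams sequential_outcome
#' @return List with `zone` (1, 2 or 3), `zone_bounds` (sorted length-2
#'   numeric), `on_boundary` and `zone2_empty` logicals.
#' @examples
#' classify_zone(game_params(0.4, 1, 1))        # zone 2, bounds (1/3, 1/2)
#' classify_zone(game_params(0.9, 0, 1))        # zone 3
#' classify_zone(game_params(0.5, 1, sqrt(2)))  # zone 2 empty here
#' @export
classify_zone <- function(params, tol = kc_tol()) {
  p <- as_game_params(params)
  th <- conflict_thresholds(p)
  bounds <- sort(c(th$adolescent_adds_second, th$parent_adds_second))
  s <- p$s
  zone2_empty <- diff(bounds) <= tol
  if (s < bounds[1] - tol) {
    zone <- 1L
    on_boundary <- FALSE
  } else if (s <= bounds[1] + tol) {
    zone <- 1L
    on_boundary <- TRUE
  } else if (s < bounds[2] - tol) {
    zone <- 2L
    on_boundary <- FALSE
  } else if (s <= bounds[2] + tol) {
    zone <- 2L
    on_boundary <- TRUE
  } else {
    zone <- 3L
    on_boundary <- FALSE
  }
  list(
    zone = zone,
    zone_bounds = bounds,
    on_boundary = on_boundary,
    zone2_empty = zone2_empty
  )
}

#' Full conflict analysis: losses, zone, and predicted winner
#'
#' Combines [loss_to_second()] for both actors with [classify_zone()] and
#' predicts the likely winner of the reproductive conflict: under equal
#' competitive abilities, the actor with the larger opportunity cost to not
#' reproducing first should be willing to expend more competitive effort and
#' so is the more likely winner. `winner` is `"no_conflict"` when neither
#' actor loses anything by moving second (zone 3, or an actor that prefers
#' the second-mover position), `"tie"` when both losses are positive and
#' equal within tolerance (the symmetric game at `c = 0`, `y = 1`), and
#' otherwise the actor with the strictly larger loss. `endogenous_timing` is
#' `TRUE` when some actor's loss is negative, i.e. both players agree on who
#' should move first. The abstention flags report whether each actor, as an
#' optimising first mover ([bruteforce_solve()]), would voluntarily forgo
#' reproducing; losses themselves follow the reproduce-first convention of
#' the piecewise sequential payoffs.
#'
#' @inheritParams sequential_outcome
#' @return Object of class `"conflict_analysis"`: `params`, `loss_parent`,
#'   `loss_adolescent`, `zone`, `zone_bounds`, `on_boundary`, `zone2_empty`,
#'   `winner`, `endogenous_timing`, `abstains_parent`, `abstains_adolescent`,
#'   `tol`.
#' @examples
#' predict_winner(game_params(0.2, 1, 1))  # parent wins: losses 0.25 vs 0
#' predict_winner(game_params(0.2, 0, 1))  # symmetric: tie
#' predict_winner(game_params(0.2, 0, 3))  # adolescent wins
#' @export
predict_winner <- function(params, tol = kc_tol()) {
  p <- as_game_params(params)
  lp <- loss_to_second("parent", p, tol = tol)
  la <- loss_to_second("adolescent", p, tol = tol)
  zn <- classify_zone(p, tol = tol)
  winner <- if (lp <= tol && la <= tol) {
    "no_conflict"
  } else if (abs(lp - la) <= tol) {
    "tie"
  } else if (lp > la) {
    "parent"
  } else {
    "adolescent"
  }
  structure(
    list(
      params = p,
      loss_parent = lp,
      loss_adolescent = la,
      zone = zn$zone,
      zone_bounds = zn$zone_bounds,
      on_boundary = zn$on_boundary,
      zone2_empty = zn$zone2_empty,
      winner = winner,
      endogenous_timing = (lp < -tol) || (la < -tol),
      abstains_parent = bruteforce_solve("parent", p, tol = tol)$first_mover_abstains,
      abstains_adolescent = bruteforce_solve("adolescent", p, tol = tol)$first_mover_abstains,
      tol = tol
    ),
    class = "conflict_analysis"
  )
}

#' @export
print.conflict_analysis <- function(x, digits = 4, ...) {
  p <- x$params
  cat(sprintf("conflict analysis at s = %g, c = %g, y = %g\n", p$s, p$c, p$y))
  cat(sprintf("  zone %d (bounds %.*f, %.*f)%s%s\n", x$zone,
              digits, x$zone_bounds[1], digits, x$zone_bounds[2],
              if (x$zone2_empty) "; zone 2 empty" else "",
              if (x$on_boundary) "; on a zone boundary" else ""))
  cat(sprintf("  loss to moving second: parent %.*f, adolescent %.*f\n",
              digits, x$loss_parent, digits, x$loss_adolescent))
  cat(sprintf("  predicted winner: %s\n", x$winner))
  if (x$endogenous_timing) {
    cat("  endogenous timing: some actor prefers to move second\n")
  }
  if (isTRUE(x$abstains_parent) || isTRUE(x$abstains_adolescent)) {
    who <- kc_roles[c(isTRUE(x$abstains_parent), isTRUE(x$abstains_adolescent))]
    cat(sprintf("  as optimising first mover, would abstain: %s\n",
                paste(who, collapse = ", ")))
  }
  invisible(x)
}
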