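#' Inclusive-fitness payoff for one actor and one action profile
#'
#' The conditional payoffs of the one-shot reproduction game. Writing
#' `V(own | other)` for an actor's payoff given its own action and the other
#' actor's action (R = reproduce, N = not), the parent (G1) receives
#' \deqn{V_1(R|R) = 0.5 s + 0.25 s y, \quad V_1(R|N) = 0.5, \quad
#'       V_1(N|R) = 0.25 y, \quad V_1(N|N) = 0,}
#' and the adolescent (G2)
#' \deqn{V_2(R|R) = 0.5 s y + 0.25 s (1 + c), \quad V_2(R|N) = 0.5 y, \quad
#'       V_2(N|R) = 0.25 (1 + c), \quad V_2(N|N) = 0.}
#' The first term of each expression is the actor's own reproduction weighted
#' by relatedness 0.5 (and quality `y` for the adolescent's infant); the
#' second is the other actor's infant weighted by 0.25 (grandchild) or the
#' expected sibling relatedness `0.25 (1 + c)`. When both reproduce, each
#' infant's survivorship is scaled by `s`.
#'
#' @param role `"parent"` or `"adolescent"`.
#' @param own This actor's action, `"R"` or `"N"`.
#' @param other The other actor's action, `"R"` or `"N"`.
#' @param params A [game_params()] object (or coercible).
#'
#' @return A single non-negative payoff in inclusive-fitness units.
#' @examples
#' payoff("parent", "R", "N", game_params(0.2, 0, 1))        # 0.5, always
#' payoff("parent", "R", "R", game_params(0.8, 0, 1))        # 0.6
#' payoff("adolescent", "R", "R", game_params(0.8, 0.5, 2))  # 1.1
#' @export
payoff <- function(role, own, other, params) {
  role <- match_role(role)
  own <- match_action(own, "own")
  other <- match_action(other, "other")
  p <- as_game_params(params)
  s <- p$s
  y <- p$y
  if (role == "parent") {
    if (own == "R" && other == "R") {
      0.5 * s + 0.25 * s * y
    } else if (own == "R") {
      0.5
    } else if (other == "R") {
      0.25 * y
    } else {
      0
    }
  } else {
    if (own == "R" && other == "R") {
      0.5 * s * y + 0.25 * s * (1 + p$c)
    } else if (own == "R") {
      0.5 * y
    } else if (other == "R") {
      0.25 * (1 + p$c)
    } else {
      0
    }
  }
}

#' Tabulate all eight conditional payoffs
#'
#' One row per (actor, own action, other action) combination, evaluated with
#' [payoff()].
#'
#' @inheritParams payoff
#' @return A data frame of class `"payoff_table"` with columns `actor`, `own`,
#'   `other`, `payoff` (8 rows).
#' @examples
#' payoff_table(game_params(0.2, 0, 1))
#' @export
payoff_table <- function(params) {
  p <- as_game_params(params)
  grid <- expand.grid(
    other = kc_actions, own = kc_actions, actor = kc_roles,
    stringsAsFactors = FALSE
  )[, c("actor", "own", "other")]
  grid$payoff <- mapply(
    function(a, o1, o2) payoff(a, o1, o2, p),
    grid$actor, grid$own, grid$other
  )
  rownames(grid) <- NULL
  structure(grid, class = c("payoff_table", "data.frame"), params = p)
}

#' @export
print.payoff_table <- function(x, digits = 4, ...) {
  p <- attr(x, "params")
  if (!is.null(p)) {
    cat(sprintf("conditional payoffs V(own | other) at s = %g, c = %g, y = %g\n",
                p$s, p$c, p$y))
  }
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  df$payoff <- round(df$payoff, digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

# fast lookup into a payoff_table (used by the brute-force solver, which is
# required to work from the tabulated payoffs alone)
pt_lookup <- function(tab, actor, own, other) {
  tab$payoff[tab$actor == actor & tab$own == own & tab$other == other]
}

#' Which actor does each prefer as the sole reproducer?
#'
#' When both actors agree that only one infant should be added to the
#' household, there can still be conflict over whose infant it is. The parent
#' prefers to be the sole reproducer iff `V1(R|N) > V1(N|R)`, i.e.
#' `0.5 > 0.25 y` (youth benefit below 2); the adolescent prefers herself iff
#' `V2(R|N) > V2(N|R)`, i.e. `0.5 y > 0.25 (1 + c)`. Equality within the
#' package tolerance is reported as indifference.
#'
#' @inheritParams payoff
#' @param tol Absolute tolerance for indifference; defaults to [kc_tol()].
#' @return `"self"`, `"other"`, or `"indifferent"`.
#' @examples
#' sole_reproducer_preference("parent", game_params(0.2, 0, 1))    # self
#' sole_reproducer_preference("parent", game_params(0.2, 0, 2))    # indifferent
#' sole_reproducer_preference("parent", game_params(0.2, 0, 3))    # other
#' @export
sole_reproducer_preference <- function(role, params, tol = kc_tol()) {
  role <- match_role(role)
  p <- as_game_params(params)
  diff <- payoff(role, "R", "N", p) - payoff(role, "N", "R", p)
  if (abs(diff) <= tol) {
    "indifferent"
  } else if (diff > 0) {
    "self"
  } else {
    "other"
  }
}
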