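#' Package-wide numerical tolerance
#'
#' A single absolute tolerance used everywhere an equality, indifference or
#' threshold decision is made (best responses, ties, zone boundaries). Set the
#' option `kinconflict.tol` to override the default of `1e-9`.
#'
#' @return A positive scalar tolerance.
#' @export
kc_tol <- function() {
  tol <- getOption("kinconflict.tol", 1e-9)
  stopifnot(is.numeric(tol), length(tol) == 1L, is.finite(tol), tol > 0)
  tol
}

# enumerations shared across the package
kc_roles <- c("parent", "adolescent")
kc_actions <- c("R", "N")

other_role <- function(role) if (role == "parent") "adolescent" else "parent"

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  x <- as.numeric(x)
  low_ok <- if (open_lower) x > lower else x >= lower
  up_ok <- if (open_upper) x < upper else x <= upper
  if (!low_ok || !up_ok) {
    stop(sprintf(
      "'%s' = %g is outside %s%g, %g%s", name, x,
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]"
    ), call. = FALSE)
  }
  x
}

match_role <- function(role) {
  if (!is.character(role) || length(role) != 1L || !role %in% kc_roles) {
    stop("'role' must be \"parent\" or \"adolescent\"", call. = FALSE)
  }
  role
}

match_action <- function(action, name = "action") {
  if (!is.character(action) || length(action) != 1L || !action %in% kc_actions) {
    stop(sprintf("'%s' must be \"R\" (reproduce) or \"N\" (not)", name),
         call. = FALSE)
  }
  action
}

#' Parameters of the intergenerational reproduction game
#'
#' Bundle and validate the three parameters that define one game instance.
#'
#' @param s Survival ratio: survivorship of an infant sharing the household
#'   with another infant relative to being the sole infant. Dimensionless, in
#'   `[0, 1]`; `1` means co-residence is costless.
#' @param c Parental continuity: probability that the parent reproduces with
#'   the same partner who produced the adolescent, so that the new infant is
#'   the adolescent's full (rather than half) sibling. In `[0, 1]`.
#' @param y Youth benefit: fitness of the adolescent's infant relative to the
#'   parent's infant. Strictly positive; `y > 1` encodes parental reproductive
#'   senescence, `y < 1` an advantage to the parent's reproduction.
#'
#' @return An object of class `"game_params"`: a named list with elements
#'   `s`, `c`, `y`.
#' @examples
#' game_params(s = 0.2, c = 0, y = 1)
#' @seealso [conflict_game()], [payoff()]
#' @export
game_params <- function(s, c, y) {
  s <- check_scalar(s, "s", 0, 1)
  cc <- check_scalar(c, "c", 0, 1)
  y <- check_scalar(y, "y", 0, Inf, open_lower = TRUE)
  structure(list(s = s, c = cc, y = y), class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("game parameters: s = %g, c = %g, y = %g\n", x$s, x$c, x$y))
  invisible(x)
}

#' Coerce to game parameters
#'
#' Accepts a `"game_params"` object, a named list, or a named numeric vector
#' with elements `s`, `c` and `y`.
#'
#' @param x Object to coerce.
#' @return A validated `"game_params"` object.
#' @export
as_game_params <- function(x) {
  if (inherits(x, "game_params")) {
    return(x)
  }
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.list(x)
  }
  if (is.list(x) && all(c("s", "c", "y") %in% names(x))) {
    return(game_params(x$s, x$c, x$y))
  }
  stop("cannot interpret 'params'; supply game_params(s, c, y)", call. = FALSE)
}

#' Relatedness weights used in the payoffs
#'
#' The coefficients of relatedness that weight each infant's fitness in an
#' actor's inclusive-fitness payoff: 0.5 to one's own offspring, 0.25 from a
#' grandparent to a grandchild, and an expected `0.25 * (1 + c)` from the
#' adolescent to the parent's new infant (0.5 if a full sibling, probability
#' `c`; 0.25 if a half sibling).
#'
#' @param c Parental continuity in `[0, 1]`.
#' @return Named list with `own_offspring`, `parent_to_grandchild`,
#'   `adolescent_to_sibling`.
#' @examples
#' relatedness_weights(0)$adolescent_to_sibling  # 0.25, half sibling certain
#' relatedness_weights(1)$adolescent_to_sibling  # 0.50, full sibling certain
#' @export
relatedness_weights <- function(c) {
  cc <- check_scalar(c, "c", 0, 1)
  list(
    own_offspring = 0.5,
    parent_to_grandchild = 0.25,
    adolescent_to_sibling = 0.25 * (1 + cc)
  )
}
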