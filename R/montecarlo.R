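# run expr with a private RNG stream: global .Random.seed is saved/restored
with_local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# vectorised generative household model; returns per-replicate payoffs
household_draws <- function(params, actions, n_reps, seed) {
  p <- as_game_params(params)
  parent_act <- match_action(actions[[1]], "parent action")
  adol_act <- match_action(actions[[2]], "adolescent action")
  n <- as.integer(n_reps)
  with_local_rng(seed, {
    two_infants <- parent_act == "R" && adol_act == "R"
    # sole infant survives with probability 1; co-resident infants survive
    # independently with marginal probability s each
    surv_parent <- if (parent_act == "R") {
      if (two_infants) stats::rbinom(n, 1L, p$s) else rep(1L, n)
    } else {
      rep(0L, n)
    }
    surv_adol <- if (adol_act == "R") {
      if (two_infants) stats::rbinom(n, 1L, p$s) else rep(1L, n)
    } else {
      rep(0L, n)
    }
    # the parent's new infant is the adolescent's full sibling (r = 0.5) with
    # probability c, else a half sibling (r = 0.25)
    r_sib <- if (parent_act == "R") {
      0.25 * (1 + stats::rbinom(n, 1L, p$c))
    } else {
      rep(0, n)
    }
    list(
      parent = 0.5 * surv_parent + 0.25 * p$y * surv_adol,
      adolescent = 0.5 * p$y * surv_adol + r_sib * surv_parent,
      r_sib = r_sib,
      surv_parent = surv_parent,
      surv_adol = surv_adol
    )
  })
}

analytic_payoffs <- function(params, actions) {
  p <- as_game_params(params)
  c(
    parent = payoff("parent", actions[[1]], actions[[2]], p),
    adolescent = payoff("adolescent", actions[[2]], actions[[1]], p)
  )
}

#' Monte Carlo validation of the analytic payoffs
#'
#' Simulates the generative household model behind the inclusive-fitness
#' payoffs: in each replicate every reproducing actor produces one infant; a
#' sole infant survives with probability 1 while two co-resident infants
#' survive independently with marginal probability `s` each; the parent's new
#' infant is a full sibling of the adolescent with probability `c` (half
#' sibling otherwise); each actor's realised payoff sums, over surviving
#' infants, relatedness times infant quality (quality `y` for the
#' adolescent's infant, 1 for the parent's). Averaging over replicates
#' recovers the analytic conditional payoffs, which are reported alongside
#' the estimates as standardised discrepancies.
#'
#' @param params A [game_params()] object (or coercible).
#' @param actions Length-2 character vector `(parent, adolescent)` of `"R"`
#'   or `"N"`.
#' @param n_reps Number of replicate households, `>= 1`.
#' @param seed Integer seed; the simulation uses a private RNG stream and
#'   leaves the global RNG state untouched. Fixed seed implies
#'   bit-reproducible output.
#' @return Object of class `"kc_sim_result"`: a list with `params`,
#'   `actions`, `n_reps`, `seed`, `mean_payoff_parent`,
#'   `mean_payoff_adolescent`, `se_parent`, `se_adolescent`,
#'   `analytic_parent`, `analytic_adolescent`, `z_parent`, `z_adolescent`,
#'   `mean_r_sib` (mean realised sibling relatedness, `NA` if the parent does
#'   not reproduce).
#' @examples
#' simulate_payoffs(game_params(0.8, 0.5, 2), c("R", "R"),
#'                  n_reps = 1e4, seed = 1)
#' @export
simulate_payoffs <- function(params, actions = c("R", "R"), n_reps, seed) {
  p <- as_game_params(params)
  n <- check_scalar(n_reps, "n_reps", 1, Inf)
  if (n != round(n)) stop("'n_reps' must be a whole number", call. = FALSE)
  draws <- household_draws(p, actions, n_reps = n, seed = seed)
  ana <- analytic_payoffs(p, actions)
  mom <- function(x) {
    m <- mean(x)
    se <- stats::sd(x) / sqrt(length(x))
    c(mean = m, se = se)
  }
  mp <- mom(draws$parent)
  ma <- mom(draws$adolescent)
  zval <- function(m, se, target) {
    if (se == 0) {
      if (abs(m - target) <= kc_tol()) 0 else Inf
    } else {
      (m - target) / se
    }
  }
  structure(
    list(
      params = p,
      actions = c(parent = actions[[1]], adolescent = actions[[2]]),
      n_reps = n,
      seed = as.integer(seed),
      mean_payoff_parent = unname(mp["mean"]),
      mean_payoff_adolescent = unname(ma["mean"]),
      se_parent = unname(mp["se"]),
      se_adolescent = unname(ma["se"]),
      analytic_parent = unname(ana["parent"]),
      analytic_adolescent = unname(ana["adolescent"]),
      z_parent = zval(mp["mean"], mp["se"], ana["parent"]),
      z_adolescent = zval(ma["mean"], ma["se"], ana["adolescent"]),
      mean_r_sib = if (actions[[1]] == "R") mean(draws$r_sib) else NA_real_
    ),
    class = "kc_sim_result"
  )
}

#' @export
print.kc_sim_result <- function(x, digits = 4, ...) {
  p <- x$params
  cat(sprintf(
    "household simulation: s = %g, c = %g, y = %g; actions (%s, %s); %d reps, seed %d\n",
    p$s, p$c, p$y, x$actions[["parent"]], x$actions[["adolescent"]],
    x$n_reps, x$seed
  ))
  cat(sprintf("  parent:     mean %.*f (se %.*f), analytic %.*f, z = %.2f\n",
              digits, x$mean_payoff_parent, digits, x$se_parent,
              digits, x$analytic_parent, x$z_parent))
  cat(sprintf("  adolescent: mean %.*f (se %.*f), analytic %.*f, z = %.2f\n",
              digits, x$mean_payoff_adolescent, digits, x$se_adolescent,
              digits, x$analytic_adolescent, x$z_adolescent))
  invisible(x)
}

#' Convergence of the household simulator toward the analytic payoffs
#'
#' Runs [simulate_payoffs()] at each parameter point for each replicate count
#' in a schedule and reports the absolute error of the estimated mean payoffs
#' against the analytic values; by the law of large numbers the error shrinks
#' as `O(1/sqrt(n_reps))` in expectation.
#'
#' @param grid Data frame with columns `s`, `c`, `y`, one row per parameter
#'   point.
#' @param actions Length-2 character vector `(parent, adolescent)`.
#' @param rep_schedule Increasing integer vector of replicate counts.
#' @param seed Integer base seed; each (point, count) cell gets its own
#'   deterministic sub-seed.
#' @return Data frame with one row per (grid point, replicate count):
#'   parameters, `n_reps`, absolute errors and standard errors per actor.
#' @examples
#' convergence_report(data.frame(s = 0.8, c = 0.5, y = 2),
#'                    rep_schedule = c(100, 10000), seed = 1)
#' @export
convergence_report <- function(grid, actions = c("R", "R"),
                               rep_schedule = c(100, 10000), seed = 1) {
  stopifnot(is.data.frame(grid), all(c("s", "c", "y") %in% names(grid)),
            all(rep_schedule >= 1))
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (n in rep_schedule) {
      k <- k + 1L
      # distinct, reproducible sub-seed per cell, kept within integer range
      sub_seed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
      sim <- simulate_payoffs(
        game_params(grid$s[i], grid$c[i], grid$y[i]),
        actions = actions, n_reps = n, seed = sub_seed
      )
      rows[[k]] <- data.frame(
        s = grid$s[i], c = grid$c[i], y = grid$y[i], n_reps = n,
        abs_err_parent = abs(sim$mean_payoff_parent - sim$analytic_parent),
        abs_err_adolescent = abs(sim$mean_payoff_adolescent - sim$analytic_adolescent),
        se_parent = sim$se_parent,
        se_adolescent = sim$se_adolescent
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
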