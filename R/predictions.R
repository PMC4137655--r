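#' Parental-absence effect on the adolescent's willingness to reproduce
#'
#' The adolescent reproduces after her parent has done so whenever the
#' survival ratio exceeds `(1 + c) / (2 y + 1 + c)`. With both genetic
#' parents present (`c = 1`, full siblings certain) this threshold is
#' `1 / (y + 1)`; with one parent absent (`c = 0`, half siblings certain) it
#' drops to `1 / (2 y + 1)`, so the adolescent reproduces over a wider range
#' of survival costs. The relative size of the absence effect is expressed as
#' the percent reduction of the parent-present threshold:
#' `100 * (threshold_present - threshold_absent) / threshold_present`, which
#' increases with the youth benefit and vanishes as `y` approaches 0.
#'
#' @param y Youth benefit value(s), each `> 0`. Vectorised.
#' @return Data frame with columns `y`, `threshold_present` (critical `s` at
#'   `c = 1`), `threshold_absent` (at `c = 0`) and `percent_difference`.
#' @examples
#' absence_effect(1)  # thresholds 1/2 vs 1/3; 33.33 %
#' absence_effect(3)  # thresholds 1/4 vs 1/7; 42.86 %
#' @export
absence_effect <- function(y) {
  if (!is.numeric(y) || length(y) < 1L || any(!is.finite(y)) || any(y <= 0)) {
    stop("'y' must be finite and > 0", call. = FALSE)
  }
  present <- vapply(y, function(yy)
    conflict_thresholds(game_params(0.5, 1, yy))$adolescent_adds_second, 0)
  absent <- vapply(y, function(yy)
    conflict_thresholds(game_params(0.5, 0, yy))$adolescent_adds_second, 0)
  data.frame(
    y = y,
    threshold_present = present,
    threshold_absent = absent,
    percent_difference = 100 * (present - absent) / present
  )
}

# Family-structure mapping: parental continuity, household flags and the
# predicted ordering of the adolescent's age at first birth (AFB).
kc_family_structures <- function() {
  data.frame(
    structure = c("two_genetic_parents", "parent_and_stepparent",
                  "widowed_single_parent", "other_single_parent"),
    c_value = c(1.0, 0.0, 0.0, 0.5),
    nonkin_present = c(FALSE, TRUE, FALSE, FALSE),
    mate_search_cost_parent = c("no", "no", "yes", "maybe"),
    predicted_afb_rank = c("latest", "intermediate", "earliest", "intermediate"),
    stringsAsFactors = FALSE
  )
}

#' Map a family household structure to game parameters
#'
#' Four stylised household structures differ in parental continuity `c` and
#' in two qualitative flags (presence of a non-kin actor, whether the
#' remaining parent faces mate-search costs), and carry an ordinal prediction
#' for the adolescent's age at first birth: two genetic parents (`c ~ 1`,
#' latest AFB), parent plus stepparent (`c ~ 0`, intermediate), widowed
#' single parent (`c = 0`, earliest), and other single parent such as a
#' separated or labour-migrant partner (`c > 0`, here defaulting to 0.5,
#' intermediate). The qualitative entries `~1` and `>0` are mapped to the
#' concrete defaults 1.0 and 0.5; use `c_override` to supply another value.
#' The flags are metadata only and never alter payoffs.
#'
#' @param structure One of `"two_genetic_parents"`, `"parent_and_stepparent"`,
#'   `"widowed_single_parent"`, `"other_single_parent"`.
#' @param c_override Optional parental continuity in `[0, 1]` replacing the
#'   default for the structure.
#' @return List with `structure`, `c` (parental continuity),
#'   `nonkin_present`, `mate_search_cost_parent` (`"no"`/`"yes"`/`"maybe"`),
#'   `predicted_afb_rank` (`"latest"`/`"intermediate"`/`"earliest"`).
#' @examples
#' family_structure_params("widowed_single_parent")
#' family_structure_params("other_single_parent", c_override = 0.3)
#' @export
family_structure_params <- function(structure, c_override = NULL) {
  tab <- kc_family_structures()
  i <- match(structure, tab$structure)
  if (length(structure) != 1L || is.na(i)) {
    stop(sprintf("unknown family structure; expected one of: %s",
                 paste(tab$structure, collapse = ", ")), call. = FALSE)
  }
  cc <- if (is.null(c_override)) tab$c_value[i] else check_scalar(c_override, "c_override", 0, 1)
  list(
    structure = tab$structure[i],
    c = cc,
    nonkin_present = tab$nonkin_present[i],
    mate_search_cost_parent = tab$mate_search_cost_parent[i],
    predicted_afb_rank = tab$predicted_afb_rank[i]
  )
}

#' Family-structure summary table
#'
#' The full mapping used by [family_structure_params()], one row per
#' household structure.
#'
#' @return Data frame with columns `structure`, `c_value`, `nonkin_present`,
#'   `mate_search_cost_parent`, `predicted_afb_rank`.
#' @export
family_structure_table <- function() {
  kc_family_structures()
}

#' Check the predicted age-at-first-birth ordering across family structures
#'
#' Uses the adolescent's fitness loss to moving second as a proxy for her
#' incentive to reproduce early: the larger the loss, the stronger the
#' pressure toward an earlier first birth. For the given survival ratio and
#' youth benefit, computes that loss under each structure's parental
#' continuity and verifies that it is weakly larger for structures with
#' earlier predicted AFB (latest -> intermediate -> earliest must be
#' non-decreasing in loss). The two intermediate-ranked structures are not
#' ordered against each other.
#'
#' @param structures Character vector of structure identifiers (default: all
#'   four).
#' @param s Survival ratio; must place at least one structure in zone 1 or 2
#'   (a conflict must exist, otherwise the ordering is undefined and an error
#'   is signalled).
#' @param y Youth benefit.
#' @param tol Absolute tolerance; defaults to [kc_tol()].
#' @return List with `table` (data frame: `structure`, `c`,
#'   `predicted_afb_rank`, `zone`, `adolescent_loss`) and logical
#'   `consistent`.
#' @examples
#' afb_rank_consistency(s = 0.2, y = 1)$consistent  # TRUE
#' @export
afb_rank_consistency <- function(structures = family_structure_table()$structure,
                                 s, y, tol = kc_tol()) {
  info <- lapply(structures, family_structure_params)
  rows <- lapply(info, function(fs) {
    p <- game_params(s, fs$c, y)
    data.frame(
      structure = fs$structure,
      c = fs$c,
      predicted_afb_rank = fs$predicted_afb_rank,
      zone = classify_zone(p, tol = tol)$zone,
      adolescent_loss = loss_to_second("adolescent", p, tol = tol),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (all(tab$zone == 3L)) {
    stop("no conflict at these (s, y): every structure lies in zone 3, ",
         "so the AFB ordering is undefined", call. = FALSE)
  }
  rank_level <- c(latest = 1, intermediate = 2, earliest = 3)
  lev <- rank_level[tab$predicted_afb_rank]
  consistent <- TRUE
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(tab))) {
      if (lev[i] < lev[j] &&
          tab$adolescent_loss[j] < tab$adolescent_loss[i] - tol) {
        consistent <- FALSE
      }
    }
  }
  list(table = tab, consistent = consistent)
}

# one fully analysed record per (s, c, y) row
sweep_points <- function(grid, tol = kc_tol()) {
  stopifnot(is.data.frame(grid), all(c("s", "c", "y") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- game_params(grid$s[i], grid$c[i], grid$y[i])
    th <- conflict_thresholds(p)
    an <- predict_winner(p, tol = tol)
    data.frame(
      s = p$s, c = p$c, y = p$y,
      adolescent_adds_second = th$adolescent_adds_second,
      parent_wants_adolescent_second = th$parent_wants_adolescent_second,
      parent_adds_second = th$parent_adds_second,
      adolescent_wants_parent_second = th$adolescent_wants_parent_second,
      loss_parent = an$loss_parent,
      loss_adolescent = an$loss_adolescent,
      zone = an$zone,
      zone_lower = an$zone_bounds[1],
      zone_upper = an$zone_bounds[2],
      winner = an$winner,
      endogenous_timing = an$endogenous_timing,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the parameter space
#'
#' Evaluates the full conflict analysis (all four thresholds, both losses,
#' zone and predicted winner) on the Cartesian grid of the supplied parameter
#' values. Deterministic, one row per grid point, ready for plotting or CSV
#' export; this is the engine behind the threshold-curve, loss-profile and
#' absence-effect figure data.
#'
#' @param s,c,y Numeric vectors of parameter values (each within its valid
#'   range). Scalars hold that parameter fixed.
#' @param tol Absolute tolerance; defaults to [kc_tol()].
#' @return Data frame with `length(s) * length(c) * length(y)` rows and
#'   columns `s`, `c`, `y`, the four thresholds, `loss_parent`,
#'   `loss_adolescent`, `zone`, `zone_lower`, `zone_upper`, `winner`,
#'   `endogenous_timing`.
#' @examples
#' head(conflict_sweep(s = seq(0, 1, 0.25), c = 0.25, y = 1))
#' @export
conflict_sweep <- function(s, c = 0, y = 1, tol = kc_tol()) {
  if (!is.numeric(s) || !is.numeric(c) || !is.numeric(y)) {
    stop("'s', 'c' and 'y' must be numeric", call. = FALSE)
  }
  grid <- expand.grid(s = s, c = c, y = y, KEEP.OUT.ATTRS = FALSE)
  sweep_points(grid, tol = tol)
}
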