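test_that("closed-form thresholds match their defining payoff comparisons", {
  th <- conflict_thresholds(game_params(0.5, 0, 1))
  expect_equal(th$adolescent_adds_second, 1 / 3)
  expect_equal(th$parent_wants_adolescent_second, 2 / 3)
  expect_equal(th$parent_adds_second, 1 / 3)
  expect_equal(th$adolescent_wants_parent_second, 2 / 3)
  th11 <- conflict_thresholds(game_params(0.5, 1, 1))
  expect_equal(th11$adolescent_adds_second, 0.5)
  expect_equal(th11$parent_adds_second, 1 / 3)
  # very large youth benefit: the adolescent adds a second infant almost always
  expect_lt(conflict_thresholds(game_params(0.5, 1, 1e6))$adolescent_adds_second, 1e-5)

  # thresholds lie in (0, 1) and respond to c and y as expected
  pts <- random_params(200, seed = 3)
  prev <- NULL
  for (i in seq_len(nrow(pts))) {
    thi <- unlist(conflict_thresholds(game_params(0.5, pts$c[i], pts$y[i])))
    expect_true(all(thi > 0 & thi < 1))
  }
  c_grid <- seq(0, 1, by = 0.1)
  a_in_c <- vapply(c_grid, function(cc)
    conflict_thresholds(game_params(0.5, cc, 1.2))$adolescent_adds_second, 0)
  expect_true(all(diff(a_in_c) > 0))
  y_grid <- seq(0.5, 4, by = 0.25)
  a_in_y <- vapply(y_grid, function(y)
    conflict_thresholds(game_params(0.5, 0.4, y))$adolescent_adds_second, 0)
  expect_true(all(diff(a_in_y) < 0))
})

test_that("best responses flip exactly at the closed-form thresholds", {
  # examples around the symmetric-case threshold of 1/3
  expect_identical(best_response("adolescent", "R", game_params(0.9, 0, 1))$action, "R")
  expect_identical(best_response("adolescent", "R", game_params(0.2, 0, 1))$action, "N")
  # reproducing alone always beats doing nothing
  for (role in c("parent", "adolescent")) {
    br <- best_response(role, "N", game_params(0.1, 0.5, 0.4))
    expect_identical(br$action, "R")
    expect_false(br$tie)
  }
  # exact indifference resolves to N with the tie flag
  br_tie <- best_response("adolescent", "R", game_params(1 / 3, 0, 1))
  expect_identical(br_tie$action, "N")
  expect_true(br_tie$tie)

  # bisection on s brackets each threshold to tolerance
  set.seed(42)
  for (rep in 1:25) {
    cc <- runif(1)
    y <- runif(1, 0.2, 4)
    p0 <- game_params(0.5, cc, y)
    cases <- list(
      list(role = "adolescent", other = "R",
           target = conflict_thresholds(p0)$adolescent_adds_second),
      list(role = "parent", other = "R",
           target = conflict_thresholds(p0)$parent_adds_second)
    )
    for (cs in cases) {
      lo <- 0
      hi <- 1
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        act <- best_response(cs$role, cs$other, game_params(mid, cc, y))$action
        if (act == "R") hi <- mid else lo <- mid
      }
      expect_equal(hi, cs$target, tolerance = 1e-6)
    }
  }
})

test_that("sequential outcomes follow the piecewise payoffs branch-for-branch", {
  out_p <- sequential_outcome("parent", game_params(0.2, 0, 1))
  expect_identical(out_p$second_action, "N")
  expect_equal(out_p$payoff_parent, 0.5)
  expect_equal(out_p$payoff_adolescent, 0.25)
  expect_equal(out_p$n_infants, 1L)

  out_a <- sequential_outcome("adolescent", game_params(0.2, 0, 1))
  expect_identical(out_a$second_action, "N")
  expect_equal(out_a$payoff_adolescent, 0.5)
  expect_equal(out_a$payoff_parent, 0.25)

  for (fm in c("parent", "adolescent")) {
    out3 <- sequential_outcome(fm, game_params(0.9, 0, 1))
    expect_identical(out3$second_action, "R")
    expect_equal(out3$n_infants, 2L)
    expect_equal(out3$payoff_parent, 0.5 * 0.9 + 0.25 * 0.9)
    expect_equal(out3$payoff_adolescent, 0.5 * 0.9 + 0.25 * 0.9)
  }

  # piecewise structure checked against the raw payoffs on random draws
  pts <- random_params(300, seed = 9)
  for (i in seq_len(nrow(pts))) {
    if (!away_from_boundaries(pts$s[i], pts$c[i], pts$y[i])) next
    p <- game_params(pts$s[i], pts$c[i], pts$y[i])
    th <- conflict_thresholds(p)
    op <- sequential_outcome("parent", p)
    if (pts$s[i] > th$adolescent_adds_second) {
      expect_equal(op$payoff_parent, payoff("parent", "R", "R", p))
      expect_equal(op$payoff_adolescent, payoff("adolescent", "R", "R", p))
    } else {
      expect_equal(op$payoff_parent, 0.5)
      expect_equal(op$payoff_adolescent, 0.25 * (1 + pts$c[i]))
    }
    oa <- sequential_outcome("adolescent", p)
    if (pts$s[i] > th$parent_adds_second) {
      expect_equal(oa$payoff_parent, payoff("parent", "R", "R", p))
    } else {
      expect_equal(oa$payoff_parent, 0.25 * pts$y[i])
      expect_equal(oa$payoff_adolescent, 0.5 * pts$y[i])
    }
  }
})

test_that("brute-force backward induction agrees with the closed-form solution", {
  pts <- random_params(10000, seed = 101)
  checked <- 0L
  for (i in seq_len(nrow(pts))) {
    if (!away_from_boundaries(pts$s[i], pts$c[i], pts$y[i])) next
    p <- game_params(pts$s[i], pts$c[i], pts$y[i])
    for (fm in c("parent", "adolescent")) {
      bf <- bruteforce_solve(fm, p)
      cf <- sequential_outcome(fm, p)
      # the second-stage (subgame) response to R always agrees
      if (!bf$first_mover_abstains) {
        expect_identical(bf$second_action, cf$second_action)
        expect_identical(bf$payoff_parent, cf$payoff_parent)
        expect_identical(bf$payoff_adolescent, cf$payoff_adolescent)
      } else {
        # abstention must strictly improve on the forced-reproduce outcome
        field <- paste0("payoff_", fm)
        expect_gt(bf[[field]], cf[[field]])
      }
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 9000L)
})

test_that("a first-moving parent forgoes reproduction under strong senescence", {
  bf3 <- bruteforce_solve("parent", game_params(0.2, 0, 3))
  expect_identical(bf3$first_action, "N")
  expect_identical(bf3$second_action, "R")
  expect_true(bf3$first_mover_abstains)
  bf19 <- bruteforce_solve("parent", game_params(0.2, 0, 1.9))
  expect_identical(bf19$first_action, "R")
  expect_false(bf19$first_mover_abstains)
})

test_that("losses to moving second reproduce the worked cases", {
  expect_equal(loss_to_second("parent", game_params(0.2, 0, 1)), 0.25)
  expect_equal(loss_to_second("adolescent", game_params(0.2, 0, 1)), 0.25)
  # full siblings certain: the adolescent is indifferent
  expect_equal(loss_to_second("adolescent", game_params(0.2, 1, 1)), 0)
  # zone 3: both reproduce regardless of order, nobody loses anything
  expect_equal(loss_to_second("parent", game_params(0.9, 0, 1)), 0)
  expect_equal(loss_to_second("adolescent", game_params(0.9, 0, 1)), 0)
})

test_that("the symmetric game has equal losses for every s", {
  for (s in seq(0, 1, by = 0.05)) {
    expect_equal(loss_to_second("parent", game_params(s, 0, 1)),
                 loss_to_second("adolescent", game_params(s, 0, 1)))
  }
})

test_that("zone classification matches the two critical bounds", {
  z2 <- classify_zone(game_params(0.4, 1, 1))
  expect_identical(z2$zone, 2L)
  expect_equal(z2$zone_bounds, c(1 / 3, 1 / 2))
  expect_false(z2$zone2_empty)

  for (cc in c(0, 0.5, 1)) {
    expect_identical(classify_zone(game_params(0.9, cc, 1))$zone, 3L)
    # zone 2 collapses exactly at y = sqrt(1 + c)
    zc <- classify_zone(game_params(0.5, cc, sqrt(1 + cc)))
    expect_true(zc$zone2_empty)
    expect_lt(diff(zc$zone_bounds), 1e-12)
  }

  # a point exactly on a bound goes to the lower-numbered zone, flagged
  zb <- classify_zone(game_params(1 / 3, 0, 1))
  expect_identical(zb$zone, 1L)
  expect_true(zb$on_boundary)
  expect_false(classify_zone(game_params(0.2, 0, 1))$on_boundary)
})

test_that("zone 1 yields exactly one reproducer; zone 3 nullifies losses", {
  pts <- random_params(400, seed = 17)
  for (i in seq_len(nrow(pts))) {
    if (!away_from_boundaries(pts$s[i], pts$c[i], pts$y[i])) next
    p <- game_params(pts$s[i], pts$c[i], pts$y[i])
    z <- classify_zone(p)$zone
    if (z == 1L) {
      expect_equal(sequential_outcome("parent", p)$n_infants, 1L)
      expect_equal(sequential_outcome("adolescent", p)$n_infants, 1L)
    } else if (z == 3L) {
      expect_equal(loss_to_second("parent", p), 0)
      expect_equal(loss_to_second("adolescent", p), 0)
    }
  }
})

test_that("the order of the zone bounds flips at y = sqrt(1 + c)", {
  for (cc in c(0, 0.25, 0.6, 1)) {
    flip <- sqrt(1 + cc)
    below <- conflict_thresholds(game_params(0.5, cc, flip - 0.05))
    above <- conflict_thresholds(game_params(0.5, cc, flip + 0.05))
    expect_gt(below$adolescent_adds_second, below$parent_adds_second)
    expect_lt(above$adolescent_adds_second, above$parent_adds_second)
  }
})

test_that("the winner prediction follows the larger loss", {
  expect_identical(predict_winner(game_params(0.2, 1, 1))$winner, "parent")
  expect_identical(predict_winner(game_params(0.2, 0, 1))$winner, "tie")
  expect_identical(predict_winner(game_params(0.2, 0, 3))$winner, "adolescent")
  a3 <- predict_winner(game_params(0.9, 0, 1))
  expect_identical(a3$winner, "no_conflict")
  expect_identical(a3$zone, 3L)
  # zone-1 division of the spoils: the parent loses less once y > (3 + c)/3
  for (cc in c(0, 0.5, 1)) {
    s1 <- 0.05  # zone 1 for all tested y
    lo <- predict_winner(game_params(s1, cc, (3 + cc) / 3 - 0.1))
    hi <- predict_winner(game_params(s1, cc, (3 + cc) / 3 + 0.1))
    expect_gte(lo$loss_parent, lo$loss_adolescent)
    expect_gt(hi$loss_adolescent, hi$loss_parent)
  }
})

test_that("endogenous timing appears where an actor prefers moving second", {
  # zone 2 at y = 1: the adolescent's loss is negative
  an <- predict_winner(game_params(0.36, 0.25, 1))
  expect_identical(an$zone, 2L)
  expect_gt(an$loss_parent, 0)
  expect_lt(an$loss_adolescent, 0)
  expect_true(an$endogenous_timing)
  expect_identical(an$winner, "parent")
  # a symmetric zone-1 point has no timing agreement
  expect_false(predict_winner(game_params(0.2, 0, 1))$endogenous_timing)
})

test_that("winner margins are monotone in c and y", {
  # zone 1, y = 1: parent's margin is non-decreasing in parental continuity
  margins_c <- vapply(seq(0, 1, by = 0.1), function(cc) {
    an <- predict_winner(game_params(0.2, cc, 1))
    an$loss_parent - an$loss_adolescent
  }, 0)
  expect_true(all(diff(margins_c) >= -1e-12))
  # zone 1, fixed c: adolescent's margin is non-decreasing in youth benefit
  margins_y <- vapply(seq(0.5, 2.5, by = 0.1), function(y) {
    an <- predict_winner(game_params(0.05, 0.5, y))
    an$loss_adolescent - an$loss_parent
  }, 0)
  expect_true(all(diff(margins_y) >= -1e-12))
})
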