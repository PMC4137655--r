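#' Threshold-curve data: when should a second infant be added?
#'
#' For each youth benefit, the critical survival ratio above which each actor
#' wants a second infant in the household, as a function of parental
#' continuity `c`, under both conditioning scenarios: given the parent has
#' reproduced (adolescent's own threshold `(1+c)/(2y+1+c)` vs the parent's
#' wish `2/(y+2)`, which is flat in `c`) and given the adolescent has
#' reproduced (parent's own threshold `y/(y+2)` vs the adolescent's wish
#' `2y/(2y+1+c)`).
#'
#' @param y_values Youth benefits, one per panel row.
#' @param c_grid Grid of parental-continuity values.
#' @return Data frame with columns `scenario`
#'   (`"parent_reproduced_first"`/`"adolescent_reproduced_first"`), `y`, `c`,
#'   `threshold_mover` (the second mover's own threshold) and
#'   `threshold_bystander` (the first mover's preference threshold).
#' @export
fig1_data <- function(y_values = c(0.3, 1, 3), c_grid = seq(0, 1, by = 0.01)) {
  rows <- list()
  k <- 0L
  for (y in y_values) {
    for (cc in c_grid) {
      th <- conflict_thresholds(game_params(0.5, cc, y))
      k <- k + 1L
      rows[[k]] <- data.frame(
        scenario = c("parent_reproduced_first", "adolescent_reproduced_first"),
        y = y, c = cc,
        threshold_mover = c(th$adolescent_adds_second, th$parent_adds_second),
        threshold_bystander = c(th$parent_wants_adolescent_second,
                                th$adolescent_wants_parent_second),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# panel map for the loss-profile figure: columns-major over c, with youth
# benefits (0.3, 1, sqrt(1+c), 3) within each c
kc_fig2_panels <- function(c_values = c(0.25, 1)) {
  rows <- list()
  for (i in seq_along(c_values)) {
    cc <- c_values[i]
    rows[[i]] <- data.frame(
      c = cc,
      y = c(0.3, 1, sqrt(1 + cc), 3),
      y_label = c("0.3", "1", "sqrt(1+c)", "3"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$panel <- LETTERS[seq_len(nrow(out))]
  rownames(out) <- NULL
  out[, c("panel", "c", "y", "y_label")]
}

#' Fitness-loss profile data over the survival ratio
#'
#' Each actor's loss to moving second as a function of `s`, for eight panels
#' crossing low and high parental continuity with four youth benefits
#' (including `y = sqrt(1+c)`, where zone 2 collapses and the actors never
#' disagree about the infant count). Panels are lettered A–H column-major
#' over `c` (A–D: `c = 0.25`; E–H: `c = 1`; `y` in order 0.3, 1,
#' `sqrt(1+c)`, 3 within each).
#'
#' @param c_values Parental-continuity values (one panel column each).
#' @param s_grid Grid of survival ratios.
#' @param tol Absolute tolerance; defaults to [kc_tol()].
#' @return Data frame with columns `panel`, `c`, `y`, `y_label`, `s`,
#'   `loss_parent`, `loss_adolescent`, `zone`, `zone_lower`, `zone_upper`,
#'   `winner`.
#' @export
fig2_data <- function(c_values = c(0.25, 1), s_grid = seq(0, 1, by = 0.01),
                      tol = kc_tol()) {
  panels <- kc_fig2_panels(c_values)
  rows <- lapply(seq_len(nrow(panels)), function(i) {
    sw <- conflict_sweep(s = s_grid, c = panels$c[i], y = panels$y[i], tol = tol)
    data.frame(
      panel = panels$panel[i], c = sw$c, y = sw$y,
      y_label = panels$y_label[i], s = sw$s,
      loss_parent = sw$loss_parent, loss_adolescent = sw$loss_adolescent,
      zone = sw$zone, zone_lower = sw$zone_lower, zone_upper = sw$zone_upper,
      winner = sw$winner,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parental-absence effect-size data over the youth benefit
#'
#' [absence_effect()] evaluated on a grid of youth benefits, with the two
#' `y` values above which the parent becomes the more reticent second mover
#' (`y = sqrt(1+c)`, i.e. 1 at `c = 0` and `sqrt(2)` at `c = 1`) attached as
#' attribute `"flip_points"`.
#'
#' @param y_grid Grid of youth benefits (all `> 0`).
#' @return Data frame as from [absence_effect()].
#' @export
fig3_data <- function(y_grid = seq(0.05, 5, by = 0.05)) {
  out <- absence_effect(y_grid)
  attr(out, "flip_points") <- c(c0 = 1, c1 = sqrt(2))
  out
}

#' Plot the loss-profile panels
#'
#' Base-graphics rendering of [fig2_data()]: one panel per (c, y)
#' combination, parent solid, adolescent dotted, zone bounds dashed.
#'
#' @param data Output of [fig2_data()].
#' @param ... Passed to [graphics::plot()].
#' @return `data`, invisibly.
#' @export
plot_loss_profiles <- function(data = fig2_data(), ...) {
  panels <- unique(data$panel)
  old <- graphics::par(mfrow = c(ceiling(length(panels) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (pn in panels) {
    d <- data[data$panel == pn, ]
    graphics::plot(d$s, d$loss_parent, type = "l", lty = 1,
                   ylim = range(c(d$loss_parent, d$loss_adolescent)),
                   xlab = "survival ratio s", ylab = "loss to moving second",
                   main = sprintf("(%s) c = %g, y = %.3g", pn, d$c[1], d$y[1]),
                   ...)
    graphics::lines(d$s, d$loss_adolescent, lty = 3, col = 2)
    graphics::abline(h = 0, col = "grey70")
    graphics::abline(v = unique(c(d$zone_lower, d$zone_upper)),
                     lty = 2, col = "grey50")
  }
  invisible(data)
}

#' Plot the parental-absence effect curves
#'
#' Threshold survival ratios at `c = 1` and `c = 0` against the youth
#' benefit, with the percent difference on a secondary axis.
#'
#' @param data Output of [fig3_data()].
#' @param ... Passed to [graphics::plot()].
#' @return `data`, invisibly.
#' @export
plot_absence_effect <- function(data = fig3_data(), ...) {
  graphics::plot(data$y, data$threshold_present, type = "l", col = "darkgreen",
                 ylim = c(0, 1), xlab = "youth benefit y",
                 ylab = "threshold survival ratio s", ...)
  graphics::lines(data$y, data$threshold_absent, col = "red")
  graphics::lines(data$y, data$percent_difference / 100, lty = 3, col = "grey40")
  graphics::abline(v = attr(data, "flip_points"), lty = 2, col = "grey70")
  graphics::axis(4, at = seq(0, 1, 0.25), labels = seq(0, 100, 25))
  graphics::mtext("percent difference", side = 4, line = 2)
  graphics::legend("topright",
                   legend = c("c = 1 (parent present)", "c = 0 (parent absent)",
                              "percent difference"),
                   col = c("darkgreen", "red", "grey40"),
                   lty = c(1, 1, 3), bty = "n")
  invisible(data)
}
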