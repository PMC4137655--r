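# Independent literal transcription of the conditional payoffs, kept separate
# from the package implementation so the two can be checked against each
# other. Returns all eight V(own | other) values.
oracle_payoffs <- function(s, c, y) {
  list(
    parent = c(
      RR = 0.5 * s + 0.25 * s * y,
      RN = 0.5,
      NR = 0.25 * y,
      NN = 0
    ),
    adolescent = c(
      RR = 0.5 * s * y + 0.25 * s * (1 + c),
      RN = 0.5 * y,
      NR = 0.25 * (1 + c),
      NN = 0
    )
  )
}

# random valid parameter draws for property tests
random_params <- function(n, seed, y_max = 5) {
  set.seed(seed)
  data.frame(
    s = runif(n),
    c = runif(n),
    y = runif(n, min = 1e-3, max = y_max)
  )
}

# TRUE when s is at least `margin` away from every critical threshold and
# from the first-mover indifference points (so strict-inequality conventions
# cannot flip a comparison)
away_from_boundaries <- function(s, c, y, margin = 1e-6) {
  th <- unlist(conflict_thresholds(game_params(0.5, c, y)))
  all(abs(s - th) > margin) &&
    abs(0.5 - 0.25 * y) > margin &&            # parent sole-reproducer tie
    abs(0.5 * y - 0.25 * (1 + c)) > margin     # adolescent sole-reproducer tie
}
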