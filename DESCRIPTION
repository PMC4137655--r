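Package: kinconflict
Title: Inclusive-Fitness Games of Intergenerational Reproductive Conflict
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the hawk-dove style reproductive conflict between a parent
    and her adolescent offspring when household resources constrain how many
    infants can be raised at once. Computes inclusive-fitness payoffs for each
    actor as a function of the infant survival ratio under reproductive overlap
    (s), parental continuity (c, the probability that the parent's next infant
    is a full sibling of the adolescent), and the youth benefit (y, the
    relative quality of the adolescent's infant under parental senescence).
    Solves the sequential reproduce/not-reproduce game by backward induction,
    classifies the parameter space into conflict zones, predicts the likely
    winner from each actor's fitness loss to moving second, derives parental
    absence effect sizes on the adolescent's willingness to reproduce, and
    validates the analytic payoffs with a seeded stochastic household
    simulator. Includes a command-line interface for reproducing the model's
    threshold curves, fitness-loss profiles, and family-structure predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
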