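Package: zfsocial
Title: Trajectory-Based Quantification of Larval Zebrafish Social Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies social behavior of larval zebrafish from per-frame
    trajectory streams. Implements the biological-motion social index (SI), an
    attraction statistic that compares the observed animal-dot distance with a
    chance expectation obtained by time-shifting the animal trajectory against
    the stimulus; split-dyad orienting and place-preference metrics with the
    motion-based exclusion rule; open-field speed and thigmotaxis; looming-dot
    escape detection and response curves; and a stunted-growth classifier.
    Because published trajectory recordings of this kind are rarely deposited,
    the package ships a seeded generator of bout-swimming agents with tunable
    social attraction, knot-path dot stimuli, split-dyad pairs, looming
    sessions with planted escapes, and body-length cohorts, so every metric
    can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
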