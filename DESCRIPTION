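Package: habitspectra
Title: Behavioral Spectra from Activity Logs and Habit-Personality Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes ordered, timed daily-activity sequences as Fourier-series
    "behavioral spectra", summarises each spectrum by five variability features
    (mean, standard deviation, variance, lag-1 autocorrelation, spectral
    entropy), clusters spectra and ten-item personality-inventory (TIPI) scores
    separately with k-means, and quantifies the agreement between the two
    two-group clusterings by an association rate and a phi coefficient. Includes
    uncentered explained-variance curves with elbow-based model selection, a
    synthetic cohort generator with a tunable coupling between latent
    neuroticism and activity switching, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
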