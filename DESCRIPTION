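Package: bypasstrain
Title: Quantitative Training Assessment for Upper-Limb Bypass Prosthesis Users
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and longitudinal analysis of training outcomes for
    able-bodied users of body-powered bypass prostheses. Converts timed
    performance on a 22-task modified Southampton Hand Assessment Procedure
    into scaled task scores, per-pattern linear indexes of functionality
    (LIF), and a weighted summary index (wLIF), and averages Box and Blocks
    Test trials. Fits inverse learning curves Y = a - b/X to session score
    series, derives a training endpoint at 90% of the learning plateau,
    computes paired-session effect sizes with magnitude classification, and
    quantifies terminal-device prepositioning from orientation-quadrant
    records via session-centred scores, grouping by quadrant-change count,
    and linear regression. Includes a synthetic-cohort generator emulating
    the longitudinal study design so the full pipeline is testable without
    subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
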