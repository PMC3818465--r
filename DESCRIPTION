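Package: articudev
Title: Developmental Analysis of Serial Order in Child Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the serial ordering of consonants develops
    in longitudinal child-speech corpora. Extracts consonant-vowel-consonant
    (CVC) units from phonemic transcriptions (CHILDES CHAT files or a plain
    tabular dialect), classifies them by place of articulation into nine
    ordered categories, and computes per-month developmental measures:
    repetition ratio, fronting index, intra-organ and inter-organ
    articulation ratios, and mean CVCV durations. Developmental trajectories
    are fitted with Bayesian radial-basis-function kernel regression using
    evidence-approximation hyperparameter updates and leave-one-out bandwidth
    selection, then max-normalized so that developmental onsets (curve
    exceeding 1/3), offsets (exceeding 2/3), peak months and curve
    intersections can be quantified. A seeded synthetic-corpus generator
    with closed-form ground-truth trajectories supports end-to-end
    parameter-recovery experiments without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
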