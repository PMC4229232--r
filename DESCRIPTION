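Package: mskuq
Title: Probabilistic Sensitivity Analysis of Subject-Specific Musculoskeletal Gait Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds articulated lower-limb musculoskeletal models from anatomical
    landmarks, simulates the stance phase of gait (inverse kinematics, inverse
    dynamics, static optimization of muscle redundancy, joint reaction analysis),
    and quantifies how uncertainty in landmark positions, musculotendon geometry
    and maximum muscle tension propagates to joint angles, moments, muscle forces
    and joint contact forces via Latin-hypercube Monte-Carlo sampling, with
    convergence monitoring, ensemble band statistics and input-output correlation
    analysis. Includes a synthetic-data generator producing template models and
    dynamically consistent gait trials so the whole pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
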