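Package: rulagree
Title: RULA Postural Risk Scoring and Inter-Method Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deterministic Rapid Upper Limb Assessment (RULA) scoring from
    joint angles, with two acquisition front-ends: two-plane 2D pose
    keypoint snapshots (17-keypoint COCO/MoveNet layout) and joint-angle
    time series as produced by inertial measurement unit (IMU) motion
    capture, the latter aggregated by the relative time spent in each RULA
    level. Includes inter-method agreement statistics (Cohen's weighted
    kappa with asymptotic confidence intervals, Bland-Altman limits of
    agreement, Mann-Whitney U with rank-biserial effect size, Bonferroni
    correction, Shapiro-Wilk normality screening, post hoc power for a
    point-biserial correlation) and a synthetic cohort simulator of seated
    static work postures with tunable inter-method noise for validation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
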