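Package: gadadyn
Title: Dynamic Joint Longitudinal-Multistate Modelling of Islet Autoantibody
    Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of longitudinal biomarker trajectories and
    multistate disease progression for children who seroconvert to GADA as
    their first islet autoantibody. Longitudinal autoantibody titers and
    metabolic variables are modelled by spline mixed-effects models; the
    progression from single GADA through multiple islet autoantibodies
    (without and with IA-2A) to type 1 diabetes is modelled by a four-state
    proportional-hazards multistate model with LASSO variable selection;
    the coupled joint model yields dynamic, individually updatable
    predictions of state-occupation probabilities. Includes a calibrated
    synthetic-cohort generator emulating a TEDDY-like GADA-first cohort so
    the whole pipeline can be exercised and validated without access to
    restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    glmnet,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
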