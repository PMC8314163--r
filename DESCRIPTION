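Package: depsense
Title: Digital Biomarkers of Depression from Smartphone Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying depression through
    passively sensed smartphone behavior. Generates realistic
    battery-sampled event logs (screen state, internet connectivity,
    foreground app launches) and repeated PHQ-8 depression assessments;
    localizes and filters participant-days; engineers 22 day-level
    behavioral markers (Shannon entropy, normalized entropy, hourly
    regularity indices, epoch-count standard deviations, counts and
    first/last app use); pools markers over 14-day assessment windows; and
    analyses them with Pearson/Holm correlation screens, random-intercept
    linear mixed models over multiply imputed data pooled by Rubin's
    rules, and an imbalance-aware nested cross-validated classification
    harness with SMOTE, random-weighted and decision-tree baselines, and
    AUC-permutation feature importance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    lubridate,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
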