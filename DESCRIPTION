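Package: oxival
Title: Validation Pipeline for Wearable Pulse-Oximeter Accuracy Studies
Version: 0.1.0
Authors@R: person("Oxival", "Maintainers", email = "maintainers@oxival.dev",
    role = c("aut", "cre"))
Description: Tools for evaluating wearable pulse-oximeter SpO2 accuracy
    against arterial-blood reference saturation (SaO2) in controlled
    desaturation studies. Implements windowed-median alignment of 1 Hz
    SpO2 streams to arterial blood gas reference samples, ISO
    80601-2-61-style accuracy metrics (RMSE, mean bias, residual-SD
    precision) with percentile bootstrap confidence intervals,
    Bland-Altman agreement statistics, between-stratum test batteries
    (one-way ANOVA, Tukey-Kramer, Levene, exact Wilcoxon signed-rank),
    and hypoxemia-detection diagnostics (error matrix, ROC/AUROC,
    Youden-optimal cut-off). A study-session simulator generates
    synthetic movement-phase and hypoxia-phase datasets with known
    ground truth, so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
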