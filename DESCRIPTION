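Package: serotrem
Title: Serotonin-Dopamine Circuit Dynamics and Parkinsonian Tremor Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: System-level simulation of the serotonin-dopamine interplay in the
    basal-ganglia-thalamo-cortical loop. Integrates an eight-variable firing-rate
    and neuromodulator-concentration circuit (primary motor cortex, thalamus,
    dorsal raphe nucleus, substantia nigra pars compacta, direct and indirect
    basal-ganglia pathways, striatal serotonin and dopamine) under timed lesion
    and drug interventions, drives a planar two-link arm through a
    proportional-derivative controller to quantify resting tremor, calibrates
    the circuit coefficients against reference steady states with a genetic
    algorithm, and runs multi-subject in-silico cohort experiments
    (dopaminergic lesion with serotonergic compensation, raphe damage, and
    SSRI dose escalation) with reproducible seeds.
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
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
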