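Package: drgstereo
Title: Stereological Quantification of Sensory Neuron Loss with Synthetic Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantifying neuron loss in
    dorsal root ganglia (DRG) from serially sectioned confocal stacks. Provides
    a synthetic ganglion generator with known ground truth (subpopulation
    structure, injury-driven cell loss, reporter and tracer labelling), virtual
    cryosectioning with serial slide collection and optical z-stacks, an
    optical-dissector counting rule with Cavalieri volume estimation of total
    neuron number, a cleared-tissue nuclear-spot filtering and size-binning
    pipeline, soma-size distribution comparison by exact two-sample
    Kolmogorov-Smirnov statistics, per-animal co-labelling proportions, and the
    accompanying inferential toolkit (paired t, one-way and split-plot
    repeated-measures ANOVA with Tukey or Sidak posttests, Shapiro-Wilk
    normality gate, and noncentral-t power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
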