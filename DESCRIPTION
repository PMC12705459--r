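Package: stateTE
Title: Brain-State Transition Energies on Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts recurring brain states from regional fMRI time series
    by replicated k-means with correlation distance, selects the stable
    partition by adjusted mutual information, computes minimum control
    energies for transitions between state centroids on a stabilized
    connectome-derived linear system (finite-horizon controllability
    Gramian), aggregates transition energies to network and global levels
    with IQR outlier exclusion, and tests family-history-by-sex group
    differences with two-way ANCOVA, partial eta squared, post-hoc t-tests,
    Spearman correlations with family-history density, and
    Benjamini-Hochberg FDR. Includes a seeded synthetic-cohort generator
    (modular connectomes, Markov state-switching BOLD series, pedigrees and
    covariates) so the full pipeline is testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
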