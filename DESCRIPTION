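Package: dnaacycle
Title: Growth-Rate-Dependent Timing of Replication Initiation by DnaA-ATP in Escherichia coli
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A minimal quantitative model of the timing of chromosome
    replication initiation in Escherichia coli across growth rates.
    Builds the Cooper-Helmstetter cell-cycle schedule (overlapping
    replication rounds, fork counts, gene dosage and genome length) for
    any doubling time, integrates the DnaA-ATP/DnaA-ADP dynamics --
    a thermodynamic (Shea-Ackers) autorepressed promoter source and a
    replication-fork-coupled RIDA sink -- to the cyclic steady state of
    an average cell by fourth-order Runge-Kutta, and imposes a
    growth-rate-independent initiation threshold on the DnaA-ATP:genome
    ratio by transforming the kinetic parameters under alternative
    scenarios of which parameters may vary with growth rate.  Includes
    the published model variants (translation delay, cooperative
    autorepression, datA titration, distributed high-affinity sites,
    DnaA-ATP recycling, Hda/RIDA perturbation) and the observable
    summaries used to compare the model against cell physiology data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
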