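Package: purkinje
Title: Simulation and Analysis of Cerebellar Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for in vivo cerebellar electrophysiology: gamma-renewal and
    Markov-modulated simulators of Purkinje-cell (simple and complex spike) and
    cerebellar-nuclear spike trains with calibrated rate, CV and CV2; synthesis
    of band-passed extracellular voltage traces; threshold spike detection and
    simple/complex spike sorting with complex-spike pause verification;
    interspike-interval statistics (firing rate, CV, CV2); hierarchical group
    inference (Wilks' lambda MANOVA gate, Wilcoxon rank-sum pairwise tests,
    Benjamini-Hochberg correction) and summary-statistic t tests; and particle
    counting arithmetic for anatomical quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    optparse
Config/testthat/edition: 3
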