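Package: tempnet
Title: Temporal Network Measures for Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for representing and quantifying temporal (time-varying)
    networks, with an emphasis on dynamic functional brain connectivity.
    Provides the graphlet-stack and contact-sequence data models with
    validated conversion and plain-text I/O; shortest temporal paths and
    intercontact times; nodal measures (temporal degree and closeness
    centrality, burstiness); global measures (fluctuability, volatility,
    reachability latency, temporal efficiency); derivation of binary
    t-graphlets from multivariate node time series via point-wise weighted
    Pearson correlation with Fisher and Box-Cox post-processing and
    variance-based thresholding; permutation statistics and surrogate
    (null) network generation; and seeded synthetic generators for
    multistate community time series and periodic, memoryless, or
    heavy-tailed edge processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
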