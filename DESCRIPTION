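Package: sortgate
Title: Automated Sorting-Gate Generation and Cell-Sorter Run Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven construction of flow-cytometry sorting gates from
    two-dimensional fluorescence/back-scatter event distributions, and a
    desk-scale simulation of an automated cell-sorter run. Gates are derived
    from highest-density-region contours of the profiled event cloud, fitted
    by translation and rotation to capture a user-defined top fraction of
    events (by default the brightest 1 percent), and bounded by a 60-vertex
    budget. The package also simulates a sorter session with event-rate-based
    sample-pressure control, orchestrates worklist-driven batches of samples
    with error isolation and notifications, renders end-of-run PDF reports,
    and generates synthetic CRISPR-edited cell pools (a non-fluorescent
    majority plus a fluorescent edited subpopulation) so the whole pipeline
    is testable without instrument data. Event data are read and written as
    FCS 3.1 or a documented CSV dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    grDevices,
    graphics,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
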