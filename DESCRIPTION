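Package: stageflow
Title: Workflow Management with Conditional Stage Dependencies for HPC Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow management core for high-performance computing:
    an immutable-versioned registry of command-line tools and workflows,
    a DAG execution engine in which stage dependencies are conditional on
    the parent stage's exit status, checkpoint/resume via working-directory
    snapshots, input profiles and batch submission, and a pluggable
    resource-manager backend layer with a local subprocess executor and
    Torque/SLURM job-script dialects. Includes a deterministic fixture
    generator for workflow patterns and scheduler status text, a persistent
    job history with sharing and permissions, and a credential-envelope
    impersonation protocol for running commands as authenticated users.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    R6,
    processx,
    openssl,
    jsonlite,
    yaml,
    zip,
    igraph,
    tibble,
    dplyr,
    purrr,
    stringr,
    rlang,
    generics,
    ggplot2,
    parallel,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
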