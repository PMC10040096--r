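Package: batchblast
Title: Distributed BLAST Search Orchestration, Resource Planning and Cost
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for planning and orchestrating large, batched BLAST
    searches the way cloud batch services run them, but without any cloud
    dependency. Splits FASTA query sets into length-bounded batches that
    never divide an individual sequence, selects the smallest instance
    type whose memory can hold a BLAST database efficiently (driven by
    database metadata), drives jobs through a retrying state machine with
    out-of-memory fail-fast and preemption requeue semantics, simulates
    autoscaled clusters with a discrete-event engine (startup delay,
    spot-instance preemption, scale-down lag, periodic shutdown monitor),
    and computes on-demand, discounted-instance and object-storage costs.
    Runs locally against a real BLAST+ executable or a bundled mock, with
    submit/status/delete commands backed by a filesystem object store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
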