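---
title: "Orchestrating batched BLAST searches: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orchestrating batched BLAST searches: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchblast)
```

# The problem

A BLAST search of millions of reads against a large reference database is
dominated not by any single alignment but by throughput: how to keep many
machines busy, how big each unit of work should be, which machine can hold
the database in memory, and what the whole exercise costs. Managed cloud
batch services solve the mechanics (queues, retries, autoscaling,
spot-capacity reclamation), but the *policies* — batch sizing, instance
selection, retry semantics, shutdown, billing — form a coherent model that
can be implemented, tested and simulated entirely locally. That model is
what this package provides; the alignment itself stays in an external
executable (BLAST+ or a scripted mock).

# Query batching

The unit of distributed work is the *query batch*: a contiguous group of
query sequences whose summed length reaches a threshold `batch_len`
(bases or residues). Batching amortises the per-job overhead of
scheduling, container startup and result upload; the target is a median
per-job runtime in the 5–30 minute band.

`split_queries()` uses a one-pass greedy *close-on-reach* rule: append
records in input order, close the batch as soon as its total reaches
`batch_len`. Exact boundary placement is a genuinely open choice (any rule
that never splits a sequence is admissible); close-on-reach was chosen
because it is streaming, order-preserving, and gives a tight two-sided
bound — every non-final batch satisfies

```
batch_len <= total < batch_len + len(final record)
```

so overshoot is bounded by a single record. Two consequences are accepted
deliberately: a record longer than `batch_len` forms its own oversized
batch (forced by the no-split rule), and the final batch may be
arbitrarily small. The property suite checks conservation, ordering, the
overshoot bound, monotonicity in `batch_len`, and equivalence with an
independent prefix-sum implementation of the same rule, over 1,000 random
FASTA fixtures of up to ~25 sequences each — small instances chosen
because every boundary case (oversized records, exact hits, empty tails)
already occurs at that scale.

**Default batch length.** No published table of defaults exists, so the
policy here is a calibration constant of this package: nucleotide-query
programs (blastn, megablast) use 5,000,000 letters per batch;
protein-query and translated programs (blastp, blastx, tblastn, tblastx)
use 20,000 — reflecting the roughly 100-fold difference in per-letter
search cost. The base is halved for databases whose cacheable core
exceeds 50 GiB (slower per-letter search), doubled below 4 GiB, and
doubled again for very large query sets (> 100 × base) to amortise
scheduling. The `batch-len` configuration key overrides all of this
unconditionally.

# Memory provisioning and instance selection

Database metadata distinguishes the total size of the database files from
`bytes-to-cache`, the portion (sequence data plus search indices) that
must be resident in memory for an efficient search; report-time data such
as sequence titles can stay on disk. Provisioning from `bytes-to-cache`
rather than the file size is the difference between a 96 GB requirement
and a 135 GB one for a refseq_protein-scale protein database.

`memory_requirement()` applies a multiplicative safety margin (default
1.1, configurable) and rounds up to a byte. The margin is this package's
own device: observed deployments provision visible headroom above the
cacheable size (a ~96 GB need running on a 128 GB machine) without
stating a rule, so a modest explicit factor is used and surfaced in the
plan report rather than hidden in the selector.

`select_instance()` is strictly *smallest sufficient*: minimal RAM among
catalog entries with `ram >= bytes_needed`, ties broken by lower hourly
price then lexicographic name (the tie-break order is repo-defined; only
"smallest" is externally given). A `machine-type` override always wins
but is validated against the requirement — an oversized override is
honoured, an undersized one is an error, because running with the
database half-resident defeats the point of the metadata. When no entry
suffices, the error reports both the requirement and the largest
available machine, since the remedy (a bigger catalog entry) is the
user's call.

**Thread layout.** BLAST throughput saturates around 16 threads per
process, so the layout is `min(vcpus, 16)` threads per process and
`max(1, floor(vcpus/16))` processes per instance. Databases whose
cacheable core is below 4 GiB use the by-query threading mode
(`query_batch`), which performs better when the database is small; the
4 GiB threshold is a package choice — the alternate mode is documented
without one.

# The job state machine

Each batch is one job. Transitions (`next_state()`):

| from      | event            | to                          |
|-----------|------------------|-----------------------------|
| PENDING   | start            | RUNNING, attempts + 1       |
| RUNNING   | success          | SUCCEEDED                   |
| RUNNING   | failure_oom      | FAILED (never retried)      |
| RUNNING   | failure_generic  | PENDING if attempts ≤ 3, else FAILED |
| RUNNING   | preempted        | same as failure_generic     |

"Up to three retries" is read as three retries *after* the first
execution — at most four executions in total — and a spot preemption
consumes a retry slot, because the requeue-after-preemption path is the
same mechanism as ordinary failure handling in the batch services being
modelled. Whether real services account preemptions against the retry
budget is ambiguous; this package picks the conservative reading and
documents it. Out-of-memory fails fast with zero retries: on a fixed
instance type the retry cannot succeed, and the reserved exit code 137
(the conventional SIGKILL/OOM-killer status) carries the signal from the
executor.

The shutdown monitor (`monitor_step()`, 300 s tick) orders teardown once
all jobs have succeeded or any job has failed; teardown is idempotent and
never touches result objects already written. The suite validates the
machine by exhaustive enumeration of all 19,530 event sequences of length
≤ 6 against an independent straight-line oracle — length 6 suffices to
exercise the full retry budget (4 starts + outcomes) in every order.

# Local execution

`run_local()` drives jobs to terminal states against any executor: an R
function or a command template with `{query}`, `{db}`, `{threads}`,
`{options}` slots (the opaque BLAST option string passes through
verbatim). Jobs are attempted in round-robin sweeps — every pending job
gets one execution per sweep, retries landing in later sweeps — so a
persistently failing batch does not starve the others, and when it
finally exhausts its budget the completed batches' results are already on
disk. Fail-fast applies at start time: once any job is FAILED, no new
execution begins. Successful output is gzip-compressed, one
`batch_<index>.out.gz` object per batch, mirroring how batch results land
in object storage. Execution is sequential in-process; the `workers`
argument exists for interface parity and does not change results.

# The cluster simulator

`simulate_cluster()` is a discrete-event model in seconds with these
elements, each a `sim_params()` field:

- **Startup** (`startup_delay_s`, default 0): instance 1 boots at t = 0
  and becomes productive after the delay; further instances join only
  once the first is productive, matching the observed single-instance
  startup period (cluster configuration plus database installation, up to
  ~22 min at production scale). No per-instance boot formula is published,
  so later instances are modelled as ready immediately — the startup
  delay is a free parameter, not a fitted model.
- **Scaling:** the pool grows toward `ceil(outstanding / slots)` capped at
  `max_nodes` (one slot per planned search process), and never exceeds
  the cap at any simulated instant.
- **Preemption** (`preemption_rate`, per busy instance-hour): exponential
  inter-arrival per busy instance; on reclaim every running job on the
  instance requeues through the state machine and a replacement boots
  after `restart_delay_s` (default 120 s).
- **Scale-down** (`scale_down_lag_s`): an instance idle that long shuts
  down, stamped at the moment the lag elapses. The monitor's tick
  observes state strictly before the tick, so final teardown happens at
  the first tick *after* completion — the cluster is billed for lag and
  monitor latency, which is exactly the mechanism that makes wide
  clusters cost more than ideal arithmetic suggests.
- **Billing:** per-instance uptime (boot to shutdown) summed into one
  meter per pricing class.

With all overheads zero the simulator reduces to ideal packing (eight
1-hour jobs: 8 h on one single-slot instance, 4 h on two, 1 h on eight),
which the acceptance suite asserts exactly; it is deterministic for a
fixed seed. Job durations come from a constant or a user function of
batch length; job *failure* inside the simulator arises only through the
preemption/retry budget — modelling stochastic search crashes was left
out as it adds a parameter with no calibration source.

# Cost model

Compute cost is `hours × instances × hourly_price`, multiplied by the
spot discount fraction when running on discounted capacity (0.2 at GCP:
preemptible instances cost 20% of on-demand). Storage is
`GB × months × rate` at $0.023 per GB-month. Rounding is half-up at two
decimals for totals of at least one cent — half-up, not R's banker's
`round()`, because bills round half-cents up (135 GB × $0.023 = $3.105 →
$3.11) — while sub-cent totals keep full precision and per-unit figures
report at two significant figures, matching how such numbers are quoted.

One divergence is explicit: multi-instance runs on an autoscaling cluster
are *not* priced as `time × n × rate`. Autoscaled billing reflects actual
per-instance uptime (startup, idle lag, monitor latency), which only the
simulator's meter sees; `estimate_run()` therefore treats
`time × max_nodes × rate` as an upper-bound what-if, and the simulator is
the supported path for realistic multi-node estimates.

# Synthetic fixtures

The package generates all of its own test data:

- `generate_fixture_fasta()`: uniform random lengths over a range, ACGT
  or amino-acid alphabet, deterministic per seed. It emulates size
  structure only — no homology, no real base composition, no quality
  information — which is sufficient because nothing downstream of the
  splitter reads the letters except the checksumming mock.
- `synth_metadata()`: cacheable core at ~1 byte/residue (protein) or
  ~0.25 byte/base (2-bit packed nucleotide) plus 10–30% index overhead,
  with file totals 25–60% above that for report-time data. The bundled
  `refseq_protein.synthetic-metadata.json` is a synthetic stand-in whose
  two size fields (135 GB total, 96 GB to cache) match the published
  values for that database; its sequence counts are plausible, not
  authoritative.
- The mock executable (in-process closure and standalone script) emits
  one deterministic line per query and scripts its exit codes per batch,
  so retry counting and result completeness are verifiable exactly.

Passing tests therefore demonstrate the orchestration semantics, not
BLAST accuracy, wire-level compatibility with any provider API, or
performance on real hardware.

# Problem sizes and limitations

Test and acceptance workloads are deliberately small — fixtures of tens
of sequences, simulations of 8–12 jobs, 200–1,000 property iterations —
sizes at which every structural case (batch boundaries, retry
exhaustion, preemption cascades, scale-down races) already occurs and
the full suite runs in a couple of minutes.

Known limitations:

- FASTA input is parsed whole via Biostrings; inputs larger than memory
  are not streamed. (Batch *writing* is per-batch and bounded.)
- `run_local()` is sequential; it models concurrency semantics, not
  wall-clock parallelism.
- Databases are never sharded across instances; the planner's answer to
  a database too big for every catalog machine is an error, by design.
- The simulator abstracts queueing services at the event level; it does
  not emulate any provider API.
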