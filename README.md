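# batchblast

Distributed BLAST searches are embarrassingly parallel over the *queries*,
and cloud batch services exploit that: split the query set into batches,
fan the batches out over a pool of instances sized to the database, retry
transient failures, tolerate spot-instance preemption, and tear everything
down when the work is done. Doing this well is mostly an orchestration and
economics problem, not an alignment problem — and the orchestration logic
is worth having *without* a cloud account, for planning, teaching, cost
forecasting and testing pipelines.

`batchblast` is that orchestration engine as a plain R package. It covers:

- **Query batching.** A FASTA query set (plain or gzipped) is partitioned
  into batches by a greedy close-on-reach rule: records are appended in
  input order and a batch closes as soon as its total length reaches the
  batch length *L* (bases/residues per batch). An individual sequence is
  never split, so every non-final batch satisfies
  `L <= total < L + len(last record)`. *L* defaults from a policy table
  keyed by program and database size — large enough to amortise per-job
  scheduling overhead, small enough to keep each job in the 5–30 minute
  band — and is user-overridable (`batch-len`).
- **Resource planning from database metadata.** BLAST database metadata
  records both the total file size and `bytes-to-cache`: the smaller
  portion (sequences + search indices) that must be resident in RAM for an
  efficient search. The planner provisions
  `ceil(bytes_to_cache * margin)` of memory (margin 1.1 by default) and
  picks the *smallest* catalog instance with at least that much RAM (ties:
  price, then name). Thread layout: at most 16 threads per search process
  — BLAST's scaling knee — with `floor(vcpus/16)` concurrent processes on
  wider machines.
- **A retrying job state machine.** PENDING → RUNNING →
  {SUCCEEDED, FAILED}; generic failures and spot preemptions requeue the
  job for up to 3 retries (≤ 4 executions); out-of-memory (exit code 137)
  fails fast with zero retries; a periodic monitor (5-minute tick) tears
  the cluster down on all-success or first failure, keeping results
  already written.
- **Execution backends.** `run_local()` drives jobs against a real BLAST+
  invocation template or a bundled deterministic mock;
  `simulate_cluster()` is a discrete-event model of the autoscaled pool
  (startup delay, per-busy-instance Poisson preemption, scale-down lag,
  monitor ticks) with a per-instance billing meter.
- **An explicit cost model.** Compute:
  `hours x instances x hourly_price x (spot_discount if preemptible)`
  with half-up cent rounding (preemptible capacity at GCP costs 20% of
  on-demand). Storage: `GB x months x $0.023`, sub-cent values kept at
  full precision. Per-unit (e.g. per-read) costs at two significant
  figures.

Everything cloud-specific is replaced by a filesystem object store:
`s3://` / `gs://` locators map onto a local directory tree, so the
submit/status/delete lifecycle, the manifests and the result objects all
behave like their bucket-backed counterparts.

## Worked example

A 50-sequence fixture searched against synthetic database metadata, with
the bundled mock standing in for the BLAST+ executable:

```r
library(batchblast)
store <- object_store("store")
writeLines(generate_fixture_fasta(50, c(100, 400), seed = 1),
           file.path(store$root, "queries.fa"))
writeLines(render_metadata(synth_metadata(1e6, "nucleotide", seed = 1)),
           file.path(store$root, "gtax-subset.json"))
cfg <- parse_config(c(
  "[cloud-provider]", "provider = gcp", "region = us-east4",
  "[cluster]", "num-nodes = 2", "use-preemptible = yes",
  "[blast]", "program = blastn", "db = store/gtax-subset.json",
  "queries = store/queries.fa", "results = gs://demo/results",
  "batch-len = 3000"))

handle <- submit(cfg, store)
status(handle)
#> <status_report> run-20260920003153-a814: phase=initializing | pending=4 running=0 succeeded=0 failed=0
execute_run(handle, mock_search_executable(), store = store)
#> <status_report> run-20260920003153-a814: phase=succeeded | pending=0 running=0 succeeded=4 failed=0
delete(handle)
#> <teardown_report> run-20260920003153-a814: deleted; 4 result object(s) retained
```

The ~12 kb query set became 4 batches of ≥ 3000 bases each; each batch
produced one gzipped result object (`batch_000.out.gz`, ...) that survives
the teardown — exactly what you want when you stop a half-finished (or
half-affordable) run.

Planning and costing without running anything:

```r
meta <- load_metadata(system.file("extdata",
        "refseq_protein.synthetic-metadata.json", package = "batchblast"))
select_instance(memory_requirement(meta), load_catalog(catalog_fixture_path()),
                provider = "gcp")
#> <instance_type> e2-highmem-16 (gcp): 16 vCPUs, 128 GB RAM, $0.81432/h on-demand (spot 20%)

# eight 1-hour jobs, up to 4 preemptible nodes, 22-min startup, 10-min scale-down lag
plan <- list(max_nodes = 4, preemptible = TRUE, thread_plan = list(processes = 1))
sim <- simulate_cluster(8, plan, sim_params(job_duration = 3600,
         startup_delay_s = 1320, scale_down_lag_s = 600,
         preemption_rate = 0.05, seed = 1))
sim
#> <sim_result> succeeded: makespan 2.37 h, teardown 2.42 h, billed 8.57 instance-hours (preemptible), peak 4 instance(s)
compute_cost(sim$billed_hours_total, 1, pricing_context(0.81432),
             preemptible = TRUE)
#> [1] 1.4
```

A database needing ~96 GB in memory lands on the 128 GB `e2-highmem-16`
(the 64 GB sibling is insufficient); the simulated 4-node run finishes in
2.37 h but bills 8.57 instance-hours — the startup period and the
scale-down lag are paid for, which is why wide clusters cost more per
unit of work — for about $1.40 on preemptible capacity.

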