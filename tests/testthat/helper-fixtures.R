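# Shared fixture builders. Everything is generated in code at test time.

make_records <- function(lengths) {
  data.frame(id = sprintf("s%03d", seq_along(lengths)),
             length = lengths,
             seq = strrep("A", lengths),
             stringsAsFactors = FALSE)
}

# Independent straight-line re-implementation of the close-on-reach greedy
# batching rule, phrased via prefix sums rather than a running accumulator.
oracle_split_assignment <- function(lengths, batch_len) {
  n <- length(lengths)
  assignment <- integer(n)
  pos <- 1L
  batch <- 0L
  while (pos <= n) {
    csum <- cumsum(lengths[pos:n])
    k <- which(csum >= batch_len)[1]
    if (is.na(k)) k <- n - pos + 1L
    assignment[pos:(pos + k - 1L)] <- batch
    pos <- pos + k
    batch <- batch + 1L
  }
  assignment
}

# Independent oracle for the job lifecycle: returns legality plus final
# state/attempts for an event sequence applied to a fresh job.
oracle_job_lifecycle <- function(events) {
  state <- "PENDING"
  attempts <- 0L
  for (e in events) {
    legal <- if (e == "start") state == "PENDING" else state == "RUNNING"
    if (!legal) return(list(legal = FALSE))
    if (e == "start") {
      state <- "RUNNING"
      attempts <- attempts + 1L
    } else if (e == "success") {
      state <- "SUCCEEDED"
    } else if (e == "failure_oom") {
      state <- "FAILED"
    } else {
      state <- if (attempts >= 4L) "FAILED" else "PENDING"
    }
  }
  list(legal = TRUE, state = state, attempts = attempts)
}

apply_events <- function(events) {
  job <- make_job("j", 0)
  for (e in events) job <- next_state(job, e)
  job
}

config_lines <- function(db, queries, results, program = "blastn",
                         extra_cluster = character(),
                         extra_blast = character()) {
  c("[cloud-provider]", "provider = gcp", "region = us-east4",
    "[cluster]", "num-nodes = 2", extra_cluster,
    "[blast]", paste("program =", program), paste("db =", db),
    paste("queries =", queries), paste("results =", results), extra_blast)
}

# A fully-populated tiny run: store, query fixture, synthetic metadata,
# parsed config. Returns the pieces tests need.
tiny_run_fixture <- function(n_seqs = 50, batch_len = 3000, seed = 3,
                             program = "blastn") {
  store <- object_store(tempfile("store-"))
  qf <- file.path(store$root, "queries.fa")
  writeLines(generate_fixture_fasta(n_seqs, c(100, 400), seed = seed), qf)
  mf <- file.path(store$root, "meta.json")
  writeLines(render_metadata(synth_metadata(1e6, "nucleotide", seed = 2)), mf)
  cfg <- parse_config(config_lines(
    mf, qf, "gs://bkt/results", program = program,
    extra_blast = paste("batch-len =", batch_len)))
  list(store = store, config = cfg, queries = qf, metadata = mf)
}

read_result_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con)
}
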