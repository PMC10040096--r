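# Helpers running a 4-batch job set through run_local with a scripted mock.
run_four <- function(behavior, store = object_store(tempfile("store-"))) {
  fa <- file.path(store$root, "q.fa")
  writeLines(generate_fixture_fasta(16, c(80, 120), seed = 2), fa)
  plan <- split_queries(read_sequences(fa), 400)
  stopifnot(length(plan$batches) >= 4)
  paths <- write_batches(plan, file.path(store$root, "batches"))
  jobs <- lapply(seq_along(paths) - 1L, function(i) {
    make_job(sprintf("job-%d", i), i)
  })
  res <- run_local(jobs, plan = NULL, mock_search_executable(behavior),
                   batch_paths = paths, results = "gs://bkt/res",
                   store = store, workers = 2)
  list(result = res, store = store, n = length(paths),
       results_dir = store_resolve(store, "gs://bkt/res"))
}

test_that("a clean run writes one gzipped result object per batch", {
  out <- run_four(list())
  expect_equal(out$result$phase, "succeeded")
  files <- list.files(out$results_dir)
  expect_equal(sort(files),
               sprintf("batch_%03d.out.gz", seq_len(out$n) - 1L))
  # deterministic tabular output: one line per query, batch index embedded
  lines <- read_result_lines(file.path(out$results_dir, "batch_001.out.gz"))
  fields <- strsplit(lines, "\t")
  expect_true(all(vapply(fields, length, integer(1)) == 3))
  expect_true(all(vapply(fields, `[`, character(1), 2) == "1"))
})

test_that("a transiently failing batch retries to success; attempts recorded", {
  out <- run_four(list("2" = list(mode = "fail_n", n = 2)))
  expect_equal(out$result$phase, "succeeded")
  attempts <- vapply(out$result$jobs, function(j) j$attempts, integer(1))
  expect_equal(attempts[3], 3L)   # two failures then success
  expect_true(all(attempts[-3] == 1L))
})

test_that("a persistently failing batch fails the run but completed results survive", {
  out <- run_four(list("1" = list(mode = "fail")))
  expect_equal(out$result$phase, "failed")
  states <- vapply(out$result$jobs, function(j) j$state, character(1))
  expect_equal(states[2], "FAILED")
  expect_equal(out$result$jobs[[2]]$attempts, 4L)
  # other batches completed in earlier sweeps; their results remain
  remaining <- list.files(out$results_dir)
  expect_true(all(sprintf("batch_%03d.out.gz", c(0, 2, 3)) %in% remaining))
  expect_false("batch_001.out.gz" %in% remaining)
})

test_that("out-of-memory fails fast: no retry, later jobs never started", {
  out <- run_four(list("1" = list(mode = "oom")))
  expect_equal(out$result$phase, "failed")
  jobs <- out$result$jobs
  expect_equal(jobs[[2]]$state, "FAILED")
  expect_equal(jobs[[2]]$last_failure, "oom")
  expect_equal(jobs[[2]]$attempts, 1L)
  # batch 0 ran before the OOM; batches 2,3 were cancelled while pending
  expect_equal(jobs[[1]]$state, "SUCCEEDED")
  expect_true(all(vapply(jobs[3:4], function(j) j$state, character(1)) ==
                  "PENDING"))
  expect_true(all(vapply(jobs[3:4], function(j) j$attempts, integer(1)) == 0L))
})

test_that("a missing search executable aborts before any job starts", {
  expect_error(
    run_local(list(make_job("j", 0)), NULL,
              c("no-such-binary-anywhere", "{query}"),
              batch_paths = "x.fa", results = tempfile()),
    "not found")
})

test_that("submit persists a manifest whose status counts always sum to the total", {
  fx <- tiny_run_fixture()
  h <- submit(fx$config, fx$store)
  rep0 <- status(h)
  expect_equal(rep0$phase, "initializing")
  expect_equal(sum(rep0$counts), rep0$counts[["pending"]])
  n_jobs <- sum(rep0$counts)
  expect_gte(n_jobs, 1)

  # manifest lists every batch
  manifest <- jsonlite::fromJSON(file.path(h$state_dir, "run.json"),
                                 simplifyVector = FALSE)
  expect_length(manifest$batch_files, n_jobs)
  expect_true(all(vapply(manifest$batch_files, file.exists, logical(1))))

  rep1 <- execute_run(h, mock_search_executable(), store = fx$store)
  expect_equal(rep1$phase, "succeeded")
  expect_equal(sum(rep1$counts), n_jobs)
  expect_equal(rep1$counts[["succeeded"]], n_jobs)
})

test_that("submitting an empty query set allocates nothing", {
  fx <- tiny_run_fixture()
  empty <- file.path(fx$store$root, "empty.fa")
  file.create(empty)
  cfg <- fx$config
  cfg$queries <- empty
  expect_error(submit(cfg, fx$store), "no sequences")
  expect_false(dir.exists(file.path(fx$store$root, "runs")))
})

test_that("duplicate active run ids are rejected", {
  fx <- tiny_run_fixture()
  submit(fx$config, fx$store, run_id = "run-x")
  expect_error(submit(fx$config, fx$store, run_id = "run-x"), "active")
})

test_that("delete releases resources, keeps results, and is idempotent", {
  fx <- tiny_run_fixture()
  h <- submit(fx$config, fx$store)
  execute_run(h, mock_search_executable(), store = fx$store)
  results_dir <- store_resolve(fx$store, fx$config$results)
  before <- list.files(results_dir)
  checks_before <- tools::md5sum(file.path(results_dir, before))

  r1 <- delete(h)
  expect_false(r1$noop)
  expect_equal(status(h)$phase, "deleted")
  expect_false(dir.exists(file.path(h$state_dir, "batches")))
  # result objects written before delete are byte-identical after it
  expect_equal(tools::md5sum(file.path(results_dir, before)), checks_before)

  r2 <- delete(h)
  expect_true(r2$noop)
  expect_equal(r2$results_retained, length(before))
  expect_error(status(structure(list(state_dir = tempfile()),
                                class = "run_handle")), "manifest")
})

test_that("delete mid-run keeps the completed jobs' results readable", {
  fx <- tiny_run_fixture()
  h <- submit(fx$config, fx$store)
  # fail batch 2 persistently: sweeps complete 0,1,3 then fail-fast stops
  execute_run(h, mock_search_executable(list("2" = list(mode = "fail"))),
              store = fx$store)
  expect_equal(status(h)$phase, "failed")
  delete(h)
  results_dir <- store_resolve(fx$store, fx$config$results)
  kept <- list.files(results_dir, pattern = "\\.out\\.gz$")
  expect_gte(length(kept), 2)
  for (f in kept) {
    expect_gt(length(read_result_lines(file.path(results_dir, f))), 0)
  }
})

test_that("the standalone mock executable honours scripted behaviour via subprocess", {
  fx <- tiny_run_fixture()
  h <- submit(fx$config, fx$store)
  cmd <- mock_blast_command(list("0" = list(mode = "fail_n", n = 1)))
  rep <- execute_run(h, cmd, store = fx$store)
  expect_equal(rep$phase, "succeeded")
  manifest <- jsonlite::fromJSON(file.path(h$state_dir, "run.json"),
                                 simplifyVector = FALSE)
  attempts <- vapply(manifest$jobs, function(j) j$attempts, numeric(1))
  expect_equal(attempts[1], 2)          # one scripted failure, then success
  expect_true(all(attempts[-1] == 1))
})
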