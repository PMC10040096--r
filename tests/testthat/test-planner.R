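GIB <- 2^30

req_bytes <- function(bytes) {
  structure(list(bytes_needed = bytes, margin = 1),
            class = "memory_requirement")
}

random_catalog <- function(n) {
  validate_catalog(data.frame(
    name = sprintf("m%02d", 1:n),
    provider = sample(c("aws", "gcp"), n, replace = TRUE),
    vcpus = sample(c(4, 8, 16, 32, 96), n, replace = TRUE),
    ram_gb = sample(c(8, 16, 32, 64, 128, 256, 768), n, replace = TRUE),
    hourly_price = round(runif(n, 0.1, 8), 3),
    spot_discount = sample(c(0.2, 0.3, 1), n, replace = TRUE),
    local_ssd_gb = 375, stringsAsFactors = FALSE))
}

test_that("bundled catalog fixture loads with the documented machines", {
  cat <- load_catalog(catalog_fixture_path())
  expect_gte(nrow(cat), 5)
  r5 <- catalog_lookup(cat, "r5ad.4xlarge")
  expect_equal(c(r5$vcpus, r5$ram_gb, r5$hourly_price), c(16, 128, 1.048))
  expect_true(all(c("e2-highmem-16", "n1-highmem-96", "r5ad.24xlarge",
                    "c5ad.4xlarge") %in% cat$name))
})

test_that("catalog validation rejects duplicates and bad rates; CSV loads", {
  df <- data.frame(name = c("a", "a"), provider = "aws", vcpus = 4,
                   ram_gb = 16, hourly_price = 1, spot_discount = 0.3,
                   local_ssd_gb = 0)
  expect_error(validate_catalog(df), "duplicate")
  df$name <- c("a", "b")
  df$hourly_price <- c(1, -1)
  expect_error(validate_catalog(df), "hourly_price")
  df$hourly_price <- 1
  df$spot_discount <- c(0, 0.3)
  expect_error(validate_catalog(df), "spot_discount")

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(name = "tiny", provider = "gcp", vcpus = 2,
                       ram_gb = 4, hourly_price = 0.05, spot_discount = 0.2,
                       local_ssd_gb = 0), csv, row.names = FALSE)
  expect_equal(load_catalog(csv)$ram_bytes, 4 * GIB)

  empty <- tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_equal(nrow(load_catalog(empty)), 0)
})

test_that("selector picks the smallest sufficient instance", {
  cat <- load_catalog(catalog_fixture_path())
  pick <- select_instance(req_bytes(96 * GIB), cat, provider = "gcp")
  expect_equal(pick$name, "e2-highmem-16")   # 64 GB insufficient, 128 GB next

  tiny <- select_instance(req_bytes(1), cat, provider = "gcp")
  expect_equal(tiny$ram_gb, min(cat$ram_gb[cat$provider == "gcp"]))

  err <- expect_error(select_instance(req_bytes(1024 * GIB), cat))
  expect_match(conditionMessage(err), "largest available")
})

test_that("selector agrees with exhaustive search on random catalogs", {
  set.seed(11)
  for (rep in 1:100) {
    cat <- random_catalog(sample(3:12, 1))
    need <- sample(c(4, 20, 100, 500, 700), 1) * GIB
    sufficient <- cat[cat$ram_bytes >= need, , drop = FALSE]
    if (nrow(sufficient) == 0) {
      expect_error(select_instance(req_bytes(need), cat), "memory")
    } else {
      # brute force with the stated tie-break: RAM, then price, then name
      best <- sufficient[order(sufficient$ram_bytes, sufficient$hourly_price,
                               sufficient$name), ][1, ]
      expect_equal(select_instance(req_bytes(need), cat)$name, best$name)
    }
  }
})

test_that("thread layout caps at 16 threads per process", {
  small_db <- synth_metadata(1e6, "nucleotide", seed = 1)     # < 4 GiB core
  large_db <- synth_metadata(2e11, "protein", seed = 1)       # >> 4 GiB core
  inst <- function(vcpus) {
    structure(list(vcpus = vcpus), class = "instance_type")
  }
  tp16 <- thread_plan(inst(16), large_db)
  expect_equal(c(tp16$processes, tp16$threads_per_process), c(1, 16))
  expect_equal(tp16$mode, "db_partition")

  tp32 <- thread_plan(inst(32), large_db)
  expect_equal(c(tp32$processes, tp32$threads_per_process), c(2, 16))

  tp8 <- thread_plan(inst(8), small_db)
  expect_equal(c(tp8$processes, tp8$threads_per_process), c(1, 8))
  expect_equal(tp8$mode, "query_batch")

  for (v in c(1, 4, 15, 16, 17, 32, 96)) {
    tp <- thread_plan(inst(v), large_db)
    expect_lte(tp$threads_per_process, 16)
    expect_lte(tp$processes * tp$threads_per_process, v)
  }
})

test_that("batch-length policy: override wins, small dbs get bigger batches", {
  small_db <- synth_metadata(1e6, "nucleotide", seed = 1)
  large_db <- synth_metadata(3e12, "nucleotide", seed = 1)
  expect_equal(default_batch_len("blastn", small_db, override = 12345), 12345)
  expect_identical(default_batch_len("megablast", small_db),
                   default_batch_len("megablast", small_db))
  expect_gte(default_batch_len("blastn", small_db),
             default_batch_len("blastn", large_db))
  # nucleotide-query programs carry far more letters per batch than protein
  expect_gt(default_batch_len("blastn", small_db),
            default_batch_len("blastp", small_db))
  expect_error(default_batch_len("blastz", small_db), "blastz")
})

test_that("plans select e2-highmem-16 for a refseq_protein-sized database", {
  meta <- load_metadata(system.file("extdata",
                                    "refseq_protein.synthetic-metadata.json",
                                    package = "batchblast"))
  expect_equal(meta$total_bytes / GIB, 135)
  expect_equal(meta$bytes_to_cache / GIB, 96)

  cfg <- parse_config(config_lines("db.json", "q.fa", "r", program = "blastx"))
  cat <- load_catalog(catalog_fixture_path())
  plan <- make_plan(cfg, meta, cat)
  expect_equal(plan$instance$name, "e2-highmem-16")
  expect_gte(plan$instance$ram_bytes, plan$memory$bytes_needed)
  expect_equal(plan$max_nodes, 2)

  # oversized override is honoured, insufficient override is rejected
  cfg$machine_type <- "r5ad.24xlarge"
  expect_equal(make_plan(cfg, meta, cat)$instance$name, "r5ad.24xlarge")
  cfg$machine_type <- "c5ad.4xlarge"
  expect_error(make_plan(cfg, meta, cat), "needs")
})

test_that("non-override plans always satisfy the memory invariant", {
  set.seed(23)
  cat <- load_catalog(catalog_fixture_path())
  for (rep in 1:25) {
    meta <- synth_metadata(sample(c(1e6, 1e9, 2e10), 1),
                           sample(c("protein", "nucleotide"), 1), seed = rep)
    cfg <- parse_config(config_lines("db.json", "q.fa", "r"))
    cfg$provider <- sample(c("aws", "gcp"), 1)
    plan <- make_plan(cfg, meta, cat)
    expect_gte(plan$instance$ram_bytes, plan$memory$bytes_needed)
    expect_equal(plan$instance$provider, cfg$provider)
  }
})
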