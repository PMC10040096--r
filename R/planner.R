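#' @title Resource planning
#' @description
#' From database metadata, the run configuration and an instance catalog,
#' the planner derives everything the executor or simulator needs: the
#' instance type (smallest sufficient memory, unless overridden), the
#' per-instance thread layout (at most 16 threads per search process, which
#' is the point of diminishing returns for BLAST; bigger machines run
#' multiple processes), and the batch length targeting job runtimes in the
#' 5-30 minute band.
#' @name resource-planner
NULL

#' Per-instance thread layout
#'
#' BLAST scales well only up to about 16 threads per process, so an instance
#' with more than 16 vCPUs runs multiple concurrent search processes of 16
#' threads each rather than one wide process. Small databases (cacheable
#' core below `small_db_threshold`) use the by-query threading mode, which
#' is more efficient when the whole database fits in a slice of memory;
#' large databases partition the database across threads.
#'
#' @param instance An `instance_type`.
#' @param meta A `db_metadata`.
#' @param small_db_threshold Bytes below which the by-query mode is used
#'   (default 4 GiB).
#' @return A `thread_plan`: `processes`, `threads_per_process`, `mode`
#'   (`"db_partition"` or `"query_batch"`).
#' @export
thread_plan <- function(instance, meta, small_db_threshold = 4 * GIB) {
  stopifnot(inherits(instance, "instance_type"), inherits(meta, "db_metadata"))
  processes <- max(1L, floor(instance$vcpus / 16))
  threads <- min(instance$vcpus, 16L)
  structure(list(
    processes = as.integer(processes),
    threads_per_process = as.integer(threads),
    mode = if (meta$bytes_to_cache < small_db_threshold) "query_batch"
           else "db_partition"
  ), class = "thread_plan")
}

# Batch-length policy table. Calibration constants intended to keep the
# median per-batch runtime in the 5-30 minute band: nucleotide-query
# programs scan more letters per unit work than protein/translated
# searches, so their batches carry far more letters. Database size class
# scales the base (a bigger database means slower per-letter search, so
# smaller batches; a small database the reverse); very large query sets
# double the batch to amortise scheduling.
BATCH_LEN_BASE <- c(blastn = 5e6, megablast = 5e6,
                    blastp = 2e4, blastx = 2e4, tblastn = 2e4, tblastx = 2e4)
DB_SMALL_BYTES <- 4 * GIB    # below: class "small", factor 2
DB_LARGE_BYTES <- 50 * GIB   # above: class "large", factor 1/2

#' Default batch length for a search
#'
#' Policy default keyed by (program, database-size class, query-size class);
#' an explicit `override` (the `batch-len` configuration key) always wins.
#'
#' @param program One of blastn, megablast, blastp, blastx, tblastn,
#'   tblastx.
#' @param meta A `db_metadata`.
#' @param query_total_length Optional total query letters, used to class the
#'   query set.
#' @param override Optional explicit batch length; returned unchanged.
#' @return A positive integer batch length (bases/residues per batch).
#' @export
default_batch_len <- function(program, meta, query_total_length = NULL,
                              override = NULL) {
  if (!is.null(override)) {
    stopifnot(override >= 1)
    return(as.numeric(override))
  }
  base <- unname(BATCH_LEN_BASE[program])[1]
  if (is.na(base)) {
    stop("unknown program '", program, "'; supported programs: ",
         paste(SUPPORTED_PROGRAMS, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(meta, "db_metadata"))
  db_factor <- if (meta$bytes_to_cache < DB_SMALL_BYTES) 2
               else if (meta$bytes_to_cache > DB_LARGE_BYTES) 0.5
               else 1
  query_factor <- if (!is.null(query_total_length) &&
                      query_total_length > 100 * base) 2 else 1
  max(1, ceiling(base * db_factor * query_factor))
}

#' Build a search plan
#'
#' Combines [memory_requirement()], [select_instance()] (honouring a
#' `machine-type` override from the configuration), [thread_plan()] and
#' [default_batch_len()] into the record the executor and the simulator
#' consume. An override naming an instance with too little memory for the
#' database is rejected rather than silently accepted.
#'
#' @param config A `run_config`.
#' @param meta A `db_metadata`.
#' @param catalog An `instance_catalog`.
#' @param margin Memory safety margin (see [memory_requirement()]).
#' @param query_total_length Optional total query letters.
#' @return A `search_plan`: `instance`, `thread_plan`, `batch_len`,
#'   `max_nodes`, `preemptible`, `memory`.
#' @examples
#' \dontrun{
#' plan <- make_plan(cfg, load_metadata("refseq_protein.json"),
#'                   load_catalog(catalog_fixture_path()))
#' plan$instance$name
#' }
#' @export
make_plan <- function(config, meta, catalog, margin = 1.1,
                      query_total_length = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(meta, "db_metadata"),
            inherits(catalog, "instance_catalog"))
  memory <- memory_requirement(meta, margin)
  if (!is.null(config$machine_type)) {
    instance <- catalog_lookup(catalog, config$machine_type)
    if (instance$ram_bytes < memory$bytes_needed) {
      stop(sprintf(paste0(
        "machine-type override '%s' has %.1f GB RAM but the database ",
        "needs %.1f GB to run efficiently"),
        instance$name, instance$ram_gb, memory$bytes_needed / GIB),
        call. = FALSE)
    }
  } else {
    instance <- select_instance(memory, catalog, provider = config$provider)
  }
  structure(list(
    instance = instance,
    thread_plan = thread_plan(instance, meta),
    batch_len = default_batch_len(config$program, meta,
                                  query_total_length = query_total_length,
                                  override = config$batch_len),
    max_nodes = config$num_nodes,
    preemptible = config$use_preemptible,
    memory = memory
  ), class = "search_plan")
}

#' @export
print.search_plan <- function(x, ...) {
  tp <- x$thread_plan
  cat("<search_plan>\n")
  cat(sprintf("  instance  : %s (%d vCPUs, %.0f GB RAM, $%.5g/h)\n",
              x$instance$name, x$instance$vcpus, x$instance$ram_gb,
              x$instance$hourly_price))
  cat(sprintf("  memory    : %.1f GB needed (margin %.2f)\n",
              x$memory$bytes_needed / GIB, x$memory$margin))
  cat(sprintf("  threads   : %d process(es) x %d thread(s), %s mode\n",
              tp$processes, tp$threads_per_process, tp$mode))
  cat(sprintf("  batch-len : %s\n", format(x$batch_len, big.mark = ",")))
  cat(sprintf("  cluster   : up to %d %s node(s)\n", x$max_nodes,
              if (x$preemptible) "preemptible" else "on-demand"))
  invisible(x)
}
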