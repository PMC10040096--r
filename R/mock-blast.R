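#' @title Mock search executable
#' @description
#' Tests and demonstrations need no BLAST+ installation: a mock stands in
#' for the search executable. Its output is deterministic and tabular (query
#' id, batch index, checksum), so result completeness after retries and
#' teardown can be verified line by line, and its behaviour is scripted per
#' batch index: succeed, fail a given number of times then succeed, fail
#' persistently, or signal out-of-memory (exit code 137).
#' @name mock-blast
NULL

mock_checksum <- function(seq) sum(utf8ToInt(seq)) %% 100000L

mock_output_lines <- function(batch_file, batch_index) {
  recs <- read_sequences(batch_file)
  sprintf("%s\t%d\t%d", recs$id, batch_index,
          vapply(recs$seq, mock_checksum, integer(1), USE.NAMES = FALSE))
}

#' In-process mock search executable
#'
#' Builds an executor function suitable for [run_local()]. The behaviour
#' spec maps batch indices to one of: `list(mode = "succeed")` (default for
#' unlisted batches), `list(mode = "fail_n", n = 2)` (fail the first `n`
#' attempts with a generic error, then succeed), `list(mode = "fail")`
#' (fail persistently), `list(mode = "oom")` (exit with the reserved
#' out-of-memory code on every attempt).
#'
#' @param behavior Named list keyed by batch index as a string (e.g.
#'   `list("1" = list(mode = "oom"))`); unlisted batches succeed.
#' @return A function `(batch_file, batch_index, attempt, db, threads,
#'   options)` returning `list(status, output)` where `status` is the exit
#'   code and `output` a character vector of result lines.
#' @examples
#' exec <- mock_search_executable(list("1" = list(mode = "fail_n", n = 2)))
#' @export
mock_search_executable <- function(behavior = list()) {
  function(batch_file, batch_index, attempt, db = NULL, threads = NULL,
           options = NULL) {
    spec <- behavior[[as.character(batch_index)]]
    mode <- if (is.null(spec)) "succeed" else spec$mode
    status <- switch(mode,
      succeed = 0L,
      fail = 1L,
      fail_n = if (attempt <= spec$n) 1L else 0L,
      oom = OOM_EXIT_CODE,
      stop("unknown mock behavior mode '", mode, "'", call. = FALSE))
    output <- if (status == 0L) mock_output_lines(batch_file, batch_index)
              else character()
    list(status = status, output = output)
  }
}

#' Command-line invocation of the bundled mock executable
#'
#' The mock also ships as a standalone script
#' (`inst/scripts/mock-blast.R`) so the subprocess execution path of
#' [run_local()] can be exercised end to end. The behaviour spec is written
#' to JSON and passed in the template's `{db}` slot; per-batch attempt
#' counters persist in files next to it.
#'
#' @param behavior Behaviour spec as in [mock_search_executable()].
#' @param dir Directory for the behaviour JSON and attempt counters.
#' @return An executor command template (character vector) for
#'   [run_local()]: the `Rscript` invocation with `{query}`, `{db}`,
#'   `{threads}`, `{options}` substitution slots.
#' @export
mock_blast_command <- function(behavior = list(), dir = tempfile("mock-")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec_path <- file.path(dir, "behavior.json")
  write_json_atomic(behavior, spec_path)
  script <- system.file("scripts", "mock-blast.R", package = "batchblast",
                        mustWork = TRUE)
  c(file.path(R.home("bin"), "Rscript"), script,
    "{query}", spec_path, "{threads}", "{options}")
}
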