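#' @title Run configuration
#' @description
#' A run is described by a three-section configuration file in an INI dialect:
#' `[cloud-provider]` (provider, region), `[cluster]` (num-nodes,
#' use-preemptible, machine-type) and `[blast]` (program, db, queries,
#' results, options, batch-len). Key names are hyphenated. Every key can also
#' be supplied as an override (command-line flags mirror the keys); an
#' override beats the file on conflict.
#' @name run-config
NULL

SUPPORTED_PROGRAMS <- c("blastn", "megablast", "blastp", "blastx",
                        "tblastn", "tblastx")
SUPPORTED_PROVIDERS <- c("aws", "gcp")

# Minimal INI-dialect reader: [section] headers, key = value lines, comments
# with '#' or ';'. Returns a named list of named character lists.
parse_ini <- function(lines) {
  sections <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, ";")) next
    if (grepl("^\\[.+\\]$", line)) {
      current <- sub("^\\[(.+)\\]$", "\\1", line)
      if (is.null(sections[[current]])) sections[[current]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      stop("configuration line ", i, " is neither a [section] nor key = value: '",
           line, "'", call. = FALSE)
    }
    if (is.null(current)) {
      stop("configuration line ", i, " appears before any [section] header",
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", line))
    value <- trimws(sub("^[^=]*=", "", line))
    sections[[current]][[key]] <- value
  }
  sections
}

parse_bool <- function(value, key) {
  v <- tolower(trimws(value))
  if (v %in% c("yes", "true")) return(TRUE)
  if (v %in% c("no", "false")) return(FALSE)
  stop("key '", key, "' must be one of yes/no/true/false, got '", value, "'",
       call. = FALSE)
}

parse_positive_int <- function(value, key) {
  n <- suppressWarnings(as.numeric(value))
  if (is.na(n) || n < 1 || n != floor(n)) {
    stop("key '", key, "' must be a positive integer, got '", value, "'",
         call. = FALSE)
  }
  n
}

require_key <- function(section, section_name, key) {
  v <- section[[key]]
  if (is.null(v) || !nzchar(trimws(v))) {
    stop("missing required key '", key, "' in section [", section_name, "]",
         call. = FALSE)
  }
  v
}

#' Parse a run configuration
#'
#' Parses the three-section INI configuration into a validated `run_config`
#' object. Unset optional keys carry documented defaults: `num-nodes` 1,
#' `use-preemptible` no, `options` empty; `machine-type` unset lets the
#' planner choose; `batch-len` unset falls back to the program/database
#' default policy (see [default_batch_len()]).
#'
#' @param text Configuration file contents: a single string or a character
#'   vector of lines.
#' @param overrides Named list of key overrides (hyphenated key names, e.g.
#'   `list("num-nodes" = 4)`); an override always beats the file.
#' @return A `run_config` list with fields `provider`, `region`, `num_nodes`,
#'   `use_preemptible`, `machine_type` (or `NULL`), `program`, `db`,
#'   `queries`, `results`, `options`, `batch_len` (or `NULL`).
#' @examples
#' cfg <- parse_config(c(
#'   "[cloud-provider]", "provider = gcp", "region = us-east4",
#'   "[cluster]", "num-nodes = 4", "use-preemptible = yes",
#'   "[blast]", "program = blastx", "db = refseq_protein.json",
#'   "queries = queries.fa", "results = gs://bucket/results"))
#' cfg$use_preemptible
#' @export
parse_config <- function(text, overrides = list()) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  ini <- parse_ini(lines)
  for (sec in c("cloud-provider", "cluster", "blast")) {
    if (is.null(ini[[sec]])) {
      stop("missing required section [", sec, "]", call. = FALSE)
    }
  }
  # overrides land in their owning section by key name
  key_section <- c(
    "provider" = "cloud-provider", "region" = "cloud-provider",
    "num-nodes" = "cluster", "use-preemptible" = "cluster",
    "machine-type" = "cluster",
    "program" = "blast", "db" = "blast", "queries" = "blast",
    "results" = "blast", "options" = "blast", "batch-len" = "blast")
  for (key in names(overrides)) {
    if (!key %in% names(key_section)) {
      stop("unknown configuration key '", key, "'", call. = FALSE)
    }
    ini[[key_section[[key]]]][[key]] <- as.character(overrides[[key]])
  }

  cp <- ini[["cloud-provider"]]
  cl <- ini[["cluster"]]
  bl <- ini[["blast"]]

  provider <- tolower(require_key(cp, "cloud-provider", "provider"))
  if (!provider %in% SUPPORTED_PROVIDERS) {
    stop("provider must be one of: ", paste(SUPPORTED_PROVIDERS, collapse = ", "),
         "; got '", provider, "'", call. = FALSE)
  }
  program <- tolower(require_key(bl, "blast", "program"))
  if (!program %in% SUPPORTED_PROGRAMS) {
    stop("unknown program '", program, "'; supported programs: ",
         paste(SUPPORTED_PROGRAMS, collapse = ", "), call. = FALSE)
  }

  config <- structure(list(
    provider = provider,
    region = require_key(cp, "cloud-provider", "region"),
    num_nodes = if (is.null(cl[["num-nodes"]])) 1
                else parse_positive_int(cl[["num-nodes"]], "num-nodes"),
    use_preemptible = if (is.null(cl[["use-preemptible"]])) FALSE
                      else parse_bool(cl[["use-preemptible"]], "use-preemptible"),
    machine_type = if (is.null(cl[["machine-type"]])) NULL
                   else trimws(cl[["machine-type"]]),
    program = program,
    db = require_key(bl, "blast", "db"),
    queries = require_key(bl, "blast", "queries"),
    results = require_key(bl, "blast", "results"),
    options = if (is.null(bl[["options"]])) "" else bl[["options"]],
    batch_len = if (is.null(bl[["batch-len"]])) NULL
                else parse_positive_int(bl[["batch-len"]], "batch-len")
  ), class = "run_config")
  config
}

#' Read and parse a configuration file
#'
#' @param path Path to the configuration file.
#' @inheritParams parse_config
#' @return A `run_config`; see [parse_config()].
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  parse_config(readLines(path, warn = FALSE), overrides = overrides)
}

#' Render a configuration back to INI text
#'
#' Inverse of [parse_config()]: `parse_config(render_config(x))` reproduces
#' `x` field for field.
#'
#' @param config A `run_config`.
#' @return Character vector of INI lines.
#' @export
render_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lines <- c(
    "[cloud-provider]",
    paste0("provider = ", config$provider),
    paste0("region = ", config$region),
    "",
    "[cluster]",
    paste0("num-nodes = ", format(config$num_nodes, scientific = FALSE)),
    paste0("use-preemptible = ", if (config$use_preemptible) "yes" else "no"))
  if (!is.null(config$machine_type)) {
    lines <- c(lines, paste0("machine-type = ", config$machine_type))
  }
  lines <- c(lines, "",
    "[blast]",
    paste0("program = ", config$program),
    paste0("db = ", config$db),
    paste0("queries = ", config$queries),
    paste0("results = ", config$results))
  if (nzchar(config$options)) {
    lines <- c(lines, paste0("options = ", config$options))
  }
  if (!is.null(config$batch_len)) {
    lines <- c(lines, paste0("batch-len = ",
                             format(config$batch_len, scientific = FALSE)))
  }
  lines
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  provider/region :", x$provider, "/", x$region, "\n")
  cat("  cluster         :", x$num_nodes, "node(s),",
      if (x$use_preemptible) "preemptible" else "on-demand",
      if (!is.null(x$machine_type)) paste0("(", x$machine_type, ")") else "", "\n")
  cat("  search          :", x$program, "vs", x$db, "\n")
  cat("  queries         :", x$queries, "\n")
  cat("  results         :", x$results, "\n")
  if (!is.null(x$batch_len)) cat("  batch-len       :", x$batch_len, "\n")
  invisible(x)
}
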