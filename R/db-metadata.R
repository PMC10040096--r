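#' @title BLAST database metadata
#' @description
#' Modern BLAST databases ship a metadata record describing their contents.
#' Two sizes matter for provisioning: the total size of all database files,
#' and `bytes-to-cache` — the smaller subset (sequence data plus search
#' indices) that must fit in main memory for the search to run efficiently;
#' sequence titles and other report-time data need not be resident. The
#' planner provisions memory from `bytes-to-cache`, not the total size.
#'
#' The JSON dialect read here is minimal and repo-defined: fields `name`,
#' `molecule` ("protein"/"nucleotide"), `num-letters`, `num-sequences`,
#' `total-bytes`, `bytes-to-cache`, `version`. [load_metadata()] is the
#' adapter point for other dialects.
#' @name db-metadata
NULL

GIB <- 2^30

new_db_metadata <- function(name, molecule, num_letters, num_sequences,
                            total_bytes, bytes_to_cache, version = "1.0") {
  meta <- structure(list(
    name = name, molecule = molecule, num_letters = num_letters,
    num_sequences = num_sequences, total_bytes = total_bytes,
    bytes_to_cache = bytes_to_cache, version = version
  ), class = "db_metadata")
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  if (!meta$molecule %in% c("protein", "nucleotide")) {
    stop("molecule must be 'protein' or 'nucleotide', got '", meta$molecule,
         "'", call. = FALSE)
  }
  if (meta$num_sequences < 1 || meta$num_letters < meta$num_sequences) {
    stop("database metadata inconsistent: need num-letters >= num-sequences >= 1",
         call. = FALSE)
  }
  if (meta$bytes_to_cache <= 0) {
    stop("bytes-to-cache must be positive", call. = FALSE)
  }
  if (meta$bytes_to_cache > meta$total_bytes) {
    stop("inconsistent metadata: bytes-to-cache (", meta$bytes_to_cache,
         ") exceeds total-bytes (", meta$total_bytes, ")", call. = FALSE)
  }
  meta
}

#' Load database metadata from JSON
#'
#' @param source Path or bucket-style locator of a metadata JSON document.
#' @param store Optional [object_store()].
#' @return A `db_metadata` object with fields `name`, `molecule`,
#'   `num_letters`, `num_sequences`, `total_bytes`, `bytes_to_cache`,
#'   `version`.
#' @export
load_metadata <- function(source, store = NULL) {
  path <- store_resolve(store, source)
  if (!file.exists(path)) {
    stop("database metadata not found: ", source, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path)
  required <- c("name", "molecule", "num-letters", "num-sequences",
                "total-bytes", "bytes-to-cache")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("metadata schema error: missing field(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  new_db_metadata(
    name = raw[["name"]], molecule = tolower(raw[["molecule"]]),
    num_letters = as.numeric(raw[["num-letters"]]),
    num_sequences = as.numeric(raw[["num-sequences"]]),
    total_bytes = as.numeric(raw[["total-bytes"]]),
    bytes_to_cache = as.numeric(raw[["bytes-to-cache"]]),
    version = if (is.null(raw[["version"]])) "1.0" else raw[["version"]])
}

#' Render database metadata to JSON text
#'
#' Inverse of [load_metadata()]; `load_metadata` of the rendered document
#' is the identity on valid records.
#'
#' @param meta A `db_metadata`.
#' @return A JSON string.
#' @export
render_metadata <- function(meta) {
  stopifnot(inherits(meta, "db_metadata"))
  as.character(jsonlite::toJSON(list(
    "name" = meta$name, "molecule" = meta$molecule,
    "num-letters" = meta$num_letters, "num-sequences" = meta$num_sequences,
    "total-bytes" = meta$total_bytes, "bytes-to-cache" = meta$bytes_to_cache,
    "version" = meta$version), auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' Memory a search needs to run efficiently
#'
#' The provisioned memory is `bytes-to-cache` scaled by a multiplicative
#' safety margin and rounded up to a whole byte. The default margin of 1.1
#' leaves headroom for the search processes themselves on top of the cached
#' database, and is surfaced in the plan report.
#'
#' @param meta A `db_metadata`.
#' @param margin Multiplicative safety factor, >= 1.
#' @return A `memory_requirement`: list with `bytes_needed` and `margin`.
#' @examples
#' meta <- synth_metadata(1e8, "protein", seed = 1)
#' memory_requirement(meta, margin = 1.1)
#' @export
memory_requirement <- function(meta, margin = 1.1) {
  stopifnot(inherits(meta, "db_metadata"))
  if (margin < 1) stop("margin must be >= 1", call. = FALSE)
  structure(list(
    bytes_needed = ceiling(meta$bytes_to_cache * margin),
    margin = margin
  ), class = "memory_requirement")
}

#' @export
print.memory_requirement <- function(x, ...) {
  cat(sprintf("<memory_requirement> %.1f GB (margin %.2f)\n",
              x$bytes_needed / GIB, x$margin))
  invisible(x)
}

#' @export
print.db_metadata <- function(x, ...) {
  cat(sprintf("<db_metadata> %s (%s): %s letters in %s sequences; %.1f GB total, %.1f GB to cache\n",
              x$name, x$molecule,
              format(x$num_letters, big.mark = ","),
              format(x$num_sequences, big.mark = ","),
              x$total_bytes / GIB, x$bytes_to_cache / GIB))
  invisible(x)
}

#' Synthesise database metadata
#'
#' Fixture generator producing a realistic metadata record from a letter
#' count. The cacheable core scales with the molecule's packing density
#' (protein ~1 byte/residue, nucleotide ~0.25 byte/base, 2-bit packed) plus
#' a jittered index overhead; total file size adds report-time data (titles,
#' taxonomy) on top. Deterministic for a fixed seed.
#'
#' @param num_letters Total bases/residues (>= 1).
#' @param molecule `"protein"` or `"nucleotide"`.
#' @param seed Integer RNG seed.
#' @param name Database identifier.
#' @return A `db_metadata`.
#' @export
synth_metadata <- function(num_letters, molecule = c("protein", "nucleotide"),
                           seed = 1L, name = NULL) {
  molecule <- match.arg(molecule)
  stopifnot(num_letters >= 1)
  if (is.null(name)) name <- sprintf("synthdb_%s_%d", molecule, seed)
  with_local_seed(seed, {
    core_per_letter <- if (molecule == "protein") 1 else 0.25
    index_overhead <- stats::runif(1, 0.10, 0.30)
    bytes_to_cache <- ceiling(num_letters * core_per_letter * (1 + index_overhead))
    title_overhead <- stats::runif(1, 0.25, 0.60)
    total_bytes <- ceiling(bytes_to_cache * (1 + title_overhead))
    mean_len <- if (molecule == "protein") 350 else 1200
    num_sequences <- max(1, round(num_letters / mean_len))
    new_db_metadata(name, molecule, num_letters, num_sequences,
                    total_bytes, bytes_to_cache)
  })
}
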