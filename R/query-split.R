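#' @title Query splitting
#' @description
#' Distributed BLAST parallelises over query batches: contiguous groups of
#' query sequences whose summed length reaches a configured threshold (the
#' batch length, in bases or residues). The batch is the unit of work; it
#' must be large enough to amortise scheduling overhead, and an individual
#' query sequence is never split between batches.
#' @name query-split
NULL

#' Read query sequences from FASTA
#'
#' Reads a FASTA query set, plain or gzip-compressed (detected by magic
#' bytes), preserving input order. Lengths count sequence characters only.
#'
#' @param source Path or bucket-style locator of a FASTA file.
#' @param store Optional [object_store()] for bucket-style locators.
#' @return A data frame with columns `id` (definition-line identifier),
#'   `length`, and `seq` (sequence text), one row per record in file order.
#' @export
read_sequences <- function(source, store = NULL) {
  path <- store_resolve(store, source)
  if (!file.exists(path)) stop("query source not readable: ", source, call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), length = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", source, "': ", conditionMessage(e),
           call. = FALSE)
    })
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    bad <- which(widths == 0L)[1]
    stop("record ", bad, " ('", names(set)[bad],
         "') has a header but no sequence", call. = FALSE)
  }
  data.frame(id = names(set), length = widths,
             seq = as.character(set), stringsAsFactors = FALSE)
}

#' Split query sequences into length-bounded batches
#'
#' Greedy close-on-reach rule: records are appended to the open batch in
#' input order, and the batch is closed as soon as its total length reaches
#' `batch_len` (the closing record included). Consequences: every batch
#' except possibly the last has total length >= `batch_len`; removing the
#' last record of such a batch would leave it below `batch_len` (minimal
#' overshoot); a single record longer than `batch_len` forms its own
#' oversized batch; no record is ever split; order is preserved.
#'
#' @param records Data frame as returned by [read_sequences()].
#' @param batch_len Positive integer: target bases/residues per batch.
#' @return A `split_plan`: list with `batches` (list of record data frames),
#'   `assignment` (0-based batch index per input record), `batch_len`, and
#'   `totals` (`n_seqs`, `n_letters` of the input).
#' @examples
#' recs <- data.frame(id = letters[1:4], length = c(100, 200, 300, 400),
#'                    seq = strrep("A", c(100, 200, 300, 400)))
#' plan <- split_queries(recs, 350)
#' vapply(plan$batches, function(b) sum(b$length), numeric(1))  # 600, 400
#' @export
split_queries <- function(records, batch_len) {
  stopifnot(is.data.frame(records))
  if (length(batch_len) != 1L || is.na(batch_len) || batch_len < 1) {
    stop("batch_len must be a positive integer", call. = FALSE)
  }
  n <- nrow(records)
  assignment <- integer(n)
  batch <- 0L
  open_total <- 0
  for (i in seq_len(n)) {
    assignment[i] <- batch
    open_total <- open_total + records$length[i]
    if (open_total >= batch_len) {
      batch <- batch + 1L
      open_total <- 0
    }
  }
  batches <- if (n > 0) {
    unname(split(records, assignment))
  } else {
    list()
  }
  structure(list(
    batches = batches,
    assignment = assignment,
    batch_len = batch_len,
    totals = list(n_seqs = n, n_letters = sum(records$length))
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan>", length(x$batches), "batch(es) of",
      x$totals$n_seqs, "sequence(s) /", format(x$totals$n_letters, big.mark = ","),
      "letters; batch-len", format(x$batch_len, big.mark = ","), "\n")
  invisible(x)
}

batch_file_name <- function(index, n_batches = NULL) {
  width <- max(3L, if (is.null(n_batches)) 3L else nchar(max(0L, n_batches - 1L)))
  sprintf("batch_%0*d.fa", width, index)
}

#' Write query batches to a destination
#'
#' One uncompressed FASTA object per batch, named by zero-padded 0-based
#' index (`batch_000.fa`, `batch_001.fa`, ...), 80-column wrapped.
#' Re-reading and concatenating the files in name order reproduces the
#' input records.
#'
#' @param plan A `split_plan` from [split_queries()].
#' @param dest Directory path or bucket-style locator to write into.
#' @param store Optional [object_store()].
#' @return Character vector of written batch locators (local paths), in
#'   batch order; empty for an empty plan.
#' @export
write_batches <- function(plan, dest, store = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  dir <- store_resolve(store, dest, create = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("destination not writable: ", dest, call. = FALSE)
  n <- length(plan$batches)
  paths <- character(n)
  for (i in seq_len(n)) {
    b <- plan$batches[[i]]
    set <- Biostrings::BStringSet(stats::setNames(b$seq, b$id))
    paths[i] <- file.path(dir, batch_file_name(i - 1L, n))
    Biostrings::writeXStringSet(set, paths[i], width = 80L)
  }
  paths
}

#' Generate a deterministic FASTA fixture
#'
#' Test/demonstration fixture generator: `n_seqs` records with unique ids
#' and lengths uniform on `length_range`, deterministic for a fixed seed.
#'
#' @param n_seqs Number of records (>= 0).
#' @param length_range `c(min, max)` sequence length bounds.
#' @param seed Integer RNG seed.
#' @param molecule `"nucleotide"` (ACGT alphabet) or `"protein"` (20 amino
#'   acids).
#' @return A single string of FASTA text (possibly empty).
#' @export
generate_fixture_fasta <- function(n_seqs, length_range = c(100, 1000),
                                   seed = 1L,
                                   molecule = c("nucleotide", "protein")) {
  molecule <- match.arg(molecule)
  stopifnot(n_seqs >= 0, length(length_range) == 2L,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (n_seqs == 0) return("")
  alphabet <- if (molecule == "nucleotide") c("A", "C", "G", "T")
              else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- with_local_seed(seed, {
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n_seqs,
                 replace = TRUE) - 1L
    vapply(seq_len(n_seqs), function(i) {
      seqtxt <- paste(sample(alphabet, lens[i], replace = TRUE), collapse = "")
      wrapped <- gsub("(.{60})", "\\1\n", seqtxt)
      sprintf(">seq_%04d len=%d\n%s", i, lens[i], sub("\n$", "", wrapped))
    }, character(1))
  })
  paste0(paste(out, collapse = "\n"), "\n")
}

# Evaluate expr under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
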