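#' Filesystem-backed object store
#'
#' Bucket-style locators (`s3://bucket/key`, `gs://bucket/key`) are accepted
#' everywhere a path is, and are mapped onto a local directory tree rooted at
#' `root`. This gives the package cloud-bucket semantics (long-term storage
#' independent of any worker) without cloud credentials: a locator resolves to
#' `<root>/<scheme>/<bucket>/<key>`. Plain filesystem paths pass through
#' unchanged.
#'
#' @param root Directory under which bucket-style locators are materialised.
#'   Created if missing.
#' @return An object of class `object_store`.
#' @examples
#' store <- object_store(tempfile("store-"))
#' store_resolve(store, "gs://my-bucket/results/run1")
#' @export
object_store <- function(root) {
  stopifnot(is.character(root), length(root) == 1L)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  structure(list(root = normalizePath(root)), class = "object_store")
}

#' @export
print.object_store <- function(x, ...) {
  cat("<object_store> root:", x$root, "\n")
  invisible(x)
}

is_bucket_locator <- function(locator) {
  grepl("^(s3|gs)://", locator)
}

#' Resolve a locator to a local path
#'
#' @param store An [object_store()]. May be `NULL` for plain paths.
#' @param locator A plain path or a `s3://`/`gs://` locator.
#' @param create Create the parent directory of the resolved path?
#' @return A local filesystem path.
#' @export
store_resolve <- function(store, locator, create = FALSE) {
  stopifnot(is.character(locator), length(locator) == 1L, nzchar(locator))
  if (is_bucket_locator(locator)) {
    if (is.null(store)) {
      stop("bucket-style locator '", locator,
           "' requires an object store (see object_store())", call. = FALSE)
    }
    scheme <- sub("^([a-z0-9]+)://.*$", "\\1", locator)
    rest <- sub("^[a-z0-9]+://", "", locator)
    path <- file.path(store$root, scheme, rest)
  } else {
    path <- locator
  }
  if (create) dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  path
}

# Atomic JSON write: write to a temp file in the target directory then rename,
# so concurrent readers (status/delete from another process) never observe a
# half-written document.
write_json_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("json-", tmpdir = dirname(path))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}
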