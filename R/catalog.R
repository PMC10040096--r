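#' @title Instance-type catalog
#' @description
#' The planner chooses from a catalog of instance types: name, provider,
#' vCPU count, RAM, on-demand hourly price, the discount fraction paid for
#' spot/preemptible capacity (e.g. 0.2 means the discounted instance costs
#' 20% of the on-demand price), and local scratch SSD. The catalog is data,
#' not code: a bundled fixture carries a handful of representative AWS and
#' GCP machines (see `catalog_fixture_path()`); real deployments would feed
#' in a full provider listing.
#' @name instance-catalog
NULL

catalog_columns <- c("name", "provider", "vcpus", "ram_gb", "hourly_price",
                     "spot_discount", "local_ssd_gb")

#' Load an instance-type catalog
#'
#' Accepts JSON (array of objects) or CSV, with columns/fields `name`,
#' `provider`, `vcpus`, `ram_gb`, `hourly_price`, `spot_discount`,
#' `local_ssd_gb`. RAM is given in GB for readability and carried internally
#' in bytes (`ram_bytes = ram_gb * 2^30`).
#'
#' @param source Path or bucket-style locator of the catalog; format chosen
#'   by extension (`.json` vs `.csv`).
#' @param store Optional [object_store()].
#' @return A data frame of class `instance_catalog` with an added
#'   `ram_bytes` and `local_ssd_bytes` column.
#' @export
load_catalog <- function(source, store = NULL) {
  path <- store_resolve(store, source)
  if (!file.exists(path)) stop("catalog not found: ", source, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    json = jsonlite::fromJSON(path),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    stop("unsupported catalog format '.", ext, "' (use .json or .csv)",
         call. = FALSE))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(name = character(), provider = character(),
                     vcpus = numeric(), ram_gb = numeric(),
                     hourly_price = numeric(), spot_discount = numeric(),
                     local_ssd_gb = numeric(), stringsAsFactors = FALSE)
  }
  missing <- setdiff(catalog_columns, names(df))
  if (length(missing)) {
    stop("catalog missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_catalog(df)
}

validate_catalog <- function(df) {
  if (anyDuplicated(df$name)) {
    stop("catalog has duplicate instance name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0) {
    if (any(!df$provider %in% SUPPORTED_PROVIDERS)) {
      stop("catalog provider must be one of: ",
           paste(SUPPORTED_PROVIDERS, collapse = ", "), call. = FALSE)
    }
    if (any(df$vcpus < 1)) stop("catalog vcpus must be >= 1", call. = FALSE)
    if (any(df$ram_gb <= 0)) stop("catalog ram_gb must be > 0", call. = FALSE)
    if (any(df$hourly_price <= 0)) {
      stop("catalog hourly_price must be > 0", call. = FALSE)
    }
    if (any(df$spot_discount <= 0 | df$spot_discount > 1)) {
      stop("catalog spot_discount must be in (0, 1]", call. = FALSE)
    }
  }
  df$ram_bytes <- df$ram_gb * GIB
  df$local_ssd_bytes <- df$local_ssd_gb * GIB
  class(df) <- c("instance_catalog", "data.frame")
  df
}

#' Path to the bundled instance-type catalog fixture
#'
#' A small representative catalog (JSON) with the workhorse memory-optimised
#' AWS and GCP machines used throughout the examples, plus small entries for
#' tests.
#'
#' @return Path to the installed JSON catalog.
#' @export
catalog_fixture_path <- function() {
  system.file("extdata", "instance-catalog.json", package = "batchblast",
               mustWork = TRUE)
}

#' Select the smallest sufficient instance type
#'
#' Returns the catalog entry with minimal RAM among those whose RAM is at
#' least the memory requirement — the cheapest machine that can hold the
#' database comfortably. Ties on RAM break by lower hourly price, then
#' lexicographic name.
#'
#' @param requirement A [memory_requirement()].
#' @param catalog An `instance_catalog`.
#' @param provider Optional provider filter (`"aws"` or `"gcp"`).
#' @return A one-row `instance_type` list: `name`, `provider`, `vcpus`,
#'   `ram_bytes`, `ram_gb`, `hourly_price`, `spot_discount`,
#'   `local_ssd_bytes`.
#' @examples
#' cat <- load_catalog(catalog_fixture_path())
#' req <- list(bytes_needed = 96 * 2^30, margin = 1)
#' class(req) <- "memory_requirement"
#' select_instance(req, cat, provider = "gcp")$name  # e2-highmem-16
#' @export
select_instance <- function(requirement, catalog, provider = NULL) {
  stopifnot(inherits(requirement, "memory_requirement"),
            inherits(catalog, "instance_catalog"))
  df <- catalog
  if (!is.null(provider)) df <- df[df$provider == provider, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("instance catalog is empty",
         if (!is.null(provider)) paste0(" after filtering to provider '",
                                        provider, "'"), call. = FALSE)
  }
  ok <- df[df$ram_bytes >= requirement$bytes_needed, , drop = FALSE]
  if (nrow(ok) == 0) {
    stop(sprintf(paste0(
      "no catalog instance has enough memory: need %.1f GB, largest ",
      "available is %s with %.1f GB (request a larger machine type ",
      "explicitly or extend the catalog)"),
      requirement$bytes_needed / GIB, df$name[which.max(df$ram_bytes)],
      max(df$ram_bytes) / GIB), call. = FALSE)
  }
  ok <- ok[order(ok$ram_bytes, ok$hourly_price, ok$name), , drop = FALSE]
  as_instance_type(ok[1, , drop = FALSE])
}

as_instance_type <- function(row) {
  structure(list(
    name = row$name, provider = row$provider, vcpus = row$vcpus,
    ram_bytes = row$ram_bytes, ram_gb = row$ram_gb,
    hourly_price = row$hourly_price, spot_discount = row$spot_discount,
    local_ssd_bytes = row$local_ssd_bytes
  ), class = "instance_type")
}

#' Look up a catalog instance by name
#'
#' @param catalog An `instance_catalog`.
#' @param name Instance name.
#' @return An `instance_type`.
#' @export
catalog_lookup <- function(catalog, name) {
  stopifnot(inherits(catalog, "instance_catalog"))
  hit <- catalog[catalog$name == name, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("instance type '", name, "' not in catalog", call. = FALSE)
  }
  as_instance_type(hit)
}

#' @export
print.instance_type <- function(x, ...) {
  cat(sprintf("<instance_type> %s (%s): %d vCPUs, %.0f GB RAM, $%.5g/h on-demand (spot %.0f%%)\n",
              x$name, x$provider, x$vcpus, x$ram_gb, x$hourly_price,
              100 * x$spot_discount))
  invisible(x)
}
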