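#' @title Cost model
#' @description
#' Explicit arithmetic for what a batched cloud search costs: compute is
#' hours x instances x hourly price, with discounted (spot/preemptible)
#' capacity billed at a fraction of the on-demand price (20% at GCP);
#' object storage is size x months x a per-GB-month rate ($0.023 at both
#' major providers). Currency totals of a cent or more round half-up to two
#' decimals; sub-cent amounts (a month of storing a few MB of gzipped
#' results) are reported at full precision, and per-unit costs (per read,
#' per query) to two significant figures.
#'
#' Multi-instance runs on an autoscaling cluster are deliberately NOT
#' modelled as `time x n x rate`: the cluster bills actual per-instance
#' uptime (including scale-down lag), which only the simulator's billing
#' meter sees — use [simulate_cluster()] and [estimate_run()] for those.
#' @name cost-model
NULL

#' Pricing context
#'
#' @param hourly_price On-demand price per instance-hour.
#' @param spot_discount Fraction of the on-demand price paid for
#'   discounted (spot/preemptible) capacity; GCP preemptible default 0.2.
#' @param storage_rate Price per GB-month of object storage (default
#'   0.023).
#' @return A `pricing_context`.
#' @export
pricing_context <- function(hourly_price, spot_discount = 0.2,
                            storage_rate = 0.023) {
  stopifnot(hourly_price > 0, spot_discount > 0, spot_discount <= 1,
            storage_rate > 0)
  structure(list(hourly_price = hourly_price, spot_discount = spot_discount,
                 storage_rate = storage_rate), class = "pricing_context")
}

# Currency rounding: half-up at 2 decimals for totals >= $0.01; sub-cent
# values keep full precision (base round() is banker's and would turn
# 3.105 into 3.10, not the 3.11 a half-up bill shows).
round_currency <- function(x) {
  ifelse(abs(x) >= 0.01, floor(x * 100 + 0.5) / 100, x)
}

#' Compute cost of a fixed-size run
#'
#' `hours x n_instances x hourly_price`, times the spot discount when
#' running on preemptible capacity, rounded per the currency rule.
#'
#' @param hours Run duration in hours (>= 0).
#' @param n_instances Number of instances (>= 1).
#' @param pricing A [pricing_context()].
#' @param preemptible Billed at the discounted rate?
#' @return Cost in currency units.
#' @examples
#' gcp <- pricing_context(0.81432)
#' compute_cost(8.07, 1, gcp)                      # 6.57
#' compute_cost(7.83, 1, gcp, preemptible = TRUE)  # 1.28
#' @export
compute_cost <- function(hours, n_instances, pricing, preemptible = FALSE) {
  stopifnot(hours >= 0, n_instances >= 1, inherits(pricing, "pricing_context"))
  raw <- hours * n_instances * pricing$hourly_price *
    (if (preemptible) pricing$spot_discount else 1)
  round_currency(raw)
}

#' Compute cost from a vCPU total
#'
#' Large runs are often reported as a vCPU count; the instance count is
#' `ceiling(total_vcpus / vcpus_per_instance)` and the cost delegates to
#' [compute_cost()].
#'
#' @param hours Run duration in hours.
#' @param total_vcpus Total vCPUs used.
#' @param vcpus_per_instance vCPUs per instance.
#' @param hourly_price On-demand price per instance-hour.
#' @param spot_discount,preemptible See [compute_cost()].
#' @return Cost in currency units.
#' @examples
#' compute_cost_from_vcpus(18 / 60, 1600, 16, 0.688)    # 20.64
#' compute_cost_from_vcpus(15.75, 32000, 16, 1.048)     # 33012
#' @export
compute_cost_from_vcpus <- function(hours, total_vcpus, vcpus_per_instance,
                                    hourly_price, spot_discount = 0.2,
                                    preemptible = FALSE) {
  stopifnot(total_vcpus >= 1, vcpus_per_instance >= 1)
  n_instances <- ceiling(total_vcpus / vcpus_per_instance)
  compute_cost(hours, n_instances,
               pricing_context(hourly_price, spot_discount),
               preemptible = preemptible)
}

#' Object-storage cost
#'
#' @param size_gb Stored size in GB (>= 0).
#' @param months Storage duration in months (>= 0).
#' @param rate Price per GB-month.
#' @return Cost in currency units (full precision below one cent).
#' @examples
#' storage_cost(0.0018)   # 4.14e-05: a month of gzipped results
#' storage_cost(135)      # 3.11: a month of a refseq_protein-sized database
#' @export
storage_cost <- function(size_gb, months = 1, rate = 0.023) {
  stopifnot(size_gb >= 0, months >= 0, rate > 0)
  round_currency(size_gb * months * rate)
}

#' Per-unit cost
#'
#' Total cost divided over a unit count (reads, queries, ...), reported to
#' a small number of significant figures as such figures are quoted.
#'
#' @param total Total cost.
#' @param n_units Unit count (>= 1).
#' @param significant_figures Significant figures for the report.
#' @return Cost per unit.
#' @examples
#' per_unit_cost(1849 + 33012, 26724497)   # 0.0013 per read
#' per_unit_cost(20.64 + 617.27, 26724497) # 0.000024 per read
#' @export
per_unit_cost <- function(total, n_units, significant_figures = 2) {
  stopifnot(n_units >= 1, total >= 0)
  signif(total / n_units, significant_figures)
}

#' Pre-submission cost estimate for a plan
#'
#' What-if report combining the compute component (predicted hours on the
#' plan's instance type, at most `max_nodes` instances) with the storage
#' component, flagging the preemptible saving. Doing a small test run and
#' estimating before a large submission is the cheap insurance of cloud
#' batch work.
#'
#' @param plan A `search_plan` from [make_plan()].
#' @param predicted_hours Predicted wall-clock hours.
#' @param storage_gb GB of results/queries to store (default 0).
#' @param storage_months Months of storage (default 1).
#' @param storage_rate Price per GB-month.
#' @return A `cost_report`: `instance_hours`, `compute_cost`,
#'   `compute_cost_preemptible`, `storage_cost`, `total`, and optionally
#'   `per_unit_cost` via [per_unit_cost()].
#' @export
estimate_run <- function(plan, predicted_hours, storage_gb = 0,
                         storage_months = 1, storage_rate = 0.023) {
  stopifnot(inherits(plan, "search_plan"), predicted_hours >= 0)
  pricing <- pricing_context(plan$instance$hourly_price,
                             plan$instance$spot_discount, storage_rate)
  n <- plan$max_nodes
  on_demand <- compute_cost(predicted_hours, n, pricing, preemptible = FALSE)
  preempt <- compute_cost(predicted_hours, n, pricing, preemptible = TRUE)
  storage <- storage_cost(storage_gb, storage_months, storage_rate)
  chosen <- if (plan$preemptible) preempt else on_demand
  structure(list(
    instance_hours = predicted_hours * n,
    compute_cost = on_demand,
    compute_cost_preemptible = preempt,
    preemptible = plan$preemptible,
    storage_cost = storage,
    total = round_currency(chosen + storage)
  ), class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("<cost_report>\n")
  cat(sprintf("  instance-hours : %.2f\n", x$instance_hours))
  cat(sprintf("  compute        : $%s on-demand / $%s preemptible%s\n",
              format(x$compute_cost, big.mark = ","),
              format(x$compute_cost_preemptible, big.mark = ","),
              if (x$preemptible) " (preemptible selected)" else ""))
  if (x$storage_cost > 0) {
    cat(sprintf("  storage        : $%s per month\n",
                format(x$storage_cost, big.mark = ",")))
  }
  cat(sprintf("  total          : $%s\n", format(x$total, big.mark = ",")))
  invisible(x)
}
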