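#' Cost grid for the proportional-threshold sweep
#'
#' @param from,to,by grid limits and step; default 1\% to 50\% in 1\% steps
#'   (50 thresholds).
#' @return numeric vector of class \code{"cost_grid"}, strictly increasing,
#'   each value in (0, 1].
#' @export
cost_grid <- function(from = 0.01, to = 0.50, by = 0.01) {
  costs <- seq(from, to, by = by)
  if (any(costs <= 0) || any(costs > 1))
    stop("costs must lie in (0, 1]", call. = FALSE)
  if (any(diff(costs) <= 0))
    stop("cost grid must be strictly increasing", call. = FALSE)
  structure(costs, class = c("cost_grid", "numeric"))
}

#' Graph metrics for one record, averaged across the cost grid
#'
#' At each cost: threshold with [prepare_adjacency()], then compute the
#' participation coefficient on the a-priori network partition, betweenness
#' centrality, global efficiency, and modularity of the partition found by
#' [newman_communities()] on the thresholded graph. Per-node and global
#' values are then arithmetically averaged across the grid, giving one mean
#' PC/BC vector and one mean efficiency/modularity scalar per record.
#'
#' @param record a [connectivity_record()].
#' @param grid a [cost_grid()].
#' @param membership a-priori community ids (from [node_communities()]).
#' @return list of class \code{"subject_condition_metrics"}: participant_id,
#'   dataset_id, condition, age, mean_pc, mean_bc (length-N vectors),
#'   mean_e_global, mean_q (scalars).
#' @export
sweep_record <- function(record, grid, membership) {
  stopifnot(inherits(record, "connectivity_record"))
  n <- nrow(record$matrix)
  stopifnot(length(membership) == n)
  pc <- bc <- matrix(NA_real_, length(grid), n)
  eg <- q <- numeric(length(grid))
  for (i in seq_along(grid)) {
    g <- prepare_adjacency(record$matrix, grid[i])
    pc[i, ] <- participation_coefficient(g, membership)
    paths <- .path_metrics(g)                 # one Brandes pass for bc + E
    bc[i, ] <- paths$bc
    eg[i] <- paths$efficiency
    q[i] <- modularity_q(g, newman_communities(g))
  }
  structure(
    list(participant_id = record$participant_id,
         dataset_id = record$dataset_id, condition = record$condition,
         age = record$age,
         mean_pc = colMeans(pc), mean_bc = colMeans(bc),
         mean_e_global = mean(eg), mean_q = mean(q)),
    class = "subject_condition_metrics"
  )
}

#' Sweep a whole cohort
#'
#' Applies [sweep_record()] to every record. Deterministic and
#' order-independent: the output for a record depends only on that record.
#'
#' @param records list of [connectivity_record()].
#' @param grid a [cost_grid()].
#' @param membership a-priori community ids.
#' @return list of \code{subject_condition_metrics}, one per record, in
#'   input order.
#' @export
sweep_cohort <- function(records, grid, membership) {
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    out[[i]] <- tryCatch(
      sweep_record(records[[i]], grid, membership),
      error = function(e)
        stop("record ", i, " (participant ", records[[i]]$participant_id,
             ", ", records[[i]]$condition, "): ", conditionMessage(e),
             call. = FALSE)
    )
  }
  out
}

#' Long-format tables from swept metrics
#'
#' \code{metrics_long_table} stacks per-node mean PC/BC into the long format
#' consumed by the univariate and classification stages; one row per
#' (participant, condition, node). \code{metrics_global_table} gives one row
#' per (participant, condition) with the two global means.
#'
#' @param metrics list of \code{subject_condition_metrics} from
#'   [sweep_cohort()].
#' @return data.frame (participant_id, dataset_id, condition, age, node_id,
#'   mean_pc, mean_bc), node_id 0-based.
#' @export
metrics_long_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m) {
    n <- length(m$mean_pc)
    data.frame(participant_id = m$participant_id, dataset_id = m$dataset_id,
               condition = m$condition, age = m$age,
               node_id = seq_len(n) - 1L,
               mean_pc = m$mean_pc, mean_bc = m$mean_bc,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname metrics_long_table
#' @return \code{metrics_global_table}: data.frame (participant_id,
#'   dataset_id, condition, age, mean_e_global, mean_q).
#' @export
metrics_global_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m)
    data.frame(participant_id = m$participant_id, dataset_id = m$dataset_id,
               condition = m$condition, age = m$age,
               mean_e_global = m$mean_e_global, mean_q = m$mean_q,
               stringsAsFactors = FALSE)))
}
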