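#' Configuration for the synthetic-connectome generator
#'
#' Describes a cohort of paired (fear/neutral) weighted connectivity matrices
#' with block structure given by a node table's networks, nested random
#' variation (participants within datasets), and a planted condition effect:
#' in the fear condition every edge with both endpoints in
#' \code{affected_network} gains \code{effect_delta}.
#'
#' Edge weights are built on a magnitude-plus-sign scale:
#' \eqn{W_{ij} = s_{ij}(\mu_{ij} + b_{subj} + b_{ds} + \epsilon_{ij})} with
#' \eqn{\mu_{ij}} equal to \code{mu_within} inside a network and
#' \code{mu_between} across networks, and \eqn{s_{ij} = -1} on a fixed
#' random \code{neg_fraction} of between-network edges (anticorrelation
#' structure shared across the cohort), \eqn{+1} elsewhere.
#'
#' @param node_table node table defining nodes and networks (default: the
#'   412-node table).
#' @param dataset_sizes participants per dataset; datasets are labeled
#'   A, B, C, ... Default \code{c(18, 29, 34, 28)}.
#' @param mu_within,mu_between mean edge magnitude inside / across networks
#'   (\code{mu_within > mu_between >= 0}).
#' @param sigma_subject,sigma_dataset,sigma_noise SDs of the subject-level
#'   offset, dataset-level offset, and per-edge Gaussian noise.
#' @param effect_delta additive within-network increase in the fear
#'   condition.
#' @param affected_network network label receiving the planted effect
#'   (default: \code{"Somatomotor"} if present in the node table, otherwise
#'   its first network).
#' @param neg_fraction fraction of between-network edges drawn negative.
#' @param age_mean,age_sd age distribution (normal, truncated at >= 18).
#' @param clip if TRUE, clip weights into [-1, 1].
#' @param seed integer RNG seed.
#' @return list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(node_table = default_node_table(),
                             dataset_sizes = c(18L, 29L, 34L, 28L),
                             mu_within = 0.5, mu_between = 0.2,
                             sigma_subject = 0.05, sigma_dataset = 0.03,
                             sigma_noise = 0.1,
                             effect_delta = 0.15,
                             affected_network = NULL,
                             neg_fraction = 0.3,
                             age_mean = 22.06, age_sd = 4.79,
                             clip = FALSE, seed = 1L) {
  stopifnot(length(dataset_sizes) >= 1L, all(dataset_sizes >= 1L))
  if (!(mu_within > mu_between && mu_between >= 0))
    stop("require mu_within > mu_between >= 0", call. = FALSE)
  if (any(c(sigma_subject, sigma_dataset, sigma_noise) < 0))
    stop("SDs must be nonnegative", call. = FALSE)
  if (neg_fraction < 0 || neg_fraction > 1)
    stop("neg_fraction must be in [0, 1]", call. = FALSE)
  if (is.null(affected_network))
    affected_network <- if ("Somatomotor" %in% node_table$network)
      "Somatomotor" else node_table$network[1L]
  if (!affected_network %in% node_table$network)
    stop("affected_network '", affected_network, "' not in node table",
         call. = FALSE)
  structure(
    list(node_table = node_table, dataset_sizes = as.integer(dataset_sizes),
         mu_within = mu_within, mu_between = mu_between,
         sigma_subject = sigma_subject, sigma_dataset = sigma_dataset,
         sigma_noise = sigma_noise, effect_delta = effect_delta,
         affected_network = affected_network, neg_fraction = neg_fraction,
         age_mean = age_mean, age_sd = age_sd, clip = clip,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.sym_noise <- function(n, sd) {
  e <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  e[lower.tri(e, diag = TRUE)] <- 0
  e + t(e)
}

#' Generate a synthetic cohort of paired connectivity matrices
#'
#' See [synthetic_config()] for the generative model. Fully reproducible
#' from \code{config$seed}; the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return list with elements:
#'   \describe{
#'     \item{records}{list of [connectivity_record()] (2 per participant,
#'       fear then neutral).}
#'     \item{truth}{class \code{"ground_truth"}: \code{affected_node_ids}
#'       (0-based), \code{effect_delta}, \code{subject_offsets},
#'       \code{dataset_offsets}, \code{negative_edge_mask}.}
#'     \item{manifest}{cohort manifest data.frame (paths filled in by
#'       [write_cohort()]).}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nt <- config$node_table
  n <- n_nodes(nt)
  net <- nt$network
  within <- outer(net, net, "==")
  diag(within) <- FALSE
  affected <- net == config$affected_network
  eff_mask <- outer(affected, affected, "&")
  diag(eff_mask) <- FALSE

  .with_seed(config$seed, {
    # cohort-level anticorrelation structure: fixed set of negative
    # between-network edges, shared by all participants
    between_ut <- which(!within & upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    n_neg <- round(config$neg_fraction * nrow(between_ut))
    neg_idx <- if (n_neg > 0) sample(nrow(between_ut), n_neg) else integer(0)
    sign_m <- matrix(1, n, n)
    if (length(neg_idx)) {
      sign_m[between_ut[neg_idx, , drop = FALSE]] <- -1
      sign_m[between_ut[neg_idx, c(2L, 1L), drop = FALSE]] <- -1
    }

    mu <- ifelse(within, config$mu_within, config$mu_between)
    diag(mu) <- 0

    n_ds <- length(config$dataset_sizes)
    ds_labels <- LETTERS[seq_len(n_ds)]
    ds_offsets <- stats::rnorm(n_ds, sd = config$sigma_dataset)
    names(ds_offsets) <- ds_labels

    total <- sum(config$dataset_sizes)
    subj_offsets <- stats::rnorm(total, sd = config$sigma_subject)
    ages <- numeric(total)
    for (i in seq_len(total)) {
      repeat {
        a <- stats::rnorm(1, config$age_mean, config$age_sd)
        if (a >= 18) break
      }
      ages[i] <- a
    }

    records <- vector("list", 2L * total)
    manifest <- data.frame(
      participant_id = character(total), dataset_id = character(total),
      age = numeric(total), path_fear = NA_character_,
      path_neutral = NA_character_, stringsAsFactors = FALSE
    )
    p <- 0L
    for (d in seq_len(n_ds)) {
      for (s in seq_len(config$dataset_sizes[d])) {
        p <- p + 1L
        pid <- sprintf("%s%03d", ds_labels[d], s)
        base_mag <- mu + subj_offsets[p] + ds_offsets[d]
        base_mag[base_mag < 0] <- 0   # magnitudes stay nonnegative
        diag(base_mag) <- 0
        for (cond in c("fear", "neutral")) {
          mag <- base_mag + .sym_noise(n, config$sigma_noise)
          if (cond == "fear") mag <- mag + config$effect_delta * eff_mask
          w <- sign_m * mag
          diag(w) <- 0
          if (config$clip) w <- pmin(pmax(w, -1), 1)
          rec <- connectivity_record(w, pid, ds_labels[d], cond, ages[p], nt)
          records[[2L * (p - 1L) + if (cond == "fear") 1L else 2L]] <- rec
        }
        manifest$participant_id[p] <- pid
        manifest$dataset_id[p] <- ds_labels[d]
        manifest$age[p] <- ages[p]
      }
    }
    names(subj_offsets) <- manifest$participant_id

    truth <- structure(
      list(affected_node_ids = nt$node_id[affected],
           effect_delta = config$effect_delta,
           subject_offsets = subj_offsets,
           dataset_offsets = ds_offsets,
           negative_edge_mask = sign_m < 0),
      class = "ground_truth"
    )
    list(records = records, truth = truth, manifest = manifest)
  })
}

#' Per-node planted/not-planted flags from a ground truth
#'
#' @param truth a \code{ground_truth} from [generate_cohort()].
#' @param node_table the node table the cohort was generated against.
#' @return data.frame (node_id, network, planted); \code{planted} is TRUE for
#'   nodes carrying the within-network condition effect (all FALSE when
#'   \code{effect_delta = 0}).
#' @export
summarize_truth <- function(truth, node_table) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!all(truth$affected_node_ids %in% node_table$node_id))
    stop("ground truth refers to node ids outside the node table",
         call. = FALSE)
  planted <- node_table$node_id %in% truth$affected_node_ids &
    truth$effect_delta != 0
  data.frame(node_id = node_table$node_id, network = node_table$network,
             planted = planted, stringsAsFactors = FALSE)
}

#' Write a generated cohort to disk
#'
#' Writes one matrix file per record (tab-delimited, headerless), the cohort
#' manifest, the node table, and the per-node ground-truth table, so a
#' generated cohort can be reloaded with [load_cohort()].
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param node_table node table to write alongside (defaults to the one the
#'   records imply nothing about; pass the config's).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, node_table) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (rec in cohort$records) {
    fn <- sprintf("%s_%s.tsv", rec$participant_id, rec$condition)
    write_connectivity(rec, file.path(dir, fn))
    col <- paste0("path_", rec$condition)
    man[[col]][man$participant_id == rec$participant_id] <- fn
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  write_node_table(node_table, file.path(dir, "node_table.csv"))
  utils::write.csv(summarize_truth(cohort$truth, node_table),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
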