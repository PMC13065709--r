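#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort the rest of the workflow analyses.
#
# The generator emulates the structure of a multi-study task-fMRI cohort:
# four datasets of paired (fear/neutral) connectivity matrices per
# participant, block structure over 8 networks, negative edges between
# networks, nested subject/dataset variation, and a planted fear-condition
# increase of within-network connectivity concentrated in the somatomotor
# network (which lowers those nodes' participation coefficients).
#
# The workflow default is a desk-scale world -- 120 nodes, 40 participants --
# so every later stage runs in minutes; pass --full for the 412-node table
# with dataset sizes 18/29/34/28 (expect hours in stage 2).

suppressPackageStartupMessages({
  library(optparse)
  library(netcontrast)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260917L),
  make_option("--out", type = "character", default = "results"),
  make_option("--full", action = "store_true", default = FALSE)
)))

if (opts$full) {
  nt <- default_node_table()
  sizes <- c(18L, 29L, 34L, 28L)
} else {
  counts <- c(Visual = 8L, Somatomotor = 12L, DorsalAttention = 8L,
              VentralAttention = 8L, Limbic = 6L, Control = 6L, Default = 8L)
  cort <- do.call(rbind, lapply(c("left", "right"), function(h)
    do.call(rbind, lapply(names(counts), function(net)
      data.frame(hemisphere = h, network = net,
                 parcel_name = paste0(net, "_", seq_len(counts[[net]])))))))
  sub <- data.frame(hemisphere = rep(c("left", "right"), each = 4),
                    structure_name = c("Thalamus", "Hippocampus", "Amygdala",
                                       "Caudate"))
  nt <- build_node_table(cort, sub)          # 112 cortical + 8 subcortical
  sizes <- c(10L, 10L, 10L, 10L)
}

cfg <- synthetic_config(
  node_table = nt, dataset_sizes = sizes,
  effect_delta = 0.15, affected_network = "Somatomotor",
  seed = opts$seed
)

cohort <- generate_cohort(cfg)
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
write_cohort(cohort, file.path(opts$out, "cohort"), nt)

tr <- summarize_truth(cohort$truth, nt)
message(sprintf(
  "wrote %d matrices for %d participants (%d nodes, %d networks) to %s",
  length(cohort$records), nrow(cohort$manifest), n_nodes(nt),
  length(unique(nt$network)), file.path(opts$out, "cohort")))
message(sprintf("planted effect: +%.2f on within-%s edges (%d nodes)",
                cfg$effect_delta, cfg$affected_network, sum(tr$planted)))
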