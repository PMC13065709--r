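#!/usr/bin/env Rscript
# Stage 4: permutation-tested nested-CV linear SVM classification.
#
# For each graph metric, rows (one per participant-condition) are classified
# fear vs neutral by a linear SVM inside stratified 4-fold nested CV (the
# inner loop picks the misclassification cost c); accuracy, macro dice and
# feature weights are averaged over repetitions with re-drawn folds, a null
# distribution is built by swapping condition labels within participants,
# and features with |z| > 1.96 (z-scored mean weights) are flagged.
#
# Default 200 permutations keeps the demo in minutes; --permutations 1000
# reproduces the full protocol.

suppressPackageStartupMessages({
  library(optparse)
  library(netcontrast)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--results", type = "character", default = "results"),
  make_option("--metrics", type = "character", default = "pc,bc,e_global,q"),
  make_option("--permutations", type = "integer", default = 200L),
  make_option("--folds", type = "integer", default = 4L),
  make_option("--seed", type = "integer", default = 20260917L)
)))

long <- read.csv(file.path(opts$results, "metrics_nodes.csv"))
glob <- read.csv(file.path(opts$results, "metrics_global.csv"))

for (metric in strsplit(opts$metrics, ",")[[1]]) {
  feats <- feature_matrix(if (metric %in% c("pc", "bc")) long else glob,
                          metric)
  cfg <- cv_config(k_folds = opts$folds, n_permutations = opts$permutations,
                   seed = opts$seed + match(metric,
                                            c("pc", "bc", "e_global", "q")))
  res <- permutation_classification(feats, cfg)
  deg <- degenerate_report(res$last_truth, res$last_predictions)

  jsonlite::write_json(
    list(metric = metric, mean_accuracy = res$mean_accuracy,
         mean_dice = res$mean_dice, p_perm = res$p_perm,
         n_flagged = length(res$flagged_features),
         flagged_features = res$flagged_features,
         degenerate = deg$collapsed),
    file.path(opts$results, paste0("classification_", metric, ".json")),
    auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(feature = feats$feature_names,
                       mean_weight = res$mean_weights, z = res$weight_z,
                       flagged = feats$feature_names %in% res$flagged_features),
            file.path(opts$results, paste0("weights_", metric, ".csv")),
            row.names = FALSE)
  write.csv(data.frame(null_accuracy = res$null_accuracies),
            file.path(opts$results, paste0("null_", metric, ".csv")),
            row.names = FALSE)

  message(sprintf(
    "%s: accuracy %.2f%%, dice %.3f, p_perm = %.3f, %d feature(s) |z| > 1.96%s",
    metric, res$mean_accuracy, res$mean_dice, res$p_perm,
    length(res$flagged_features),
    if (deg$collapsed) sprintf(" [degenerate: all-%s predictions]",
                               deg$predicted_class) else ""))
}
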