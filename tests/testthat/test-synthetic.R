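test_that("generation is deterministic and leaves the caller's RNG alone", {
  nt <- small_node_table(2L)         # 32 nodes
  cfg <- synthetic_config(node_table = nt, dataset_sizes = c(2, 2, 2, 2),
                          seed = 42)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- generate_cohort(cfg)
  after <- runif(1)
  expect_identical(before, after)    # RNG state restored

  b <- generate_cohort(cfg)
  expect_identical(
    lapply(a$records, `[[`, "matrix"),
    lapply(b$records, `[[`, "matrix"))
  expect_identical(a$manifest, b$manifest)
})

test_that("generated records satisfy the connectivity invariants", {
  nt <- small_node_table(2L)
  for (seed in c(1, 7)) {
    cfg <- synthetic_config(node_table = nt, dataset_sizes = c(2, 3),
                            seed = seed)
    coh <- generate_cohort(cfg)
    expect_length(coh$records, 10L)
    for (rec in coh$records) {
      expect_true(all(diag(rec$matrix) == 0))
      expect_lt(max(abs(rec$matrix - t(rec$matrix))), 1e-12)
      expect_identical(nrow(rec$matrix), n_nodes(nt))
    }
    ages <- coh$manifest$age
    expect_true(all(ages >= 18))
  }
})

test_that("planted within-network effect has the configured mean", {
  nt <- small_node_table(4L)         # 64 nodes, 8 per network
  delta <- 0.15
  cfg <- synthetic_config(node_table = nt,
                          dataset_sizes = c(10, 10, 10, 10),
                          effect_delta = delta, affected_network = "Net3",
                          seed = 5)
  coh <- generate_cohort(cfg)
  aff <- nt$node_id[nt$network == "Net3"] + 1L
  diffs <- vapply(seq(1, length(coh$records), 2), function(i) {
    f <- coh$records[[i]]$matrix[aff, aff]
    n <- coh$records[[i + 1]]$matrix[aff, aff]
    mean((f - n)[upper.tri(f)])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - delta), 3 * se)

  # null case: no systematic difference anywhere
  cfg0 <- synthetic_config(node_table = nt,
                           dataset_sizes = c(10, 10, 10, 10),
                           effect_delta = 0, seed = 6)
  coh0 <- generate_cohort(cfg0)
  diffs0 <- vapply(seq(1, length(coh0$records), 2), function(i) {
    d <- coh0$records[[i]]$matrix - coh0$records[[i + 1]]$matrix
    mean(d[upper.tri(d)])
  }, numeric(1))
  se0 <- sd(diffs0) / sqrt(length(diffs0))
  expect_lt(abs(mean(diffs0)), 3 * se0)
})

test_that("summarize_truth flags exactly the planted nodes", {
  nt <- small_node_table(4L)
  cfg <- synthetic_config(node_table = nt, dataset_sizes = c(2, 2),
                          effect_delta = 0.2, affected_network = "Net1",
                          seed = 2)
  coh <- generate_cohort(cfg)
  tr <- summarize_truth(coh$truth, nt)
  expect_identical(sum(tr$planted), 8L)
  expect_true(all(tr$network[tr$planted] == "Net1"))

  cfg0 <- synthetic_config(node_table = nt, dataset_sizes = c(2, 2),
                           effect_delta = 0, seed = 2)
  tr0 <- summarize_truth(generate_cohort(cfg0)$truth, nt)
  expect_false(any(tr0$planted))

  bad <- coh$truth
  bad$affected_node_ids <- c(bad$affected_node_ids, 999L)
  expect_error(summarize_truth(bad, nt), "outside")
})

test_that("written cohorts reload identically through the manifest", {
  nt <- small_node_table(1L)
  cfg <- synthetic_config(node_table = nt, dataset_sizes = c(2, 2), seed = 3)
  coh <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(coh, dir, nt)
  recs <- load_cohort(file.path(dir, "manifest.csv"), read_node_table(
    file.path(dir, "node_table.csv")))
  expect_length(recs, length(coh$records))
  ord <- function(r) paste(r$participant_id, r$condition)
  m0 <- lapply(coh$records, `[[`, "matrix")
  names(m0) <- vapply(coh$records, ord, "")
  for (r in recs)
    expect_identical(r$matrix, m0[[ord(r)]])
})

test_that("config validation rejects impossible worlds", {
  nt <- small_node_table(1L)
  expect_error(synthetic_config(node_table = nt, mu_within = 0.1,
                                mu_between = 0.2), "mu_within")
  expect_error(synthetic_config(node_table = nt, sigma_noise = -1), "SDs")
  expect_error(synthetic_config(node_table = nt, neg_fraction = 1.5),
               "neg_fraction")
  expect_error(synthetic_config(node_table = nt,
                                affected_network = "NotANet"),
               "not in node table")
})
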