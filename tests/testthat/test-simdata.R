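test_that("noise-free simulation reproduces planted means exactly", {
  cfg <- sim_config(n_reporters = 60, noise_sd = 0, bias_coeffs = 0,
                    low_confidence_rate = 0, seed = 11)
  sim <- simulate_expression_dataset(cfg)
  d <- sim$dataset
  tps <- cfg$time_points
  for (j in seq_along(tps)) {
    dep <- d$design$array_id[d$design$time == tps[j] &
                               d$design$condition == "depleted"]
    ctl <- d$design$array_id[d$design$time == tps[j] &
                               d$design$condition == "control"]
    # control arrays carry only the baseline: constant across replicates
    expect_true(all(apply(d$M[, ctl], 1, function(x) diff(range(x)) == 0)))
    diff_means <- rowMeans(d$M[, dep]) - rowMeans(d$M[, ctl])
    expect_equal(unname(diff_means), sim$truth[[paste0("effect_", tps[j])]])
  }
})

test_that("simulation is deterministic under the seed and emits the design", {
  cfg <- sim_config(n_reporters = 40, seed = 5)
  a <- simulate_expression_dataset(cfg)
  b <- simulate_expression_dataset(cfg)
  expect_identical(a$dataset$M, b$dataset$M)
  expect_identical(a$dataset$confidence, b$dataset$confidence)
  expect_identical(a$truth, b$truth)
  # 2 conditions x 5 time points x 5 replicates minus one control dropout
  expect_equal(ncol(a$dataset$M), 49)
  expect_equal(sum(a$dataset$design$condition == "control" &
                     a$dataset$design$time == 4), 4)
  expect_equal(nrow(a$truth), 40)
})

test_that("regulated-reporter count matches the configured fraction", {
  cfg <- sim_config(n_reporters = 16000, frac_regulated = 0.03, seed = 2)
  sim <- simulate_expression_dataset(cfg)
  expect_equal(sum(sim$truth$regulated), 480) # 0.03 * 16000, by enumeration
  expect_true(all(sim$truth$persistent ==
    apply(sign(as.matrix(sim$truth[, grep("^effect_", names(sim$truth))])), 1,
          function(s) all(s != 0) && length(unique(s)) == 1)))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(frac_regulated = 1.2), "frac_regulated")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(dropout = list(list(condition = "bad", time = 4))),
               "dropout")
})

test_that("promoter simulation plants sites at the requested frequencies", {
  ids <- sprintf("G%04d", 1:60)
  fg <- ids[1:26]
  ps <- simulate_promoter_set(60, length = 500, gc = 0.4,
    planted = list(list(motif = "TGCGCACGGACT", name = "m1",
                        fg = 1.0, bg = 0.0)),
    foreground_ids = fg, seed = 3)
  planted_fg <- unique(ps$truth$gene[ps$truth$motif == "m1"])
  expect_setequal(planted_fg, fg)
  # every planted site is present verbatim at its recorded position
  for (i in seq_len(nrow(ps$truth))) {
    r <- ps$truth[i, ]
    expect_equal(substr(ps$promoters$seqs[[r$gene]], r$position,
                        r$position + nchar(r$site) - 1), r$site)
  }
})

test_that("fractional presence rounds to whole carriers (0.115 x 26 -> 3)", {
  ps <- simulate_promoter_set(240, length = 300,
    planted = list(list(motif = "TGCGCACGGACT", fg = 0.115, bg = 0.0)),
    foreground_ids = sprintf("G%04d", 1:26), seed = 9)
  expect_equal(length(unique(ps$truth$gene)), 3)
})

test_that("unplanted sequence matches a single base at its composition rate", {
  ps <- simulate_promoter_set(30, length = 2000, gc = 0.5, seed = 4)
  sc <- scan_promoters(ps$promoters, motif_pattern("A", "A"),
                       strands = "plus")
  rate <- sum(sc$plus) / (30 * 2000)
  expect_lt(abs(rate - 0.25), 0.01)
})

test_that("promoter simulation validates its inputs", {
  expect_error(simulate_promoter_set(10, planted =
    list(list(motif = "AXG", fg = 0.5, bg = 0))), "IUPAC")
  expect_error(simulate_promoter_set(10, length = 5, planted =
    list(list(motif = "ACGTACGTAA", fg = 0.5, bg = 0))), "longer")
})

test_that("annotation table reproduces planted overlaps exactly", {
  ids <- sprintf("G%04d", 1:20)
  tm <- simulate_annotation_table(20, 5, term_size_range = c(5, 5),
    planted = list(list(term = "T001", genes = ids[1:5])), seed = 6)
  gene_list <- c(ids[1:4], ids[20]) # 4 of the planted term, 1 outside
  k <- length(intersect(tm$T001, gene_list))
  expect_equal(k, 4)
  expect_equal(length(tm$T001), 5)
  tm2 <- simulate_annotation_table(20, 5, term_size_range = c(5, 5),
    planted = list(list(term = "T001", genes = ids[1:5])), seed = 6)
  expect_identical(tm, tm2)
  expect_error(simulate_annotation_table(10, 2,
    planted = list(list(term = "T001", genes = c("Gxxxx")))), "universe")
})

test_that("interaction table honours density bounds and the seed", {
  nodes <- c("a", "b", "c", "d")
  expect_equal(nrow(simulate_interaction_table(nodes, edge_density = 0)), 0)
  full <- simulate_interaction_table(nodes, edge_density = 1)
  expect_equal(nrow(full), 6) # complete graph on 4 nodes, no self-loops
  expect_false(any(full$source == full$target))
  e1 <- simulate_interaction_table(nodes, edge_density = 0.5, seed = 8)
  e2 <- simulate_interaction_table(nodes, edge_density = 0.5, seed = 8)
  expect_identical(e1, e2)
})
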