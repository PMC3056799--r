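test_that("identical seeds give bit-identical simulations", {
  cfg <- small_sim_config(seed = 3)
  a <- simulate_experiment_pair(cfg)
  b <- simulate_experiment_pair(cfg)
  expect_identical(a$exp1$signal, b$exp1$signal)
  expect_identical(a$exp2$detection, b$exp2$detection)
  expect_identical(a$truth, b$truth)
  expect_identical(a$gene_sets, b$gene_sets)
  d <- simulate_experiment_pair(small_sim_config(seed = 4))
  expect_false(identical(a$exp1$signal, d$exp1$signal))
})

test_that("platform A is a strict subset of platform B", {
  sim <- simulate_experiment_pair(small_sim_config())
  expect_true(all(rownames(sim$exp1$signal) %in% rownames(sim$exp2$signal)))
  expect_lt(nrow(sim$exp1$signal), nrow(sim$exp2$signal))
  expect_identical(rownames(sim$exp1$signal),
                   sim$annotation$probe_id[sim$annotation$on_platform_A])
})

test_that("group sizes mirror the study design by default", {
  cfg <- simulation_config()
  expect_identical(cfg$group_sizes$exp1,
                   c(CONTROL = 4L, ALC_NTC = 2L, ALC_NTO = 2L))
  expect_identical(cfg$group_sizes$exp2,
                   c(CONTROL = 4L, ALC_NTC = 3L, ALC_NTO = 4L))
})

test_that("planted categories are disjoint and live on both platforms", {
  sim <- simulate_experiment_pair(small_sim_config())
  cats <- list(sim$truth$planted_down_ids, sim$truth$planted_up_ids,
               sim$truth$planted_off_ids, sim$truth$planted_subgroup_ids)
  all_ids <- unlist(cats)
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_true(all(all_ids %in% rownames(sim$exp1$signal)))
  # planted set members are also disjoint from the other categories
  members <- unlist(sim$gene_sets$members[
    grepl("^PLANTED", sim$gene_sets$name)])
  member_probes <- sim$annotation$probe_id[
    match(members, sim$annotation$gene_symbol)]
  expect_length(intersect(member_probes, all_ids), 0L)
  expect_true(all(member_probes %in% rownames(sim$exp1$signal)))
})

test_that("a null configuration plants nothing and has symmetric group differences", {
  cfg <- null_simulation_config(n_shared = 400L, seed = 9)
  sim <- simulate_experiment_pair(cfg)
  expect_length(sim$truth$planted_down_ids, 0L)
  expect_length(sim$truth$planted_up_ids, 0L)
  expect_length(sim$truth$planted_off_ids, 0L)
  expect_true(all(sim$truth$true_log2_effect == 0))
  logm <- log_transform(sim$exp1)
  alc <- sim$exp1$groups != "CONTROL"
  diffs <- rowMeans(logm[, alc]) - rowMeans(logm[, !alc])
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)))
})

test_that("zero planted effect size zeroes the ground truth", {
  cfg <- small_sim_config()
  cfg$planted_log2_effect <- 0
  cfg$set_shift_log2 <- 0
  sim <- simulate_experiment_pair(cfg)
  expect_true(all(sim$truth$true_log2_effect == 0))
})

test_that("detection calls track the signal threshold when flips are off", {
  cfg <- small_sim_config()
  cfg$detection_flip_prob <- 0
  sim <- simulate_experiment_pair(cfg)
  for (e in list(sim$exp1, sim$exp2)) {
    expected <- ifelse(log2(e$signal) >= cfg$detection_threshold_log2,
                       "P", "A")
    expect_identical(unname(e$detection), unname(expected))
  }
})

test_that("planted off probes are present in every control and absent in every alcohol array", {
  sim <- simulate_experiment_pair(small_sim_config())
  for (e in list(sim$exp1, sim$exp2)) {
    calls <- e$detection[sim$truth$planted_off_ids, , drop = FALSE]
    expect_true(all(calls[, e$groups == "CONTROL"] == "P"))
    expect_true(all(calls[, e$groups != "CONTROL"] == "A"))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(group_sizes = list(
    exp1 = c(CONTROL = 1L, ALC_NTC = 2L, ALC_NTO = 2L),
    exp2 = c(CONTROL = 4L, ALC_NTC = 3L, ALC_NTO = 4L))), ">= 2 arrays")
  expect_error(simulation_config(n_probes_platform_A = 20000L,
                                 n_probes_platform_B = 20000L),
               "strict subset")
  expect_error(simulation_config(n_probes_platform_B = 300L,
                                 n_probes_platform_A = 200L,
                                 n_planted_down = 250L),
               "exceed")
  expect_error(simulation_config(detection_flip_prob = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(noise_log2_sd = 0), "> 0")
})

test_that("planted effects are recovered by the replication intersection", {
  # planted_log2_effect = 4 x noise sd, 4 vs 4 in experiment 1
  sim <- simulate_experiment_pair(small_sim_config(seed = 21))
  f1 <- present_filter(sim$exp1)
  f2 <- present_filter(sim$exp2)
  d1 <- differential_table(sim$exp1, "CTRL_vs_ALC",
                           probes = f1$retained_probe_ids)
  d2 <- differential_table(sim$exp2, "CTRL_vs_ALC",
                           probes = f2$retained_probe_ids)
  shared <- intersect(intersect(f1$retained_probe_ids,
                                f2$retained_probe_ids),
                      rownames(sim$exp1$signal))
  rep <- directional_intersection(d1, d2, shared)
  planted <- c(sim$truth$planted_down_ids, sim$truth$planted_up_ids)
  expect_gte(mean(planted %in% rep$shared_records$probe_id), 0.9)
  # recovered directions match the planted sign
  rec <- rep$shared_records
  down <- rec$probe_id %in% sim$truth$planted_down_ids
  expect_true(all(rec$direction[down] == "down"))
  up <- rec$probe_id %in% sim$truth$planted_up_ids
  expect_true(all(rec$direction[up] == "up"))
})
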