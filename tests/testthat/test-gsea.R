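test_that("ES profile on a 10-gene universe matches exhaustive enumeration", {
  ids <- sprintf("g%02d", 1:10)
  ranked <- make_ranked(ids, scores = 10:1)
  members <- ids[c(1, 2, 5)]
  got <- enrichment_score(ranked, members)
  oracle <- es_oracle(ranked$gene_ids, members)
  expect_equal(got$es_profile, oracle$profile, tolerance = 1e-12)
  expect_equal(got$es_peak, oracle$peak, tolerance = 1e-12)
  expect_identical(got$peak_position, oracle$pos)
  expect_identical(got$leading_edge, oracle$leading)
  # hand arithmetic: hits at 1,2 then miss, miss, hit
  expect_equal(got$es_profile[1:5],
               c(1/3, 2/3, 2/3 - 1/7, 2/3 - 2/7, 1 - 2/7), tolerance = 1e-12)
  expect_identical(got$peak_position, 5L)
})

test_that("a set occupying the exact top of the list scores a peak of 1", {
  ids <- sprintf("g%03d", 1:200)
  ranked <- make_ranked(ids)
  got <- enrichment_score(ranked, ids[1:17])
  expect_equal(got$es_peak, 1, tolerance = 1e-12)
  expect_identical(got$peak_position, 17L)
  expect_identical(got$leading_edge, ids[1:17])
})

test_that("bottom-concentrated sets score below top-concentrated ones", {
  ids <- sprintf("g%03d", 1:100)
  ranked <- make_ranked(ids)
  top <- enrichment_score(ranked, ids[1:10])$es_peak
  bottom <- enrichment_score(ranked, ids[91:100])$es_peak
  expect_lt(bottom, top)
  expect_lte(bottom, 1 / 90 + 1e-12)
})

test_that("the running sum telescopes to zero when all members are present", {
  set.seed(17)
  ids <- sprintf("g%03d", 1:500)
  ranked <- make_ranked(ids, scores = stats::rnorm(500))
  es <- enrichment_score(ranked, sample(ids, 40))
  expect_lt(abs(es$es_profile[length(ids)]), 1e-9)
})

test_that("permuting non-members below the last member leaves the peak unchanged", {
  ids <- sprintf("g%03d", 1:60)
  members <- ids[c(3, 10, 22)]
  base <- enrichment_score(make_ranked(ids), members)
  # shuffle the tail beyond the last member (rank 22)
  set.seed(9)
  ids2 <- c(ids[1:22], sample(ids[23:60]))
  shuffled <- enrichment_score(make_ranked(ids2, scores = 60:1), members)
  expect_equal(shuffled$es_peak, base$es_peak, tolerance = 1e-12)
  expect_identical(shuffled$peak_position, base$peak_position)
})

test_that("members absent from the universe warn; empty sets error", {
  ids <- sprintf("g%02d", 1:10)
  ranked <- make_ranked(ids)
  expect_warning(es <- enrichment_score(ranked, c("g01", "nope")),
                 "absent from the ranked universe")
  expect_identical(es$n_hits, 1L)
  expect_error(suppressWarnings(enrichment_score(ranked, "nope")),
               "no gene-set member")
})

test_that("rank_genes puts control-high genes first and is antisymmetric", {
  eff <- stats::setNames(c(-3, 3), c("P001_at", "P002_at"))
  exp <- noisy_experiment(n_probes = 40, noise_sd = 0.2, effects = eff,
                          seed = 14)
  ann <- identity_annotation(exp)
  ranked <- rank_genes(exp, "CTRL_vs_NTC", ann)
  expect_identical(ranked$gene_ids[1L], "P001")          # lower in treated
  expect_identical(ranked$gene_ids[length(ranked$gene_ids)], "P002")
  rev_ <- reverse_ranking(ranked)
  expect_identical(rev_$gene_ids, rev(ranked$gene_ids))
  expect_equal(rev_$scores, rev(-ranked$scores))
  expect_identical(rev_$ref_label, "ALC_NTC")
})

test_that("welch_t ranking equals independently sorted welch_test statistics", {
  exp <- noisy_experiment(n_probes = 25, seed = 19)
  ann <- identity_annotation(exp)
  ranked <- rank_genes(exp, "CTRL_vs_NTC", ann, metric = "welch_t")
  logm <- log_transform(exp)
  ref <- names(exp$groups)[exp$groups == "CONTROL"]
  tst <- names(exp$groups)[exp$groups == "ALC_NTC"]
  t_oracle <- vapply(rownames(logm), function(p)
    welch_test(logm[p, ref], logm[p, tst])$t, numeric(1L))
  expected_order <- names(sort(-t_oracle))
  expect_identical(ranked$gene_ids, sub("_at$", "", expected_order))
  expect_equal(unname(sort(-ranked$scores)), unname(sort(-t_oracle)),
               tolerance = 1e-10)
})

test_that("probes collapse to genes by maximum absolute metric", {
  m <- rbind(
    a1_at = c(10, 10, 10, 10, 9, 9, 9, 9),     # gene A, strong
    a2_at = c(10, 10, 10, 10, 9.9, 9.9, 9.9, 9.9), # gene A, weak
    b1_at = c(8, 8, 8, 8, 8.05, 8.05, 8.05, 8.05))
  colnames(m) <- sprintf("s%d", 1:8)
  set.seed(4)
  exp <- make_experiment(m + stats::rnorm(length(m), 0, 0.02),
                         stats::setNames(c(rep("CONTROL", 4),
                                           rep("ALC_NTC", 4)),
                                         colnames(m)))
  ann <- data.frame(probe_id = rownames(m),
                    gene_symbol = c("A", "A", "B"),
                    on_platform_A = TRUE)
  ranked <- rank_genes(exp, "CTRL_vs_NTC", ann)
  expect_identical(sort(ranked$gene_ids), c("A", "B"))
  # gene A inherits the strong probe's positive (control-high) score
  expect_identical(ranked$gene_ids[1L], "A")
  expect_gt(ranked$scores[1L], 5)
})

test_that("gene-mode permutation p hits its floor for a planted top set", {
  exp <- noisy_experiment(n_probes = 1000, noise_sd = 0.2, seed = 2,
                          effects = stats::setNames(
                            rep(-2, 20), sprintf("P%03d_at", 1:20)))
  ann <- identity_annotation(exp)
  members <- ann$gene_symbol[1:20]
  res <- permutation_pvalue(exp, "CTRL_vs_NTC", members, n_perm = 999,
                            mode = "gene", seed = 33, annotation = ann)
  expect_equal(res$p_value, 1 / 1000)
  expect_gte(res$p_value, 1 / (999 + 1))  # lower bound by construction
})

test_that("gene-mode p-values are calibrated for random sets on null data", {
  exp <- noisy_experiment(n_probes = 600, seed = 27)
  ann <- identity_annotation(exp)
  set.seed(41)
  draws <- replicate(250, {
    members <- sample(ann$gene_symbol, 15)
    permutation_pvalue(exp, "CTRL_vs_NTC", members, n_perm = 199,
                       mode = "gene", seed = sample.int(1e6, 1),
                       annotation = ann)$p_value
  })
  frac <- mean(draws <= 0.05)
  se <- sqrt(0.05 * 0.95 / 250)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
})

test_that("phenotype mode enumerates all 70 relabellings at 4 vs 4", {
  exp <- noisy_experiment(n_probes = 80, seed = 23,
                          effects = stats::setNames(rep(-1.5, 10),
                                                    sprintf("P%03d_at", 1:10)))
  ann <- identity_annotation(exp)
  res <- permutation_pvalue(exp, "CTRL_vs_NTC", ann$gene_symbol[1:10],
                            n_perm = 999, mode = "phenotype", seed = 5,
                            annotation = ann)
  expect_identical(res$n_perm_used, 70L)
  expect_gte(res$p_value, 1 / 70)
  expect_lte(res$p_value, 1)
  # strong coherent shift: only near-identity relabellings can beat it
  expect_lte(res$p_value, 5 / 70)
})

test_that("campaign counts tests as contrasts x sets and applies the alpha^2/2 rule", {
  sim <- simulate_experiment_pair(small_sim_config(seed = 13))
  g <- gsea_campaign(sim$exp1, sim$exp2, sim$gene_sets, sim$annotation,
                     n_perm = 199, seed = 3)
  expect_identical(g$report$n_tests_total, 4L * 25L)
  expect_equal(g$report$expected_shared, 100 * 0.05^2 / 2)
  expect_identical(nrow(g$results), 2L * 4L * 25L)
  if (g$report$n_shared_observed > 0)
    expect_equal(g$report$fdr,
                 g$report$expected_shared / g$report$n_shared_observed)
  # planted sets are shared-significant in the pooled-alcohol contrast
  shared <- g$report$shared_sets
  planted_names <- sim$truth$planted_enriched_set_names
  hit <- shared$set[shared$contrast == "CTRL_vs_ALC" &
                      shared$enriched_in == "CONTROL"]
  expect_true(all(planted_names %in% hit))
  # leading edges of planted sets are non-empty member lists
  planted_rows <- g$results[g$results$set %in% planted_names &
                              g$results$contrast == "CTRL_vs_ALC", ]
  expect_true(all(nzchar(planted_rows$leading_edge)))
})

test_that("contrasts missing a group are skipped with a warning", {
  sim <- simulate_experiment_pair(small_sim_config())
  # drop the NTC arrays from experiment 1
  keep <- sim$exp1$groups != "ALC_NTC"
  e1 <- expression_experiment("platform_A",
                              sim$exp1$signal[, keep],
                              sim$exp1$detection[, keep],
                              sim$exp1$groups[keep])
  expect_warning(
    g <- gsea_campaign(e1, sim$exp2, sim$gene_sets[1:5, ], sim$annotation,
                       n_perm = 199, seed = 3),
    "skipping contrast")
  expect_setequal(unique(g$results$contrast),
                  c("CTRL_vs_ALC", "CTRL_vs_NTO"))
  expect_identical(g$report$n_tests_total, 2L * 5L)
})

test_that("campaign p-values are reproducible under the same seed", {
  sim <- simulate_experiment_pair(small_sim_config())
  sets <- sim$gene_sets[1:8, ]
  a <- gsea_campaign(sim$exp1, sim$exp2, sets, sim$annotation,
                     contrasts = "CTRL_vs_ALC", n_perm = 199, seed = 77)
  b <- gsea_campaign(sim$exp1, sim$exp2, sets, sim$annotation,
                     contrasts = "CTRL_vs_ALC", n_perm = 199, seed = 77)
  expect_identical(a$results, b$results)
})
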