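# In-code fixtures: small experiments built deterministically.

# Experiment from explicit log2 means: one row per probe, one column per
# sample; detection defaults to all-Present.
make_experiment <- function(log2_signal, groups, detection = NULL,
                            platform_id = "test_platform") {
  signal <- 2^log2_signal
  if (is.null(detection)) {
    detection <- matrix("P", nrow(signal), ncol(signal),
                        dimnames = dimnames(signal))
  }
  expression_experiment(platform_id, signal, detection, groups)
}

# A small two-group experiment with i.i.d. normal log2 noise around a flat
# baseline, plus optional planted effects (named vector probe -> log2 shift
# applied to the test arm).
noisy_experiment <- function(n_probes = 40, n_ref = 4, n_test = 4,
                             baseline = 8, noise_sd = 0.25,
                             effects = NULL, seed = 1,
                             test_group = "ALC_NTC") {
  set.seed(seed)
  probes <- sprintf("P%03d_at", seq_len(n_probes))
  samples <- c(sprintf("ctrl_%d", seq_len(n_ref)),
               sprintf("alc_%d", seq_len(n_test)))
  groups <- stats::setNames(c(rep("CONTROL", n_ref),
                              rep(test_group, n_test)), samples)
  m <- matrix(stats::rnorm(n_probes * length(samples), baseline, noise_sd),
              n_probes, length(samples), dimnames = list(probes, samples))
  if (!is.null(effects))
    m[names(effects), groups != "CONTROL"] <-
      m[names(effects), groups != "CONTROL"] + effects
  make_experiment(m, groups)
}

# Annotation with a one-to-one probe -> gene map.
identity_annotation <- function(exp) {
  data.frame(probe_id = rownames(exp$signal),
             gene_symbol = sub("_at$", "", rownames(exp$signal)),
             on_platform_A = TRUE, stringsAsFactors = FALSE)
}

# Ranked list built directly from scores (descending), bypassing the
# expression machinery, for enrichment-score unit tests.
make_ranked <- function(gene_ids, scores = rev(seq_along(gene_ids)),
                        contrast = "CTRL_vs_ALC") {
  o <- order(-scores, gene_ids)
  structure(list(contrast = contrast, gene_ids = gene_ids[o],
                 scores = scores[o], orientation = "forward",
                 ref_label = "CONTROL", test_label = "ALC"),
            class = "ranked_list")
}

# Brute-force running-sum oracle: walks the ranked list step by step.
es_oracle <- function(gene_ids, members) {
  N <- length(gene_ids)
  n_hits <- sum(gene_ids %in% members)
  running <- numeric(N)
  s <- 0
  for (i in seq_len(N)) {
    s <- s + if (gene_ids[i] %in% members) 1 / n_hits else -1 / (N - n_hits)
    running[i] <- s
  }
  peak <- which.max(running)
  list(profile = running, peak = running[peak], pos = peak,
       leading = gene_ids[seq_len(peak)][gene_ids[seq_len(peak)] %in% members])
}

# A small simulation shared by several pipeline-level tests.
small_sim_config <- function(seed = 11) {
  simulation_config(
    n_probes_platform_B = 800L, n_probes_platform_A = 500L,
    n_planted_down = 25L, n_planted_up = 15L, n_planted_off = 4L,
    n_planted_subgroup = 20L,
    n_gene_sets = 25L, set_size_range = c(8L, 15L),
    n_planted_enriched_sets = 2L,
    seed = seed)
}
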