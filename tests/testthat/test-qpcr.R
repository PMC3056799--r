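qpcr_fixture <- function(ct_target_ctrl, ct_target_trt,
                         ct_ref_ctrl = 20, ct_ref_trt = 20,
                         group_trt = "ALC_NTC") {
  n <- length(ct_target_ctrl)
  m <- length(ct_target_trt)
  data.frame(
    sample = c(sprintf("c%d", seq_len(n)), sprintf("t%d", seq_len(m)),
               sprintf("c%d", seq_len(n)), sprintf("t%d", seq_len(m))),
    group = c(rep("CONTROL", n), rep(group_trt, m),
              rep("CONTROL", n), rep(group_trt, m)),
    gene = c(rep("Ngn2", n + m), rep("Gapdh", n + m)),
    replicate = 1L,
    ct = c(ct_target_ctrl, ct_target_trt,
           rep(ct_ref_ctrl, n), rep(ct_ref_trt, m)),
    stringsAsFactors = FALSE)
}

test_that("ddct reproduces hand arithmetic (ddCt 1 -> fold -2)", {
  meas <- qpcr_fixture(ct_target_ctrl = c(25, 25, 25),
                       ct_target_trt = c(26, 26, 26))
  res <- ddct(meas, "Ngn2")
  expect_identical(nrow(res), 1L)
  expect_equal(res$delta_delta_ct, 1)
  expect_equal(res$relative_quantity, 0.5)
  expect_equal(res$signed_fold, -2)
})

test_that("equal dCt in treated and control gives quantity and fold 1", {
  meas <- qpcr_fixture(c(25, 24.5, 25.5), c(25.5, 25, 24.5))
  res <- ddct(meas, "Ngn2")
  expect_equal(res$delta_delta_ct, 0, tolerance = 1e-12)
  expect_equal(res$relative_quantity, 1, tolerance = 1e-12)
  expect_equal(res$signed_fold, 1, tolerance = 1e-12)
})

test_that("ddct is invariant to per-sample machine offsets", {
  meas <- qpcr_fixture(c(25, 25.3, 24.7), c(26.1, 26, 25.9))
  base <- ddct(meas, "Ngn2")
  shifted <- meas
  # add a different constant to every Ct of each sample (target and ref)
  off <- stats::setNames(seq(0.1, by = 0.3,
                             length.out = length(unique(meas$sample))),
                         unique(meas$sample))
  shifted$ct <- shifted$ct + off[shifted$sample]
  res <- ddct(shifted, "Ngn2")
  expect_equal(res$delta_delta_ct, base$delta_delta_ct, tolerance = 1e-12)
  expect_equal(res$signed_fold, base$signed_fold, tolerance = 1e-12)
})

test_that("missing reference Ct errors with the sample name", {
  meas <- qpcr_fixture(c(25, 25), c(26, 26))
  meas <- meas[!(meas$sample == "t2" & meas$gene == "Gapdh"), ]
  expect_error(ddct(meas, "Ngn2"), "t2")
  expect_error(ddct(meas, "Ngn2", control_group = "MOCK"), "absent")
  expect_error(ddct(qpcr_fixture(25:26, 26:27), "Sox5"), "no Ct for target")
})

test_that("replicate-level aggregation matches sample-level on balanced data", {
  meas <- rbind(qpcr_fixture(c(25, 25.4), c(26, 26.4)),
                qpcr_fixture(c(25.2, 25.2), c(26.2, 26.2)))
  meas$replicate <- rep(1:2, each = nrow(meas) / 2)
  a <- ddct(meas, "Ngn2", aggregate = "sample")
  b <- ddct(meas, "Ngn2", aggregate = "replicate")
  expect_equal(a$delta_delta_ct, b$delta_delta_ct, tolerance = 1e-12)
})

test_that("a perfect dilution series is inverted exactly", {
  amounts <- 2^(0:7)                      # spans log10(128) = 2.1 units
  curve <- data.frame(log10_amount = log10(amounts),
                      ct = 30 - log2(amounts))   # slope -1/log10(2)=-3.3219
  fit <- standard_curve_quantify(curve, unknown_ct = curve$ct)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(fit$amount, amounts, tolerance = 1e-6)
  expect_equal(fit$efficiency, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # an unknown at a curve point's Ct recovers that point's amount
  one <- standard_curve_quantify(curve, unknown_ct = curve$ct[4L])
  expect_equal(one$amount, amounts[4L], tolerance = 1e-6)
})

test_that("degenerate standard curves are rejected", {
  curve <- data.frame(log10_amount = c(0, 1, 2), ct = c(30, 30.01, 29.99))
  expect_error(standard_curve_quantify(curve, 30), "flat")
  short <- data.frame(log10_amount = c(0, 0.5, 1), ct = c(30, 28, 26))
  expect_error(standard_curve_quantify(short, 28), "log10 units")
  expect_error(standard_curve_quantify(short[1:2, ], 28), ">= 3")
})

test_that("noisy standard curves recover the truth within simulation error", {
  set.seed(55)
  reps <- replicate(200, {
    la <- seq(0, 3, length.out = 7)
    ct <- 32 - 3.3219 * la + stats::rnorm(7, 0, 0.15)
    curve <- data.frame(log10_amount = la, ct = ct)
    true_ct <- 32 - 3.3219 * 1.5
    standard_curve_quantify(curve, true_ct)$amount
  })
  expect_lt(abs(mean(reps) - 10^1.5), 3 * sd(reps) / sqrt(200))
})

test_that("two-group ANOVA reduces to the pooled t-test (F = t^2)", {
  set.seed(3)
  v <- c(stats::rnorm(6, 10), stats::rnorm(6, 10.8))
  g <- rep(c("CONTROL", "ALC_NTO"), each = 6)
  res <- group_compare(v, g)
  tt <- stats::t.test(v[g == "CONTROL"], v[g == "ALC_NTO"], var.equal = TRUE)
  expect_equal(res$anova_f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$anova_p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$pairwise$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA matches a hand-computed F on a three-group fixture", {
  v <- c(1, 2, 3, 4, 5, 6, 8, 9, 10)
  g <- rep(c("CONTROL", "ALC_NTC", "ALC_NTO"), each = 3)
  gm <- tapply(v, g, mean); n <- 3
  ss_b <- n * sum((gm - mean(v))^2)
  ss_w <- sum((v - gm[g])^2)
  f_exp <- (ss_b / 2) / (ss_w / 6)
  p_exp <- stats::pf(f_exp, 2, 6, lower.tail = FALSE)
  res <- group_compare(v, g)
  expect_equal(res$anova_f, f_exp, tolerance = 1e-10)
  expect_equal(res$anova_p, p_exp, tolerance = 1e-10)
  expect_identical(nrow(res$pairwise), 3L)
})

test_that("identical constant groups give p = 1, tiny groups error", {
  res <- group_compare(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_identical(res$anova_p, 1)
  expect_identical(res$pairwise$p_value, rep(1, 3))
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), "degenerate")
  expect_error(group_compare(1:3, rep("a", 3)), ">= 2 groups")
})
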