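#' Delta-delta-Ct relative quantification
#'
#' For each sample, the target gene's mean Ct (over replicate wells) is
#' normalized against the reference gene measured in the same sample
#' (`dCt = Ct_target - Ct_reference`); each treated group's `ddCt` is the
#' mean dCt of its samples minus the mean dCt of the control group.
#' Relative quantity is `2^-ddCt`, mapped to the signed fold convention
#' (quantities below 1 reported as -1/q). With
#' `aggregate = "replicate"`, dCt is computed per replicate index instead
#' of per sample mean.
#'
#' @param measurements data.frame with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct` (Ct in cycles, > 0).
#' @param target_gene Gene to quantify.
#' @param reference_gene Internal reference gene (default `"Gapdh"`).
#' @param control_group Group used as calibrator (default `"CONTROL"`).
#' @param aggregate `"sample"` (default) or `"replicate"`.
#' @return data.frame with one row per non-control group: `gene`, `group`,
#'   `delta_ct` (group mean), `delta_delta_ct`, `relative_quantity`,
#'   `signed_fold`.
#' @export
ddct <- function(measurements, target_gene, reference_gene = "Gapdh",
                 control_group = "CONTROL",
                 aggregate = c("sample", "replicate")) {
  aggregate <- match.arg(aggregate)
  need <- c("sample", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(measurements$ct <= 0))
    stop("Ct values must be > 0", call. = FALSE)
  if (!control_group %in% measurements$group)
    stop("control group '", control_group, "' absent from measurements",
         call. = FALSE)

  key <- if (aggregate == "sample") measurements$sample
         else paste(measurements$sample, measurements$replicate, sep = "#")
  tgt <- measurements$gene == target_gene
  ref <- measurements$gene == reference_gene
  if (!any(tgt)) stop("no Ct for target gene ", target_gene, call. = FALSE)
  ct_t <- tapply(measurements$ct[tgt], key[tgt], mean)
  ct_r <- tapply(measurements$ct[ref], key[ref], mean)
  missing_ref <- setdiff(names(ct_t), names(ct_r))
  if (length(missing_ref))
    stop("missing reference Ct (", reference_gene, ") for sample: ",
         sub("#.*$", "", missing_ref[1L]), call. = FALSE)
  dct <- ct_t - ct_r[names(ct_t)]
  grp <- measurements$group[match(names(ct_t), key)]

  ctrl_mean <- mean(dct[grp == control_group])
  if (is.nan(ctrl_mean))
    stop("control group has no measurements of the target gene",
         call. = FALSE)
  treated <- setdiff(unique(grp), control_group)
  out <- do.call(rbind, lapply(treated, function(g) {
    ddc <- mean(dct[grp == g]) - ctrl_mean
    q <- 2^(-ddc)
    data.frame(gene = target_gene, group = g,
               delta_ct = mean(dct[grp == g]),
               delta_delta_ct = ddc,
               relative_quantity = q,
               signed_fold = if (q >= 1) q else -1 / q,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Standard-curve relative quantification
#'
#' Fits the least-squares line `Ct = a * log10(amount) + b` through the
#' dilution-series points and inverts it at the unknown's Ct. The slope
#' yields the amplification efficiency `10^(-1/a) - 1` (reported for QC;
#' -3.3219 cycles/log10 is the perfect-doubling slope).
#'
#' @param curve_points data.frame with columns `log10_amount` and `ct`
#'   (>= 3 points spanning >= 2 log10 units).
#' @param unknown_ct Ct value(s) of the unknown(s).
#' @return List: `amount` (recovered relative amounts), `slope`,
#'   `intercept`, `r_squared`, `efficiency`.
#' @export
standard_curve_quantify <- function(curve_points, unknown_ct) {
  if (!all(c("log10_amount", "ct") %in% names(curve_points)))
    stop("curve_points needs columns log10_amount, ct", call. = FALSE)
  if (nrow(curve_points) < 3L)
    stop("need >= 3 standard-curve points", call. = FALSE)
  span <- diff(range(curve_points$log10_amount))
  if (span < 2)
    stop(sprintf("dilution series spans only %.2f log10 units (need >= 2)",
                 span), call. = FALSE)
  fit <- stats::lm(ct ~ log10_amount, data = curve_points)
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  if (!is.finite(a) || abs(a) < 0.1)
    stop("standard curve is flat (|slope| < 0.1); cannot quantify",
         call. = FALSE)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((curve_points$ct - mean(curve_points$ct))^2)
  list(amount = 10^((unknown_ct - b) / a),
       slope = a, intercept = b,
       r_squared = r2,
       efficiency = 10^(-1 / a) - 1)
}

#' One-way ANOVA with pairwise Student's t follow-up
#'
#' Classic fixed-effects one-way ANOVA (so with two groups `F = t^2`
#' exactly), followed by all pairwise two-sided pooled-variance t-tests.
#' When the between-group variance is exactly zero (all group means equal)
#' the p-value is reported as 1.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group label per measurement (>= 2 groups, >= 2 values
#'   each).
#' @return List: `anova_f`, `anova_p`, `pairwise` (data.frame `group1`,
#'   `group2`, `t`, `p_value`).
#' @export
group_compare <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L))
    stop("degenerate group (< 2 values): ",
         names(tab)[which(tab < 2L)[1L]], call. = FALSE)
  gm <- tapply(values, groups, mean)
  if (max(gm) - min(gm) == 0) {
    f <- 0; p <- 1
  } else {
    a <- stats::anova(stats::lm(values ~ factor(groups)))
    f <- a$`F value`[1L]
    p <- a$`Pr(>F)`[1L]
    if (!is.finite(p)) p <- 1
  }
  pairs <- utils::combn(names(tab), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    x <- values[groups == g1]; y <- values[groups == g2]
    if (stats::var(x) + stats::var(y) == 0) {
      tt <- list(statistic = if (mean(x) == mean(y)) 0 else
        sign(mean(x) - mean(y)) * Inf,
        p.value = if (mean(x) == mean(y)) 1 else .Machine$double.xmin)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
    }
    data.frame(group1 = g1, group2 = g2, t = unname(tt$statistic[1L]),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(anova_f = f, anova_p = p, pairwise = pw)
}
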