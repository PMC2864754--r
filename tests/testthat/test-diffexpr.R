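# Per-gene two-way ANOVA, contrasts, variance fractions and the
# threshold filter.

test_that("two-way sums of squares match the cell-mean oracle and car", {
  sheet <- make_design(4)
  set.seed(10)
  y <- rnorm(nrow(sheet), sd = 0.3) +
    0.2 * sheet$day + 0.4 * (sheet$treatment == "treated") * (sheet$day == 3)
  res <- fit_gene_anova(y, sheet$day, sheet$treatment)
  o <- oracle_twoway_ss(y, sheet$day, sheet$treatment)
  # balanced design: Type II equals the classical decomposition
  expect_equal(o$day + o$trt + o$int + o$res, o$tot, tolerance = 1e-10)
  expect_equal(res$eta2_day, o$day / o$tot, tolerance = 1e-8)
  expect_equal(res$eta2_treat, o$trt / o$tot, tolerance = 1e-8)
  expect_equal(res$eta2_interaction, o$int / o$tot, tolerance = 1e-8)
  # p-values agree with car::Anova Type II on the same fit
  fit <- lm(y ~ d * t, data.frame(y = y, d = factor(sheet$day),
                                  t = factor(sheet$treatment)))
  tab <- car::Anova(fit, type = 2)
  expect_equal(res$p_day, tab["d", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$p_treat, tab["t", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$p_interaction, tab["d:t", "Pr(>F)"], tolerance = 1e-8)
})

test_that("unbalanced (degraded-replicate) designs agree with car Type II", {
  sheet <- make_design(4, drop_degraded = TRUE)
  set.seed(11)
  y <- rnorm(nrow(sheet), sd = 0.2) + 0.15 * sheet$day +
    0.3 * (sheet$treatment == "treated")
  res <- fit_gene_anova(y, sheet$day, sheet$treatment)
  fit <- lm(y ~ d * t, data.frame(y = y, d = factor(sheet$day),
                                  t = factor(sheet$treatment)))
  tab <- car::Anova(fit, type = 2)
  expect_equal(res$p_day, tab["d", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$p_treat, tab["t", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$p_interaction, tab["d:t", "Pr(>F)"], tolerance = 1e-8)
})

test_that("constant profiles get F = 0, p = 1 by convention", {
  sheet <- make_design(3)
  res <- fit_gene_anova(rep(0.7, nrow(sheet)), sheet$day, sheet$treatment)
  expect_equal(res$p_day, 1)
  expect_equal(res$p_treat, 1)
  expect_equal(res$p_d3, 1)
  expect_equal(res$eta2_day, 0)
})

test_that("a planted day-3 treated shift is detected with the right fold change", {
  sheet <- make_design(4)
  set.seed(12)
  y <- rnorm(nrow(sheet), sd = 0.05) +
    1 * (sheet$treatment == "treated" & sheet$day == 3)
  res <- fit_gene_anova(y, sheet$day, sheet$treatment)
  expect_lt(res$p_d3, 0.01)
  expect_equal(res$fc_d3, 10, tolerance = 0.15)
  expect_gt(res$p_d1, 0.05)
})

test_that("treatment-dominated profiles have treatment-dominated eta2", {
  # a strongly induced gene: large treated/control ratio every day
  sheet <- make_design(4)
  set.seed(13)
  y <- rnorm(nrow(sheet), sd = 0.05) +
    1.5 * (sheet$treatment == "treated") + 0.05 * sheet$day
  res <- fit_gene_anova(y, sheet$day, sheet$treatment)
  expect_gt(res$eta2_treat, 0.8)
  expect_gt(res$eta2_treat, 5 * res$eta2_day)
})

test_that("insufficient replication is an error", {
  sheet <- make_design(1)
  expect_error(fit_gene_anova(rnorm(nrow(sheet)), sheet$day,
                              sheet$treatment),
               "insufficient replication")
})

test_that("call_de assigns DE days, first-DE day and developmental flags", {
  sheet <- make_design(4)
  set.seed(14)
  n <- nrow(sheet)
  vals <- rbind(
    day1_only = rnorm(n, sd = 0.05) +
      0.8 * (sheet$treatment == "treated" & sheet$day == 1),
    dev_only = rnorm(n, sd = 0.05) + 0.4 * sheet$day,
    from_day2 = rnorm(n, sd = 0.05) +
      0.8 * (sheet$treatment == "treated" & sheet$day >= 2))
  colnames(vals) <- sheet$sample_id
  de <- call_de(expr_dataset(vals, sheet), alpha = 0.01)
  expect_true(1L %in% de$de_days[[1]])
  expect_equal(de$first_de_day[1], 1L)
  # in the exact (noise-free) construction the day-1 call is the only one
  vals0 <- vals
  vals0["day1_only", ] <- 0.8 * (sheet$treatment == "treated" &
                                   sheet$day == 1)
  de0 <- call_de(expr_dataset(vals0, sheet), alpha = 0.01)
  expect_equal(de0$de_days[[1]], 1L)
  expect_false(1 %in% de$de_days[[2]])
  expect_true(de$developmental[2])
  expect_true(is.na(de$first_de_day[2]))
  expect_equal(de$first_de_day[3], 2L)
  # monotone in alpha: larger alpha gives a superset of DE days
  de2 <- call_de(expr_dataset(vals, sheet), alpha = 0.1)
  for (i in 1:3) expect_true(all(de$de_days[[i]] %in% de2$de_days[[i]]))
})

test_that("null per-day contrasts hold their nominal type-I rate", {
  sheet <- make_design(4, drop_degraded = TRUE)
  set.seed(15)
  n_genes <- 1000
  vals <- matrix(rnorm(n_genes * nrow(sheet), sd = 0.1), n_genes,
                 dimnames = list(sprintf("n%04d", 1:n_genes),
                                 sheet$sample_id))
  an <- gene_anova(expr_dataset(vals, sheet))
  alpha <- 0.01
  hits <- sum(unlist(an[, paste0("p_d", 1:5)]) < alpha)
  rate <- hits / (n_genes * 5)
  expect_gt(rate, alpha * 0.7)
  expect_lt(rate, alpha * 1.3)
})

test_that("variance fractions recover a known mix within the bootstrap CI", {
  sheet <- make_design(4)
  # exact decomposition: profile equal to its day means -> DAY fraction 1
  yd <- (1:5 / 5)[sheet$day]
  vf <- variance_fractions(yd, sheet$day, sheet$treatment, n_boot = 50,
                           seed = 1)
  expect_equal(vf$fraction[vf$factor == "day"], 1, tolerance = 1e-10)
  # simulated mix: day and treatment effects against noise
  set.seed(16)
  y <- sqrt(2) * scale((1:5)[sheet$day])[, 1] +
    (sheet$treatment == "treated") * 2 + rnorm(nrow(sheet), sd = 1)
  vf2 <- variance_fractions(y, sheet$day, sheet$treatment, n_boot = 400,
                            seed = 2)
  day_row <- vf2[vf2$factor == "day", ]
  expect_true(day_row$ci_lo <= day_row$fraction &&
                day_row$fraction <= day_row$ci_hi)
  expect_gt(day_row$fraction, 0.2)
  trt_row <- vf2[vf2$factor == "treatment", ]
  expect_gt(trt_row$fraction, 0.1)
  expect_equal(sum(vf2$fraction), 1, tolerance = 1e-8)
})

test_that("the threshold filter applies its three rules per replicate", {
  stats <- expand.grid(gene = c("gA", "gB", "gC", "gD", "gE"),
                       day = 1L, replicate = 1:4,
                       stringsAsFactors = FALSE)
  stats$p_value <- 0.05
  stats$fold_change <- 2
  stats$log10_intensity <- 3
  # gA passes everywhere; gB fails fold change (1.0 everywhere);
  # gC dim intensity; gD p too large; gE passes in only 2 replicates
  stats$fold_change[stats$gene == "gB"] <- 1.0
  stats$log10_intensity[stats$gene == "gC"] <- 2.0
  stats$p_value[stats$gene == "gD"] <- 0.5
  stats$p_value[stats$gene == "gE" & stats$replicate <= 2] <- 0.5
  out <- threshold_filter(stats)
  expect_equal(out$gene, "gA")
  # a negative (down-regulated) fold change counts via its magnitude
  stats$fold_change[stats$gene == "gB"] <- -1.5
  out2 <- threshold_filter(stats)
  expect_setequal(out2$gene, c("gA", "gB"))
  expect_error(threshold_filter(stats, min_reps = 5), "min_reps")
})
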