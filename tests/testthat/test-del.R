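# Split-condition correlations, the link ANOVA, the classification
# cascade and DEL detection with its permutation FDR.

test_that("pearson_plc matches the direct formula and handles edge cases", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  # direct product-moment formula, computed independently
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_plc(x, y), direct)
  expect_equal(pearson_plc(x, x), 1)
  expect_equal(pearson_plc(x, -x), -1)
  expect_true(is.na(pearson_plc(x, rep(1, 4))))
  expect_warning(v <- pearson_plc(c(1, 2, NA, NA), c(1, NA, 2, 3)),
                 "3 complete pairs")
  expect_true(is.na(v))
})

test_that("the PLC cutoff is significant at the design's profile length", {
  expect_lt(plc_pvalue(0.75, 39), 0.01)
})

test_that("split-condition PLCs separate the two halves of the profile", {
  sheet <- make_design(4, drop_degraded = TRUE)
  n <- nrow(sheet)
  set.seed(20)
  z <- rnorm(5)
  trt <- sheet$treatment == "treated"
  a <- rnorm(n, sd = 0.05); b <- rnorm(n, sd = 0.05)
  a[trt] <- a[trt] + z[sheet$day[trt]]
  b[trt] <- b[trt] + 2 * z[sheet$day[trt]]
  vals <- rbind(ga = a, gb = b, gc = a + 1)
  colnames(vals) <- sheet$sample_id
  ds <- expr_dataset(vals, sheet)
  plc <- split_condition_plc(ds, "ga", "gb")
  expect_gt(plc[["plc_trt"]], 0.9)
  expect_lt(abs(plc[["plc_ctl"]]), 0.6)
  # identical profiles (up to a constant) correlate everywhere
  plc2 <- split_condition_plc(ds, "ga", "gc")
  expect_equal(unname(plc2), c(1, 1, 1), tolerance = 1e-10)
})

test_that("link ANOVA matches the balanced three-way cell-mean oracle", {
  sheet <- make_design(2)
  set.seed(21)
  ya <- rnorm(nrow(sheet), sd = 0.1) +
    0.5 * (sheet$treatment == "treated") * sheet$day / 5
  yb <- rnorm(nrow(sheet), sd = 0.1)
  vals <- rbind(ga = ya, gb = yb)
  colnames(vals) <- sheet$sample_id
  ds <- expr_dataset(vals, sheet)
  res <- fit_link_anova(ds, "ga", "gb")
  y <- c(ya, yb)
  g <- rep(c("a", "b"), each = nrow(sheet))
  o <- oracle_threeway_ss(y, g, rep(sheet$day, 2), rep(sheet$treatment, 2))
  tab <- attr(res, "table")
  # balanced: Type II SS equal the classical decomposition
  expect_equal(tab["gene:treatment", "Sum Sq"], o$ss13, tolerance = 1e-8)
  expect_equal(tab["gene:day", "Sum Sq"], o$ss12, tolerance = 1e-8)
  expect_equal(tab["gene:day:treatment", "Sum Sq"], o$ss123,
               tolerance = 1e-8)
  expect_equal(tab["Residuals", "Sum Sq"], o$res, tolerance = 1e-8)
})

test_that("parallel profiles give GENE-interaction p-values of 1", {
  sheet <- make_design(3)
  set.seed(22)
  ya <- rnorm(nrow(sheet), sd = 0.1) + 0.3 * sheet$day
  vals <- rbind(ga = ya, gb = ya + 2)
  colnames(vals) <- sheet$sample_id
  res <- fit_link_anova(expr_dataset(vals, sheet), "ga", "gb")
  expect_equal(res$p_gene_x_treat, 1)
  expect_equal(res$p_gene_x_day, 1)
  expect_equal(res$p_gene_x_day_x_treat, 1)
})

test_that("planted treatment-dependent divergence passes the ANOVA gate", {
  sheet <- make_design(4, drop_degraded = TRUE)
  set.seed(23)
  trt <- sheet$treatment == "treated"
  z <- rnorm(5)
  ya <- rnorm(nrow(sheet), sd = 0.05)
  yb <- rnorm(nrow(sheet), sd = 0.05)
  ya[trt] <- ya[trt] + 0.3 * z[sheet$day[trt]]
  yb[trt] <- yb[trt] + 1.2 * z[sheet$day[trt]]
  vals <- rbind(ga = ya, gb = yb)
  colnames(vals) <- sheet$sample_id
  res <- fit_link_anova(expr_dataset(vals, sheet), "ga", "gb")
  expect_lt(min(res$p_gene_x_treat, res$p_gene_x_day_x_treat), 0.01)
})

test_that("the classification cascade follows its documented order", {
  p <- del_params()
  rec <- function(...) {
    modifyList(list(plc_all = 0.9, plc_trt = 0.9, plc_ctl = 0.9,
                    n_trt = 19, n_ctl = 20, p_gene_x_treat = 1,
                    p_gene_x_day_x_treat = 1, plc_day_trt = 0,
                    plc_day_ctl = 0, p_day_a = 1, p_day_b = 1),
               list(...))
  }
  # the reference enabled pattern: treated 0.9032, control 0.1286
  expect_equal(classify_link(rec(plc_trt = 0.9032, plc_ctl = 0.1286,
                                 p_gene_x_treat = 0.001), p), "enabled")
  expect_equal(classify_link(rec(plc_trt = 0.1286, plc_ctl = 0.9032,
                                 p_gene_x_day_x_treat = 0.001), p),
               "sensitive")
  # without the ANOVA gate the same correlations stay unclassified
  expect_equal(classify_link(rec(plc_trt = 0.9032, plc_ctl = 0.1286,
                                 plc_all = 0.6), p), "none")
  # both-condition co-expression without day structure is resistant
  expect_equal(classify_link(rec(), p), "resistant")
  # with synchronised day means and significant DAY effects: developmental
  expect_equal(classify_link(rec(plc_day_trt = 0.95, plc_day_ctl = 0.95,
                                 p_day_a = 1e-5, p_day_b = 1e-4), p),
               "developmental")
  # overall correlation with no condition/day structure is ambiguous
  expect_equal(classify_link(rec(plc_all = 0.876, plc_trt = 0.6,
                                 plc_ctl = 0.6), p), "ambiguous")
  # too few pairs in a condition cannot be classified
  expect_equal(classify_link(rec(n_trt = 5), p), "none")
})

test_that("identical conditions yield no enabled or sensitive links", {
  bb <- generate_backbone(60, m = 2, seed = 31)
  sheet <- make_design(4)
  set.seed(32)
  base <- matrix(rnorm(60 * 5, sd = 0.3), 60, 5)
  vals <- base[, sheet$day] + matrix(rnorm(60 * nrow(sheet), sd = 0.05),
                                     60, nrow(sheet))
  dimnames(vals) <- list(igraph::V(bb)$name, sheet$sample_id)
  dels <- detect_dels(expr_dataset(vals, sheet), bb, del_params())
  expect_equal(sum(dels$links$link_class %in% c("enabled", "sensitive")), 0)
})

test_that("planted enabled links are recovered and unplanted edges stay clean", {
  # pooled over replicate simulations for a stable rate estimate
  hits <- 0; planted_n <- 0; fp <- 0; clean_n <- 0
  for (r in 1:2) {
    bb <- generate_backbone(300, m = 3, seed = r)
    set1 <- pick_set(bb, 1, 8)
    set2 <- pick_set(bb, 2, 8, avoid = set1)
    sim <- simulate_dataset(bb, truth_config(
      planted_enabled = list(set1), planted_sensitive = list(set2),
      seed = 100 + r))
    dels <- detect_dels(sim$dataset, bb, del_params())
    tl <- sim$truth_links
    found_en <- with(dels$links[dels$links$link_class == "enabled", ],
                     ekey(gene_a, gene_b))
    found_se <- with(dels$links[dels$links$link_class == "sensitive", ],
                     ekey(gene_a, gene_b))
    planted_en <- with(tl[tl$class == "enabled", ], ekey(gene_a, gene_b))
    planted_se <- with(tl[tl$class == "sensitive", ], ekey(gene_a, gene_b))
    hits <- hits + sum(planted_en %in% found_en)
    planted_n <- planted_n + length(planted_en)
    fp <- fp + sum(!(c(found_en, found_se) %in% c(planted_en, planted_se)))
    clean_n <- clean_n + nrow(dels$links) - length(planted_en) -
      length(planted_se)
    # every DEL is a backbone edge by construction
    bb_keys <- with(igraph::as_data_frame(bb, "edges"), ekey(from, to))
    expect_true(all(c(found_en, found_se) %in% bb_keys))
  }
  expect_gte(hits / planted_n, 0.8)
  expect_lte(fp / clean_n, 0.05)
})

test_that("classification is invariant to swapping the two genes", {
  bb <- generate_backbone(80, m = 2, seed = 41)
  set1 <- pick_set(bb, 1, 6)
  sim <- simulate_dataset(bb, truth_config(planted_enabled = list(set1),
                                           seed = 42))
  dels <- detect_dels(sim$dataset, bb, del_params())
  links <- dels$links
  some <- links[links$link_class != "none", ][1:5, ]
  some <- some[!is.na(some$gene_a), ]
  for (i in seq_len(nrow(some))) {
    sw <- some[i, ]
    swapped <- list(
      plc_all = sw$plc_all, plc_trt = sw$plc_trt, plc_ctl = sw$plc_ctl,
      n_trt = sw$n_trt, n_ctl = sw$n_ctl,
      p_gene_x_treat = sw$p_gene_x_treat,
      p_gene_x_day_x_treat = sw$p_gene_x_day_x_treat,
      plc_day_trt = sw$plc_day_trt, plc_day_ctl = sw$plc_day_ctl,
      p_day_a = sw$p_day_b, p_day_b = sw$p_day_a)   # genes swapped
    expect_equal(classify_link(swapped, dels$params), sw$link_class)
  }
})

test_that("raising plc_high never increases the DEL fraction", {
  bb <- generate_backbone(120, m = 2, seed = 51)
  set1 <- pick_set(bb, 1, 6)
  sim <- simulate_dataset(bb, truth_config(planted_enabled = list(set1),
                                           seed = 52))
  counts <- vapply(c(0.7, 0.8, 0.9), function(hi) {
    d <- detect_dels(sim$dataset, bb, del_params(plc_high = hi))
    sum(d$links$link_class %in% c("enabled", "sensitive"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the permutation FDR is small for planted signal, honest for noise", {
  bb <- generate_backbone(150, m = 2, seed = 61)
  set1 <- pick_set(bb, 1, 7)
  set2 <- pick_set(bb, 2, 7, avoid = set1)
  sim <- simulate_dataset(bb, truth_config(
    planted_enabled = list(set1), planted_sensitive = list(set2),
    seed = 62))
  f <- estimate_del_fdr(sim$dataset, bb, del_params(), n_perm = 20,
                        seed = 63)
  expect_gt(f$observed, 5)
  expect_lt(f$fdr, 0.5)
  # pure noise: either nothing is observed (FDR undefined by convention)
  # or the estimate is near 1
  sim0 <- simulate_dataset(bb, truth_config(seed = 64))
  f0 <- estimate_del_fdr(sim0$dataset, bb, del_params(), n_perm = 20,
                         seed = 65)
  if (f0$observed == 0) {
    expect_true(is.na(f0$fdr))
  } else {
    expect_gt(f0$fdr, 0.3)
  }
})
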