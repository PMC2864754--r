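# Two-way per-gene ANOVA (DAY x TREATMENT), per-day treatment contrasts,
# eta-squared variance decomposition, DE calling and threshold filtering.
#
# The design is shared by all genes, so sums of squares are computed for
# all complete-case genes at once from QR decompositions of the candidate
# model matrices (Type II: each term adjusted for the terms that do not
# contain it). Genes with missing values fall back to a per-gene fit on
# their complete rows.

.anova_designs <- function(day, treatment) {
  day <- factor(day)
  trt <- factor(treatment, levels = c("control", "treated"))
  if (nlevels(day) < 2 || nlevels(trt) < 2) {
    .stopf("need >= 2 day levels and both treatments")
  }
  cell <- table(day, trt)
  if (any(cell == 0)) .stopf("insufficient replication: empty (day, treatment) cell")
  df <- data.frame(day = day, trt = trt)
  X <- list(
    d    = model.matrix(~day, df),
    t    = model.matrix(~trt, df),
    dt   = model.matrix(~day + trt, df),
    full = model.matrix(~day * trt, df)
  )
  if (nrow(df) <= ncol(X$full)) {
    .stopf("insufficient replication: no residual degrees of freedom")
  }
  list(day = day, trt = trt, qr = lapply(X, qr),
       df_day = nlevels(day) - 1L, df_trt = 1L,
       df_int = ncol(X$full) - ncol(X$dt),
       df_res = nrow(df) - ncol(X$full))
}

.rss <- function(qrobj, Y) colSums(qr.resid(qrobj, Y)^2)

# Type II sums of squares for a samples x genes response matrix
.twoway_ss <- function(des, Y) {
  rss_d <- .rss(des$qr$d, Y)
  rss_t <- .rss(des$qr$t, Y)
  rss_dt <- .rss(des$qr$dt, Y)
  rss_full <- .rss(des$qr$full, Y)
  n <- nrow(Y)
  ss_tot <- colSums(scale(Y, scale = FALSE)^2)
  list(ss_day = pmax(rss_t - rss_dt, 0),
       ss_trt = pmax(rss_d - rss_dt, 0),
       ss_int = pmax(rss_dt - rss_full, 0),
       ss_res = rss_full, ss_tot = ss_tot)
}

.twoway_p <- function(des, ss) {
  ms_res <- ss$ss_res / des$df_res
  fp <- function(ssx, dfx) {
    f <- (ssx / dfx) / ms_res
    p <- pf(f, dfx, des$df_res, lower.tail = FALSE)
    # all-constant profile convention: no variance at all -> F = 0, p = 1
    degen <- ss$ss_tot <= .Machine$double.eps * 1e3
    f[degen] <- 0; p[degen] <- 1
    # zero residual with non-zero effect: perfectly determined
    exact <- ms_res <= .Machine$double.eps * 1e3 & !degen
    f[exact] <- ifelse(ssx[exact] > .Machine$double.eps * 1e3, Inf, 0)
    p[exact] <- ifelse(ssx[exact] > .Machine$double.eps * 1e3, 0, 1)
    list(f = f, p = p)
  }
  list(day = fp(ss$ss_day, des$df_day),
       trt = fp(ss$ss_trt, des$df_trt),
       int = fp(ss$ss_int, des$df_int))
}

# per-day treated-vs-control contrasts against pooled residual variance
.day_contrasts <- function(des, Y, ss) {
  days <- levels(des$day)
  s2 <- ss$ss_res / des$df_res
  out <- lapply(days, function(d) {
    it <- des$day == d & des$trt == "treated"
    ic <- des$day == d & des$trt == "control"
    diff <- colMeans(Y[it, , drop = FALSE]) - colMeans(Y[ic, , drop = FALSE])
    se <- sqrt(s2 * (1 / sum(it) + 1 / sum(ic)))
    tval <- diff / se
    p <- 2 * pt(-abs(tval), des$df_res)
    degen <- ss$ss_tot <= .Machine$double.eps * 1e3
    p[degen] <- 1
    p[!degen & se <= .Machine$double.eps * 1e3] <-
      ifelse(abs(diff[!degen & se <= .Machine$double.eps * 1e3]) > 0, 0, 1)
    p[is.na(p)] <- 1
    list(diff = diff, p = p)
  })
  names(out) <- days
  out
}

#' Per-gene two-way ANOVA over the full design
#'
#' Fits, for every gene, the classical fixed-effects two-way ANOVA of the
#' log-ratio values on DAY (up to 5 levels), TREATMENT (2 levels) and their
#' interaction, using Type II sums of squares (robust to the mildly
#' unbalanced design left by a degraded replicate). Per-day contrasts test
#' the treated-vs-control difference within each day against the pooled
#' residual variance of the full model; the day-`d` fold change is
#' `10^(mean_treated(d) - mean_control(d))`.
#'
#' A gene with an all-constant profile gets F = 0 and p = 1 by convention.
#' Genes with missing values are fit on their complete rows.
#'
#' @param dataset an [expr_dataset()].
#' @return A data.frame with one row per gene: `p_day`, `p_treat`,
#'   `p_interaction`, `p_d1` ... `p_d5` (per-day contrast p-values),
#'   `fc_d1` ... `fc_d5` (ratio-scale fold changes), `eta2_day`,
#'   `eta2_treat`, `eta2_interaction`, `eta2_residual`.
#' @export
gene_anova <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  des <- .anova_designs(dataset$samples$day, dataset$samples$treatment)
  Y <- t(dataset$values)
  genes <- colnames(Y)
  days <- levels(des$day)
  res <- matrix(NA_real_, length(genes), 4 + 2 * length(days) + 4,
                dimnames = list(genes, c(
                  "p_day", "p_treat", "p_interaction",
                  paste0("p_d", days), paste0("fc_d", days),
                  "eta2_day", "eta2_treat", "eta2_interaction",
                  "eta2_residual", "df_res")))
  fill <- function(idx, des_i, Yi) {
    ss <- .twoway_ss(des_i, Yi)
    pv <- .twoway_p(des_i, ss)
    ctr <- .day_contrasts(des_i, Yi, ss)
    tot <- ifelse(ss$ss_tot <= .Machine$double.eps * 1e3, NA, ss$ss_tot)
    eta <- function(ssx) ifelse(is.na(tot), 0, ssx / tot)
    res[idx, "p_day"] <<- pv$day$p
    res[idx, "p_treat"] <<- pv$trt$p
    res[idx, "p_interaction"] <<- pv$int$p
    for (d in names(ctr)) {
      res[idx, paste0("p_d", d)] <<- ctr[[d]]$p
      res[idx, paste0("fc_d", d)] <<- 10^ctr[[d]]$diff
    }
    res[idx, "eta2_day"] <<- eta(ss$ss_day)
    res[idx, "eta2_treat"] <<- eta(ss$ss_trt)
    res[idx, "eta2_interaction"] <<- eta(ss$ss_int)
    res[idx, "eta2_residual"] <<- eta(ss$ss_res)
    res[idx, "df_res"] <<- des_i$df_res
  }
  complete <- colSums(is.na(Y)) == 0
  if (any(complete)) fill(which(complete), des, Y[, complete, drop = FALSE])
  for (j in which(!complete)) {
    ok <- !is.na(Y[, j])
    des_j <- tryCatch(
      .anova_designs(dataset$samples$day[ok], dataset$samples$treatment[ok]),
      error = function(e) NULL)
    if (is.null(des_j)) next
    fill(j, des_j, Y[ok, j, drop = FALSE])
  }
  out <- as.data.frame(res)
  out$gene <- genes
  out[, c("gene", setdiff(names(out), "gene"))]
}

#' Two-way ANOVA for a single gene profile
#'
#' Convenience wrapper around the machinery behind [gene_anova()] for one
#' expression profile.
#'
#' @param values numeric vector of log-ratio values.
#' @param day,treatment design vectors, same length as `values`.
#' @return A one-row data.frame as in [gene_anova()].
#' @export
fit_gene_anova <- function(values, day, treatment) {
  sid <- paste0("s", seq_along(values))
  m <- matrix(values, nrow = 1, dimnames = list("gene", sid))
  ds <- expr_dataset(m, data.frame(
    sample_id = sid, day = day, treatment = treatment,
    replicate = ave(seq_along(values), paste(day, treatment),
                    FUN = seq_along)))
  gene_anova(ds)
}

#' Call differentially expressed genes from per-day contrasts
#'
#' A gene is differentially expressed on day `d` when its per-day
#' treatment contrast is significant at `alpha`; it is developmental when
#' the DAY main effect is significant at `alpha` (the two calls are
#' independent). `first_de_day` is the earliest DE day.
#'
#' @param dataset an [expr_dataset()], or a data.frame already produced by
#'   [gene_anova()].
#' @param alpha significance threshold on raw p-values (default 0.01).
#' @return A data.frame of class `de_calls`: `gene`, `de_days` (list
#'   column), `first_de_day` (NA when never DE), `developmental`.
#' @export
call_de <- function(dataset, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  an <- if (inherits(dataset, "expr_dataset")) gene_anova(dataset) else dataset
  pcols <- grep("^p_d[0-9]$", names(an), value = TRUE)
  days <- as.integer(sub("^p_d", "", pcols))
  de_days <- lapply(seq_len(nrow(an)), function(i) {
    p <- unlist(an[i, pcols])
    days[!is.na(p) & p < alpha]
  })
  out <- data.frame(gene = an$gene, stringsAsFactors = FALSE)
  out$de_days <- de_days
  out$first_de_day <- vapply(de_days, function(d) {
    if (length(d)) min(d) else NA_integer_
  }, integer(1))
  out$developmental <- !is.na(an$p_day) & an$p_day < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("de_calls", class(out))
  out
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf(
    "de_calls: %d genes; %d DE on >= 1 day (%d on day 1); %d developmental (alpha = %g)\n",
    nrow(x), sum(!is.na(x$first_de_day)),
    sum(x$first_de_day == 1, na.rm = TRUE),
    sum(x$developmental), attr(x, "alpha")))
  invisible(x)
}

#' Variance fractions per experimental factor
#'
#' Decomposes a gene's total sum of squares into eta-squared fractions for
#' DAY, TREATMENT, their interaction and the residual, with bootstrap 95%
#' confidence intervals obtained by resampling observations within each
#' (day, treatment) cell.
#'
#' @param values numeric vector of log-ratio values.
#' @param day,treatment design vectors.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return A data.frame with columns `factor`, `fraction`, `ci_lo`, `ci_hi`.
#' @export
variance_fractions <- function(values, day, treatment, n_boot = 1000,
                               seed = NULL) {
  des <- .anova_designs(day, treatment)
  Y <- matrix(values, ncol = 1)
  one <- function(Yb) {
    ss <- .twoway_ss(des, Yb)
    tot <- ss$ss_tot
    if (tot <= .Machine$double.eps * 1e3) return(c(0, 0, 0, 0))
    c(ss$ss_day, ss$ss_trt, ss$ss_int, ss$ss_res) / tot
  }
  point <- one(Y)
  cells <- split(seq_along(values), paste(day, treatment))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- unlist(lapply(cells, function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
      Yb <- Y
      Yb[unlist(cells, use.names = FALSE), 1] <- values[idx]
      one(Yb)
    }, numeric(4))
  })
  ci <- apply(boots, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(factor = c("day", "treatment", "interaction", "residual"),
             fraction = point, ci_lo = ci[1, ], ci_hi = ci[2, ])
}

#' Threshold-based differential expression filter
#'
#' Replicate-level filter in the style of classic microarray GO-enrichment
#' preprocessing: a gene passes on a day when its per-replicate statistics
#' clear all three thresholds in at least `min_reps` replicates. Defaults
#' are p-value < 0.1, absolute fold change > 1.3, log10 intensity > 2.5 in
#' at least 3 of 4 replicates.
#'
#' @param stats data.frame with columns `gene`, `day`, `replicate`,
#'   `p_value`, `fold_change` (signed ratio; negative means
#'   down-regulation), `log10_intensity`.
#' @param p_max,fc_min,intensity_min thresholds (defaults 0.1, 1.3, 2.5).
#' @param min_reps minimum passing replicates (default 3).
#' @return A data.frame with columns `gene`, `day` for passing pairs.
#' @export
threshold_filter <- function(stats, p_max = 0.1, fc_min = 1.3,
                             intensity_min = 2.5, min_reps = 3) {
  need <- c("gene", "day", "replicate", "p_value", "fold_change",
            "log10_intensity")
  if (!all(need %in% names(stats))) {
    .stopf("stats needs columns: %s", paste(need, collapse = ", "))
  }
  max_reps <- max(table(paste(stats$gene, stats$day)))
  if (min_reps > max_reps) {
    .stopf("min_reps (%d) exceeds the replicate count (%d)",
           min_reps, max_reps)
  }
  pass <- stats$p_value < p_max &
    abs(stats$fold_change) > fc_min &
    stats$log10_intensity > intensity_min
  agg <- aggregate(pass, by = list(gene = stats$gene, day = stats$day), sum)
  out <- agg[agg$x >= min_reps, c("gene", "day")]
  rownames(out) <- NULL
  out[order(out$gene, out$day), , drop = FALSE]
}
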