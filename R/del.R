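# Differentially expressed link (DEL) detection: split-condition Pearson
# correlations on backbone edges, a three-way (GENE x DAY x TREATMENT)
# ANOVA gate, a deterministic classification cascade, and a permutation
# estimate of the false discovery rate.

#' Parameters for DEL detection
#'
#' @param plc_high Pearson correlation threshold above which co-expression
#'   is treated as significant (default 0.75; with 39 samples this bound
#'   corresponds to p well below 0.01, see [plc_pvalue()]).
#' @param plc_low ceiling below which co-expression counts as absent on
#'   the other side of an enabled/sensitive call (default 0.5).
#' @param alpha significance level for the ANOVA gates (default 0.01).
#' @param fbs_min backbone confidence floor; edges with `fbs < fbs_min`
#'   are excluded (default 3).
#' @param min_pairs minimum complete sample pairs per condition required
#'   to classify a link (default 10).
#' @return A list of class `del_params`.
#' @export
del_params <- function(plc_high = 0.75, plc_low = 0.5, alpha = 0.01,
                       fbs_min = 3, min_pairs = 10) {
  stopifnot(plc_low < plc_high, plc_high <= 1, plc_low >= -1,
            alpha > 0, alpha < 1)
  structure(list(plc_high = plc_high, plc_low = plc_low, alpha = alpha,
                 fbs_min = fbs_min, min_pairs = min_pairs),
            class = "del_params")
}

#' Pearson correlation with pairwise deletion
#'
#' Standard product-moment correlation over complete pairs. Returns `NA`
#' (with a warning) when fewer than 3 complete pairs remain, and `NA` when
#' either vector is constant.
#'
#' @param x,y numeric vectors of equal length.
#' @return A correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_plc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    .warnf("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Significance of a Pearson correlation
#'
#' Two-sided p-value of the usual t-test for a product-moment correlation
#' of `r` over `n` observations; useful to check what co-expression level
#' a PLC cutoff corresponds to for a given profile length.
#'
#' @param r correlation.
#' @param n number of observations (>= 3).
#' @return A p-value.
#' @examples
#' plc_pvalue(0.75, 39)  # the default cutoff over a 39-sample profile
#' @export
plc_pvalue <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), n - 2)
}

#' Split-condition correlations for a gene pair
#'
#' Computes the Pearson correlation of the two genes' profiles over all
#' samples, over treated samples only, and over control samples only.
#'
#' @param dataset an [expr_dataset()].
#' @param gene_a,gene_b gene ids present in the dataset.
#' @return Named numeric vector `c(plc_all, plc_trt, plc_ctl)`.
#' @export
split_condition_plc <- function(dataset, gene_a, gene_b) {
  stopifnot(inherits(dataset, "expr_dataset"))
  x <- dataset$values[gene_a, ]
  y <- dataset$values[gene_b, ]
  it <- .cond_cols(dataset, "treated")
  ic <- .cond_cols(dataset, "control")
  c(plc_all = pearson_plc(x, y),
    plc_trt = pearson_plc(x[it], y[it]),
    plc_ctl = pearson_plc(x[ic], y[ic]))
}

#' Three-way link ANOVA for a gene pair
#'
#' Stacks the two genes' profiles and fits the fixed-effects three-way
#' ANOVA with factors GENE (2 levels), DAY, TREATMENT and all
#' interactions, using Type II sums of squares. The GENE interactions are
#' what distinguish a genuine link rewiring from two genes that merely
#' shift in parallel: parallel profiles give interaction p-values of 1.
#'
#' @param dataset an [expr_dataset()].
#' @param gene_a,gene_b gene ids.
#' @return A list with `p_gene_x_treat`, `p_gene_x_day`,
#'   `p_gene_x_day_x_treat` and the full `car::Anova` table as attribute
#'   `"table"`.
#' @export
fit_link_anova <- function(dataset, gene_a, gene_b) {
  stopifnot(inherits(dataset, "expr_dataset"))
  s <- dataset$samples
  y <- c(dataset$values[gene_a, ], dataset$values[gene_b, ])
  df <- data.frame(
    value = y,
    gene = factor(rep(c("a", "b"), each = nrow(s))),
    day = factor(rep(s$day, 2)),
    treatment = factor(rep(s$treatment, 2), levels = c("control", "treated")))
  df <- df[!is.na(df$value), ]
  cells <- table(df$gene, df$day, df$treatment)
  if (any(cells == 0)) .stopf("insufficient replication: empty design cell")
  n_par <- 2 * nlevels(df$day) * 2
  if (nrow(df) <= n_par) .stopf("insufficient replication: no residual df")
  fit <- lm(value ~ gene * day * treatment, data = df)
  tab <- car::Anova(fit, type = 2)
  ss <- tab[["Sum Sq"]]
  names(ss) <- rownames(tab)
  p <- tab[["Pr(>F)"]]
  names(p) <- rownames(tab)
  eps <- .Machine$double.eps * 1e3 * max(1, sum(df$value^2))
  # degenerate fits (zero residual or zero term SS) get the documented
  # conventions rather than NaN
  fixp <- function(term) {
    pv <- p[[term]]
    if (is.na(pv)) pv <- if (ss[[term]] <= eps) 1 else 0
    if (ss[[term]] <= eps) pv <- 1
    pv
  }
  out <- list(p_gene_x_treat = fixp("gene:treatment"),
              p_gene_x_day = fixp("gene:day"),
              p_gene_x_day_x_treat = fixp("gene:day:treatment"))
  attr(out, "table") <- tab
  out
}

#' Classify one backbone link from its record
#'
#' Deterministic decision cascade over the split-condition correlations,
#' the GENE-interaction ANOVA p-values and the day-level structure:
#'
#' * `enabled`: treated-only co-expression (`plc_trt >= plc_high`,
#'   `plc_ctl < plc_low`) with a significant GENE x TREATMENT or
#'   GENE x DAY x TREATMENT interaction;
#' * `sensitive`: the mirror image (control-only co-expression);
#' * `developmental`: co-expression at resistant level in both conditions
#'   that is explained by shared day dependence (per-day-mean profiles
#'   correlate at `plc_high` in both conditions and both genes have a
#'   significant DAY effect);
#' * `resistant`: co-expression in both conditions without that day
#'   structure;
#' * `ambiguous`: overall co-expression (`plc_all >= plc_high`) that no
#'   other class explains;
#' * `none`: everything else, including records with too few complete
#'   pairs.
#'
#' @param record a list or one-row data.frame with fields `plc_all`,
#'   `plc_trt`, `plc_ctl`, `n_trt`, `n_ctl`, `p_gene_x_treat`,
#'   `p_gene_x_day_x_treat`, `plc_day_trt`, `plc_day_ctl`, `p_day_a`,
#'   `p_day_b` (missing fields are treated as `NA`).
#' @param params a [del_params()] object.
#' @return A single class string.
#' @export
classify_link <- function(record, params = del_params()) {
  g <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }
  n_trt <- g("n_trt"); n_ctl <- g("n_ctl")
  if (!is.na(n_trt) && n_trt < params$min_pairs) return("none")
  if (!is.na(n_ctl) && n_ctl < params$min_pairs) return("none")
  plc_all <- g("plc_all"); plc_trt <- g("plc_trt"); plc_ctl <- g("plc_ctl")
  gate <- suppressWarnings(
    min(g("p_gene_x_treat"), g("p_gene_x_day_x_treat"), na.rm = TRUE))
  hi <- params$plc_high; lo <- params$plc_low; a <- params$alpha
  ok <- function(x) !is.na(x)
  if (ok(plc_trt) && ok(plc_ctl)) {
    if (plc_trt >= hi && plc_ctl < lo && is.finite(gate) && gate < a) {
      return("enabled")
    }
    if (plc_ctl >= hi && plc_trt < lo && is.finite(gate) && gate < a) {
      return("sensitive")
    }
    if (plc_trt >= hi && plc_ctl >= hi) {
      dev <- ok(g("plc_day_trt")) && ok(g("plc_day_ctl")) &&
        g("plc_day_trt") >= hi && g("plc_day_ctl") >= hi &&
        ok(g("p_day_a")) && ok(g("p_day_b")) &&
        g("p_day_a") < a && g("p_day_b") < a
      return(if (dev) "developmental" else "resistant")
    }
  }
  if (ok(plc_all) && plc_all >= hi) return("ambiguous")
  "none"
}

# condition-wise correlation matrices, complete-pair counts and
# per-day-mean-profile correlations for a set of genes
.plc_tables <- function(dataset, genes) {
  V <- dataset$values[genes, , drop = FALSE]
  it <- .cond_cols(dataset, "treated")
  ic <- .cond_cols(dataset, "control")
  day <- dataset$samples$day
  daymeans <- function(cols) {
    sapply(sort(unique(day[cols])), function(d) {
      rowMeans(V[, cols[day[cols] == d], drop = FALSE], na.rm = TRUE)
    })
  }
  npairs <- function(cols) {
    ok <- t(!is.na(V[, cols, drop = FALSE])) * 1
    crossprod(ok)
  }
  safe_cor <- function(M) suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  list(all = safe_cor(t(V)),
       trt = safe_cor(t(V[, it, drop = FALSE])),
       ctl = safe_cor(t(V[, ic, drop = FALSE])),
       day_trt = safe_cor(t(daymeans(it))),
       day_ctl = safe_cor(t(daymeans(ic))),
       n_trt = npairs(it), n_ctl = npairs(ic))
}

#' Detect differentially expressed links on a backbone network
#'
#' Produces one record per retained backbone edge (edges restricted to
#' measured genes, `fbs >= fbs_min`): split-condition correlations, the
#' GENE-interaction ANOVA p-values (computed for enabled/sensitive
#' candidates, i.e. edges whose correlation pattern makes such a call
#' possible), and the link class from [classify_link()]. Only backbone
#' edges can become DELs: co-expression alone never creates a link.
#'
#' @param dataset an [expr_dataset()].
#' @param network undirected igraph with `fbs` edge attribute.
#' @param params a [del_params()] object.
#' @return An object of class `del_links`: list with `links` (data.frame
#'   of per-edge records), `params`, `n_genes`, `n_edges`.
#' @export
detect_dels <- function(dataset, network, params = del_params()) {
  stopifnot(inherits(dataset, "expr_dataset"))
  net <- restrict_to_measured(network, dataset)
  net <- .filter_fbs(net, params$fbs_min, strict = FALSE)
  ed <- igraph::as_data_frame(net, what = "edges")
  if (!nrow(ed)) {
    .warnf("no backbone edges among measured genes at fbs >= %g",
           params$fbs_min)
    links <- data.frame(gene_a = character(0), gene_b = character(0))
    return(structure(list(links = links, params = params,
                          n_genes = 0L, n_edges = 0L),
                     class = "del_links"))
  }
  genes <- sort(unique(c(ed$from, ed$to)))
  tabs <- .plc_tables(dataset, genes)
  an <- gene_anova(expr_dataset(dataset$values[genes, , drop = FALSE],
                                dataset$samples))
  p_day <- setNames(an$p_day, an$gene)
  a <- ed$from; b <- ed$to
  ix <- cbind(match(a, genes), match(b, genes))
  links <- data.frame(
    gene_a = pmin(a, b), gene_b = pmax(a, b),
    fbs = if ("fbs" %in% names(ed)) ed$fbs else 1,
    plc_all = tabs$all[ix], plc_trt = tabs$trt[ix], plc_ctl = tabs$ctl[ix],
    plc_day_trt = tabs$day_trt[ix], plc_day_ctl = tabs$day_ctl[ix],
    n_trt = tabs$n_trt[ix], n_ctl = tabs$n_ctl[ix],
    p_day_a = p_day[pmin(a, b)], p_day_b = p_day[pmax(a, b)],
    p_gene_x_treat = NA_real_, p_gene_x_day = NA_real_,
    p_gene_x_day_x_treat = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  enough <- !is.na(links$n_trt) & links$n_trt >= params$min_pairs &
    !is.na(links$n_ctl) & links$n_ctl >= params$min_pairs
  cand <- enough & !is.na(links$plc_trt) & !is.na(links$plc_ctl) &
    ((links$plc_trt >= params$plc_high & links$plc_ctl < params$plc_low) |
     (links$plc_ctl >= params$plc_high & links$plc_trt < params$plc_low))
  for (i in which(cand)) {
    pv <- tryCatch(
      fit_link_anova(dataset, links$gene_a[i], links$gene_b[i]),
      error = function(e) NULL)
    if (is.null(pv)) next
    links$p_gene_x_treat[i] <- pv$p_gene_x_treat
    links$p_gene_x_day[i] <- pv$p_gene_x_day
    links$p_gene_x_day_x_treat[i] <- pv$p_gene_x_day_x_treat
  }
  links$link_class <- vapply(seq_len(nrow(links)), function(i) {
    classify_link(links[i, ], params)
  }, character(1))
  structure(list(links = links, params = params,
                 n_genes = length(genes), n_edges = nrow(links)),
            class = "del_links")
}

#' @export
print.del_links <- function(x, ...) {
  cat(sprintf("del_links: %d backbone edges over %d measured genes\n",
              x$n_edges, x$n_genes))
  if (x$n_edges) {
    cls <- factor(x$links$link_class,
                  levels = c("enabled", "sensitive", "resistant",
                             "developmental", "ambiguous", "none"))
    print(table(cls))
  }
  invisible(x)
}

#' @export
summary.del_links <- function(object, ...) {
  print(object)
  cat(sprintf("params: plc_high = %g, plc_low = %g, alpha = %g, fbs_min = %g\n",
              object$params$plc_high, object$params$plc_low,
              object$params$alpha, object$params$fbs_min))
  invisible(object)
}

# edge data.frames for one or more classes
del_edges <- function(dels, classes) {
  stopifnot(inherits(dels, "del_links"))
  l <- dels$links
  l[l$link_class %in% classes, c("gene_a", "gene_b"), drop = FALSE]
}

#' Export DEL records as TSV (and per-class SIF files)
#'
#' @param dels a `del_links` object.
#' @param path output TSV path.
#' @param sif_prefix if non-NULL, additionally writes one SIF per link
#'   class at `<prefix>_<class>.sif` for network-viewer overlays.
#' @return Invisibly, `dels`.
#' @export
write_dels <- function(dels, path, sif_prefix = NULL) {
  stopifnot(inherits(dels, "del_links"))
  write.table(dels$links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sif_prefix) && nrow(dels$links)) {
    for (cls in unique(dels$links$link_class)) {
      sel <- dels$links[dels$links$link_class == cls, ]
      writeLines(paste(sel$gene_a, cls, sel$gene_b, sep = "\t"),
                 sprintf("%s_%s.sif", sif_prefix, cls))
    }
  }
  invisible(dels)
}

#' Permutation estimate of the DEL false discovery rate
#'
#' Re-runs DEL detection on datasets whose treatment labels are permuted
#' within each (day, replicate) stratum (the stratification preserves the
#' day structure of the design), and reports the mean permuted count of
#' enabled + sensitive links over the observed count, truncated to
#' `[0, 1]`.
#'
#' @param dataset an [expr_dataset()].
#' @param network backbone igraph.
#' @param params a [del_params()] object.
#' @param n_perm number of permutations (>= 20).
#' @param seed RNG seed.
#' @return A list with `fdr` (NA when the observed count is zero),
#'   `observed` and `perm_counts`.
#' @export
estimate_del_fdr <- function(dataset, network, params = del_params(),
                             n_perm = 20, seed = 1) {
  stopifnot(n_perm >= 20)
  count_ds <- function(ds) {
    d <- suppressWarnings(detect_dels(ds, network, params))
    sum(d$links$link_class %in% c("enabled", "sensitive"))
  }
  observed <- count_ds(dataset)
  strata <- split(seq_len(nrow(dataset$samples)),
                  paste(dataset$samples$day, dataset$samples$replicate))
  perm_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      s <- dataset$samples
      for (idx in strata) {
        s$treatment[idx] <- sample(s$treatment[idx])
      }
      count_ds(expr_dataset(dataset$values, s))
    }, numeric(1))
  })
  fdr <- if (observed == 0) NA_real_ else
    min(max(mean(perm_counts) / observed, 0), 1)
  list(fdr = fdr, observed = observed, perm_counts = perm_counts)
}
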