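# Synthetic fixtures with the statistical structure the analyses assume:
# a scale-free backbone with edge confidences, replicated two-condition
# 5-day expression with planted condition-specific co-expression, planted
# DE schedules and planted temporal propagation over GO-labelled sets.

#' Generate a scale-free backbone network
#'
#' Preferential-attachment (Barabasi-Albert) graph whose degree
#' distribution has the heavy tail typical of functional-coupling
#' networks. Edge confidences (FBS) are drawn uniformly from `fbs_range`.
#'
#' @param n_nodes number of genes (> m).
#' @param m edges added per step (default 3; `m = 1` yields a tree).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param fbs_range range of the uniform FBS draw (default `c(3, 12)`).
#' @return An undirected igraph with vertex names `g0001`, ... and edge
#'   attributes `fbs`, `relation`.
#' @export
generate_backbone <- function(n_nodes, m = 3, seed, fbs_range = c(3, 12)) {
  if (n_nodes <= m || m < 1) .stopf("need n_nodes > m >= 1")
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    igraph::V(g)$name <- sprintf("g%04d", seq_len(n_nodes))
    igraph::E(g)$fbs <- runif(igraph::ecount(g), fbs_range[1], fbs_range[2])
    igraph::E(g)$relation <- "pp"
    g
  })
}

#' Configuration of the planted ground truth
#'
#' Describes the study conditions the generator emulates: 2 conditions x
#' 5 days x `n_replicates` arrays (with an optional dropped sample
#' standing in for a degraded array, giving the 39-array design), planted
#' condition-specific co-expression sets, a per-gene DE schedule and a
#' GO labelling.
#'
#' The coupling strength of planted sets is derived from `target_plc`,
#' the intended within-condition Pearson correlation between planted
#' genes: with a standardised per-(day, condition) latent trajectory
#' (population variance 0.8 over the five days) and residual noise
#' `noise_sd`, the base loading `lambda = sqrt(rho / (1 - rho) *
#' noise_sd^2 / 0.8)` gives correlation `rho` for two genes at loading
#' `lambda`; larger loadings only increase it.
#'
#' @param n_replicates replicates per (day, condition) cell (default 4).
#' @param drop_sample optional list `(day, treatment, replicate)` naming
#'   one sample to drop (default: treated day-2 replicate 4, emulating the
#'   degraded array; set NULL to keep all 40).
#' @param planted_enabled,planted_sensitive lists of gene-id vectors; the
#'   genes of each set share a treated-only (enabled) or control-only
#'   (sensitive) latent factor.
#' @param de_schedule data.frame `gene`, `first_de_day`, `effect` (log10
#'   treated shift applied from `first_de_day` onwards; default effect
#'   0.3, i.e. a 2-fold change).
#' @param go_scheme optional `go_map` or named list gene -> GO terms.
#' @param noise_sd residual noise sd on the log10 scale (default 0.05).
#' @param baseline_step day-to-day random-walk step of per-gene baselines
#'   (default 0.3, making developmental variance dominate). Planted-set
#'   genes instead get a flat baseline: their variation is
#'   condition-driven, not developmental, mirroring links whose
#'   co-expression is absent in the other condition.
#' @param target_plc intended within-condition correlation anchoring the
#'   weakest planted gene (default 0.9; pairs correlate at or above this).
#' @param loading_range range of the uniform per-gene loading multiplier
#'   (default `c(1, 10)`): response magnitudes in a co-regulated set span
#'   about an order of magnitude, which is what makes gene-by-treatment
#'   interactions detectable.
#' @param seed RNG seed (mandatory).
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_replicates = 4,
                         drop_sample = list(day = 2, treatment = "treated",
                                            replicate = 4),
                         planted_enabled = list(),
                         planted_sensitive = list(),
                         de_schedule = NULL,
                         go_scheme = NULL,
                         noise_sd = 0.05,
                         baseline_step = 0.3,
                         target_plc = 0.9,
                         loading_range = c(1, 10),
                         seed) {
  if (missing(seed)) .stopf("truth_config requires a seed")
  stopifnot(n_replicates >= 2, noise_sd >= 0, baseline_step >= 0,
            target_plc > 0, target_plc < 1)
  if (!is.null(de_schedule)) {
    stopifnot(all(c("gene", "first_de_day") %in% names(de_schedule)))
    if (is.null(de_schedule$effect)) de_schedule$effect <- 0.3
    stopifnot(all(is.finite(de_schedule$effect)),
              all(de_schedule$first_de_day %in% 1:5))
  }
  stopifnot(length(loading_range) == 2, loading_range[1] >= 1,
            diff(loading_range) >= 0)
  structure(list(n_replicates = n_replicates, drop_sample = drop_sample,
                 planted_enabled = planted_enabled,
                 planted_sensitive = planted_sensitive,
                 de_schedule = de_schedule, go_scheme = go_scheme,
                 noise_sd = noise_sd, baseline_step = baseline_step,
                 target_plc = target_plc, loading_range = loading_range,
                 seed = seed),
            class = "truth_config")
}

# Base latent-factor loading: a gene loading lambda on a unit-variance
# day trajectory against residual variance s2 has within-condition
# correlation rho = 0.8 lambda^2 / (0.8 lambda^2 + s2) with its set mates
# (0.8 = expected population variance of 5 i.i.d. day values); solving for
# rho = target_plc anchors the weakest planted gene at the target.
.planted_lambda <- function(truth) {
  rho <- truth$target_plc
  resid <- 0.8 * .planted_step(truth)^2 + truth$noise_sd^2
  sqrt(rho / (1 - rho) * resid / 0.8)
}

# planted genes carry condition-driven, not developmental, variation:
# their day baseline is flat, so the other condition shows pure noise
.planted_step <- function(truth) 0

#' Simulate an expression dataset over a backbone
#'
#' Each gene's value is the sum of a per-gene day-baseline random walk
#' (developmental trajectory), a treated-only mean shift from its DE
#' schedule, a shared latent per-(day, condition) trajectory for genes in
#' planted enabled (treated-only) or sensitive (control-only) sets with
#' per-gene loadings, and Gaussian noise. Planted sets must induce a
#' connected backbone subgraph.
#'
#' @param backbone igraph from [generate_backbone()] (or any backbone).
#' @param truth a [truth_config()].
#' @return A list: `dataset` (an [expr_dataset()]), `truth_links`
#'   (data.frame `gene_a`, `gene_b`, `class` of planted backbone edges)
#'   and `truth_de` (the DE schedule used).
#' @export
simulate_dataset <- function(backbone, truth) {
  stopifnot(inherits(truth, "truth_config"))
  genes <- igraph::V(backbone)$name
  for (set in c(truth$planted_enabled, truth$planted_sensitive)) {
    miss <- setdiff(set, genes)
    if (length(miss)) .stopf("planted gene(s) not in backbone: %s",
                             paste(miss, collapse = ", "))
    sub <- igraph::induced_subgraph(backbone, set)
    if (!igraph::is_connected(sub)) {
      .stopf("planted set is not backbone-connected")
    }
  }
  days <- 1:5
  samples <- expand.grid(replicate = seq_len(truth$n_replicates),
                         treatment = c("control", "treated"),
                         day = days, stringsAsFactors = FALSE)
  samples <- samples[, c("day", "treatment", "replicate")]
  if (!is.null(truth$drop_sample)) {
    ds <- truth$drop_sample
    hit <- samples$day == ds$day & samples$treatment == ds$treatment &
      samples$replicate == ds$replicate
    if (!any(hit)) .stopf("drop_sample does not name an existing sample")
    samples <- samples[!hit, , drop = FALSE]
  }
  samples$sample_id <- sprintf("d%d_%s_r%d", samples$day,
                               ifelse(samples$treatment == "treated",
                                      "t", "c"),
                               samples$replicate)
  rownames(samples) <- NULL
  lambda <- .planted_lambda(truth)
  eff <- setNames(numeric(length(genes)), genes)
  fday <- setNames(rep(NA_integer_, length(genes)), genes)
  if (!is.null(truth$de_schedule)) {
    sched <- truth$de_schedule
    eff[as.character(sched$gene)] <- sched$effect
    fday[as.character(sched$gene)] <- sched$first_de_day
  }
  planted_genes <- unique(unlist(c(truth$planted_enabled,
                                   truth$planted_sensitive)))
  values <- with_seed(truth$seed, {
    step <- ifelse(genes %in% planted_genes, .planted_step(truth),
                   truth$baseline_step)
    base <- t(apply(matrix(rnorm(length(genes) * 5, 0, 1) * step,
                           length(genes), 5), 1L, cumsum))
    V <- matrix(rnorm(length(genes) * nrow(samples), 0, truth$noise_sd),
                length(genes), nrow(samples),
                dimnames = list(genes, samples$sample_id))
    V <- V + base[, samples$day]
    treated <- samples$treatment == "treated"
    for (g in names(fday)[!is.na(fday)]) {
      on <- treated & samples$day >= fday[g]
      V[g, on] <- V[g, on] + eff[g]
    }
    plant <- function(V, sets, condition) {
      for (set in sets) {
        # latent day trajectory, standardised so the coupling calibration
        # is exact (population variance over the 5 days is always 0.8)
        Z <- as.numeric(scale(rnorm(5)))
        load <- lambda * runif(length(set), truth$loading_range[1],
                               truth$loading_range[2])
        on <- samples$treatment == condition
        V[set, on] <- V[set, on, drop = FALSE] +
          outer(load, Z[samples$day[on]])
      }
      V
    }
    V <- plant(V, truth$planted_enabled, "treated")
    V <- plant(V, truth$planted_sensitive, "control")
    V
  })
  truth_links <- do.call(rbind, c(
    lapply(truth$planted_enabled, .set_edges, backbone = backbone,
           class = "enabled"),
    lapply(truth$planted_sensitive, .set_edges, backbone = backbone,
           class = "sensitive")))
  if (is.null(truth_links)) {
    truth_links <- data.frame(gene_a = character(0), gene_b = character(0),
                              class = character(0))
  }
  list(dataset = expr_dataset(values, samples),
       truth_links = truth_links,
       truth_de = truth$de_schedule)
}

.set_edges <- function(set, backbone, class) {
  ed <- igraph::as_data_frame(igraph::induced_subgraph(backbone, set),
                              what = "edges")
  if (!nrow(ed)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      class = character(0)))
  }
  data.frame(gene_a = pmin(ed$from, ed$to), gene_b = pmax(ed$from, ed$to),
             class = class, stringsAsFactors = FALSE)
}

#' Plant a temporal propagation structure
#'
#' Assigns first-DE days to genes so that each requested flow
#' (`GO_source` on day `a` to `GO_target` on day `a + 1`) is supported by
#' at least `n_links` backbone edges between the two categories with the
#' required day labels. Fails, naming the flow, when the backbone does
#' not carry enough consistent cross-category edges.
#'
#' @param backbone igraph.
#' @param go_scheme a `go_map` or named list gene -> GO terms.
#' @param flows data.frame with columns `go_source`, `day_a`, `go_target`,
#'   `n_links` (day_b is `day_a + 1`).
#' @param seed RNG seed (used to shuffle candidate edges).
#' @param effect log10 treated shift for scheduled genes (default 0.3).
#' @return A `de_schedule` data.frame (`gene`, `first_de_day`, `effect`)
#'   usable in [truth_config()].
#' @export
plant_propagation <- function(backbone, go_scheme, flows, seed,
                              effect = 0.3) {
  if (inherits(go_scheme, "go_map")) go_scheme <- go_scheme$gene2go
  if (is.null(flows) || !nrow(flows)) {
    return(data.frame(gene = character(0), first_de_day = integer(0),
                      effect = numeric(0)))
  }
  stopifnot(all(c("go_source", "day_a", "go_target", "n_links") %in%
                  names(flows)))
  if (any(flows$day_a >= 5)) .stopf("day_a must be <= 4 (day_b = day_a + 1)")
  ed <- igraph::as_data_frame(backbone, what = "edges")
  assigned <- integer(0)   # named: gene -> day
  with_seed(seed, {
    for (fi in seq_len(nrow(flows))) {
      src <- flows$go_source[fi]; tgt <- flows$go_target[fi]
      da <- flows$day_a[fi]; db <- da + 1L
      in_cat <- function(g, cat) {
        vapply(g, function(x) cat %in% (go_scheme[[x]] %||% character(0)),
               logical(1))
      }
      cand <- rbind(
        ed[in_cat(ed$from, src) & in_cat(ed$to, tgt), c("from", "to")],
        setNames(ed[in_cat(ed$to, src) & in_cat(ed$from, tgt),
                    c("to", "from")], c("from", "to")))
      cand <- cand[sample(nrow(cand)), , drop = FALSE]
      got <- 0L
      for (i in seq_len(nrow(cand))) {
        a <- cand$from[i]; b <- cand$to[i]
        ok_a <- !(a %in% names(assigned)) || assigned[[a]] == da
        ok_b <- !(b %in% names(assigned)) || assigned[[b]] == db
        if (!ok_a || !ok_b || a == b) next
        assigned[a] <- da
        assigned[b] <- db
        got <- got + 1L
        if (got >= flows$n_links[fi]) break
      }
      if (got < flows$n_links[fi]) {
        .stopf("infeasible flow %s (day %d) -> %s (day %d): %d of %d links",
               src, da, tgt, db, got, flows$n_links[fi])
      }
    }
  })
  data.frame(gene = names(assigned),
             first_de_day = as.integer(assigned),
             effect = effect, stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
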