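# Day-1 seed linkage statistics and degree comparison between altered and
# non-altered genes.

#' Linkage from day-1 seed genes to later-regulated genes
#'
#' Measures how much of the late response is in direct network contact
#' with the genes altered first: the fraction of genes first
#' differentially expressed on days 2-5 that are adjacent to at least one
#' day-1 seed gene, against a null in which the seed set is replaced by
#' random measured genes of equal size (uniform, or matched to the seeds'
#' degree distribution via log2 degree bins).
#'
#' @param network backbone igraph restricted to measured genes.
#' @param de_calls a `de_calls` data.frame from [call_de()].
#' @param n_draws null draws (>= 100; default 1000).
#' @param seed RNG seed.
#' @param degree_matched draw null seed sets within degree bins
#'   (default FALSE: uniform).
#' @param fbs_min count edges at this confidence floor (default 3).
#' @return A list of class `linkage_stats`: `n_seed`, `n_later`,
#'   `n_seed_edges`, `contacted_fraction`, `expected_fraction`,
#'   `empirical_p`, `per_seed` (data.frame: seed gene, number of
#'   later-day partners).
#' @export
linkage_stats <- function(network, de_calls, n_draws = 1000, seed = 1,
                          degree_matched = FALSE, fbs_min = 3) {
  stopifnot(n_draws >= 100)
  net <- .filter_fbs(network, fbs_min, strict = FALSE)
  genes <- igraph::V(net)$name
  first <- setNames(de_calls$first_de_day, de_calls$gene)
  seeds <- intersect(genes, de_calls$gene[!is.na(de_calls$first_de_day) &
                                            de_calls$first_de_day == 1])
  later <- intersect(genes, de_calls$gene[!is.na(de_calls$first_de_day) &
                                            de_calls$first_de_day >= 2])
  empty <- structure(list(
    n_seed = length(seeds), n_later = length(later), n_seed_edges = 0L,
    contacted_fraction = 0, expected_fraction = 0, empirical_p = 1,
    per_seed = data.frame(seed = character(0), n_later_partners = integer(0))),
    class = "linkage_stats")
  if (!length(seeds) || !length(later)) return(empty)
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), names)
  names(adj) <- genes
  frac_contacted <- function(seed_set) {
    contacted <- unique(unlist(adj[seed_set], use.names = FALSE))
    mean(later %in% contacted)
  }
  obs <- frac_contacted(seeds)
  deg <- igraph::degree(net)
  n_seed_edges <- sum(deg[seeds]) -
    igraph::ecount(igraph::induced_subgraph(net, seeds))
  draw_pool <- genes
  if (degree_matched) {
    bin <- floor(log2(pmax(deg, 1)))
    pool_by_bin <- split(genes, bin[genes])
    seed_bins <- table(bin[seeds])
  }
  null_frac <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      s <- if (degree_matched) {
        unlist(lapply(names(seed_bins), function(b) {
          pool <- pool_by_bin[[b]]
          sample(pool, min(seed_bins[[b]], length(pool)))
        }), use.names = FALSE)
      } else {
        sample(draw_pool, length(seeds))
      }
      frac_contacted(s)
    }, numeric(1))
  })
  per_seed <- data.frame(
    seed = seeds,
    n_later_partners = vapply(seeds, function(s) {
      sum(later %in% adj[[s]])
    }, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  per_seed <- per_seed[order(-per_seed$n_later_partners, per_seed$seed), ]
  structure(list(
    n_seed = length(seeds), n_later = length(later),
    n_seed_edges = as.integer(n_seed_edges),
    contacted_fraction = obs,
    expected_fraction = mean(null_frac),
    empirical_p = (1 + sum(null_frac >= obs)) / (1 + n_draws),
    per_seed = per_seed), class = "linkage_stats")
}

#' @export
print.linkage_stats <- function(x, ...) {
  cat(sprintf(
    paste0("linkage_stats: %d seed genes (%d incident edges) contact ",
           "%.1f%% of %d later-regulated genes (%.1f%% expected by chance; ",
           "empirical p = %.3g)\n"),
    x$n_seed, x$n_seed_edges, 100 * x$contacted_fraction, x$n_later,
    100 * x$expected_fraction, x$empirical_p))
  invisible(x)
}

#' Write linkage statistics as TSV
#'
#' Emits a single-row summary table and a per-seed table (seed gene and
#' its number of later-day partners).
#'
#' @param stats a `linkage_stats` object.
#' @param path summary TSV path.
#' @param per_seed_path optional path for the per-seed table.
#' @return Invisibly, `stats`.
#' @export
write_linkage_stats <- function(stats, path, per_seed_path = NULL) {
  stopifnot(inherits(stats, "linkage_stats"))
  write.table(
    data.frame(n_seed = stats$n_seed, n_later = stats$n_later,
               n_seed_edges = stats$n_seed_edges,
               contacted_fraction = stats$contacted_fraction,
               expected_fraction = stats$expected_fraction,
               empirical_p = stats$empirical_p),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(per_seed_path)) {
    write.table(stats$per_seed, per_seed_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(stats)
}

#' Compare node degree between altered and non-altered genes
#'
#' Group means of backbone degree with a one-way ANOVA p-value (equivalent
#' to a pooled-variance two-sample t-test).
#'
#' @param network backbone igraph.
#' @param altered_genes character vector of altered gene ids.
#' @return A list: `mean_altered`, `mean_other`, `p`.
#' @export
degree_comparison <- function(network, altered_genes) {
  deg <- igraph::degree(network)
  grp <- names(deg) %in% altered_genes
  if (!any(grp) || all(grp)) .stopf("both gene groups must be non-empty")
  p <- anova(lm(deg ~ grp))[["Pr(>F)"]][1]
  list(mean_altered = mean(deg[grp]), mean_other = mean(deg[!grp]), p = p)
}
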