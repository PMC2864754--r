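# Greedy discovery of network modules enriched in differentially
# expressed links, and hypergeometric GO enrichment of the results.

#' Hypergeometric DEL enrichment of a node set
#'
#' Upper-tail hypergeometric probability of drawing at least `k` DEL edges
#' among the `m` edges induced by the module, from a universe of `M`
#' backbone edges of which `K` are DELs. A module inducing no edges gets
#' p = 1.
#'
#' @param module_nodes character vector of gene ids.
#' @param network backbone igraph (the edge universe).
#' @param del_edges data.frame with columns `gene_a`, `gene_b` (must be
#'   backbone edges).
#' @return A p-value.
#' @export
del_enrichment_p <- function(module_nodes, network, del_edges) {
  M <- igraph::ecount(network)
  K <- nrow(del_edges)
  sub <- igraph::induced_subgraph(network,
                                  intersect(module_nodes,
                                            igraph::V(network)$name))
  ed <- igraph::as_data_frame(sub, what = "edges")
  m <- nrow(ed)
  if (m == 0) return(1)
  k <- sum(.ekey(ed$from, ed$to) %in% .ekey(del_edges$gene_a,
                                            del_edges$gene_b))
  phyper(k - 1, K, M - K, m, lower.tail = FALSE)
}

# adjacency bookkeeping shared by grow_module / find_modules
.grow_env <- function(network, del_edges) {
  ed <- igraph::as_data_frame(network, what = "edges")
  adj <- lapply(igraph::as_adj_list(network, mode = "all"),
                function(v) v$name)
  list(adj = adj, M = nrow(ed), K = nrow(del_edges),
       del_keys = .ekey(del_edges$gene_a, del_edges$gene_b))
}

#' Grow one DEL-enriched module from a seed edge
#'
#' Greedy seed-and-extend: starting from the seed edge's two endpoints,
#' repeatedly add the neighbouring node that most decreases the
#' hypergeometric enrichment p-value of the induced edge set; stop when no
#' addition improves the p-value or `max_size` is reached. Ties are broken
#' by the lexicographically smallest gene id, so growth is deterministic.
#' Connectivity holds by construction.
#'
#' @param seed_edge length-2 character vector (must be a DEL).
#' @param network backbone igraph.
#' @param del_edges data.frame `gene_a`/`gene_b` of the DELs defining the
#'   polarity universe.
#' @param polarity `"P"`, `"N"` or `"PN"` (annotation only).
#' @param max_size maximum module size in nodes (default 130).
#' @return A list: `nodes`, `core_nodes` (genes incident to an internal
#'   DEL), `n_edges`, `n_del_edges`, `p`, `polarity`.
#' @export
grow_module <- function(seed_edge, network, del_edges, polarity = "PN",
                        max_size = 130) {
  env <- .grow_env(network, del_edges)
  .grow_module_impl(seed_edge, env, polarity, max_size)
}

.grow_module_impl <- function(seed_edge, env, polarity, max_size) {
  nodes <- sort(unique(seed_edge))
  in_mod <- structure(rep(TRUE, length(nodes)), names = nodes)
  m <- 1L
  k <- as.integer(.ekey(seed_edge[1], seed_edge[2]) %in% env$del_keys)
  pcur <- phyper(k - 1, env$K, env$M - env$K, m, lower.tail = FALSE)
  repeat {
    if (length(nodes) >= max_size) break
    cand <- setdiff(sort(unique(unlist(env$adj[nodes], use.names = FALSE))),
                    nodes)
    if (!length(cand)) break
    add_m <- integer(length(cand))
    add_k <- integer(length(cand))
    for (ci in seq_along(cand)) {
      nb <- intersect(env$adj[[cand[ci]]], nodes)
      add_m[ci] <- length(nb)
      if (length(nb)) {
        add_k[ci] <- sum(.ekey(cand[ci], nb) %in% env$del_keys)
      }
    }
    pnew <- phyper(k + add_k - 1, env$K, env$M - env$K, m + add_m,
                   lower.tail = FALSE)
    best <- which(pnew == min(pnew))[1]   # cand is sorted: lexicographic tie-break
    if (pnew[best] >= pcur) break
    nodes <- sort(c(nodes, cand[best]))
    m <- m + add_m[best]
    k <- k + add_k[best]
    pcur <- pnew[best]
  }
  # core nodes: incident to an internal DEL
  core <- character(0)
  for (nd in nodes) {
    nb <- intersect(env$adj[[nd]], nodes)
    if (length(nb) && any(.ekey(nd, nb) %in% env$del_keys)) {
      core <- c(core, nd)
    }
  }
  list(nodes = nodes, core_nodes = core, n_edges = m, n_del_edges = k,
       p = pcur, polarity = polarity)
}

#' Discover DEL-enriched modules
#'
#' One greedy growth pass per DEL seed edge per polarity: `P` modules grow
#' from condition-enabled seeds against the enabled-DEL universe, `N` from
#' sensitive seeds, `PN` from either seed kind against the combined
#' universe (a PN module must contain at least one internal enabled and
#' one internal sensitive DEL). Modules of the same polarity are merged
#' when their node Jaccard exceeds `jaccard_max` (the better p wins);
#' modules are retained when their Benjamini-Hochberg adjusted enrichment
#' is below `q_max`, and named `P-k` / `N-k` / `PN-k` in discovery order.
#'
#' @param network backbone igraph (restricted and FBS-filtered as used for
#'   DEL detection).
#' @param del_records a `del_links` object from [detect_dels()], or a
#'   data.frame with `gene_a`, `gene_b`, `link_class`.
#' @param max_size,jaccard_max,q_max tuning parameters (defaults 130,
#'   0.5, 0.05).
#' @return An object of class `del_modules`: list of module lists plus a
#'   `summary` data.frame (`id`, `polarity`, `size`, `n_edges`,
#'   `n_del_edges`, `p`, `q`).
#' @export
find_modules <- function(network, del_records, max_size = 130,
                         jaccard_max = 0.5, q_max = 0.05) {
  links <- if (inherits(del_records, "del_links")) del_records$links
           else del_records
  enab <- links[links$link_class == "enabled", c("gene_a", "gene_b")]
  sens <- links[links$link_class == "sensitive", c("gene_a", "gene_b")]
  both <- rbind(enab, sens)
  if (!nrow(both)) {
    return(structure(list(modules = list(),
                          summary = data.frame(id = character(0))),
                     class = "del_modules"))
  }
  grow_all <- function(seeds, universe, polarity) {
    if (!nrow(seeds)) return(list())
    env <- .grow_env(network, universe)
    lapply(seq_len(nrow(seeds)), function(i) {
      .grow_module_impl(c(seeds$gene_a[i], seeds$gene_b[i]),
                        env, polarity, max_size)
    })
  }
  mods <- c(grow_all(enab, enab, "P"),
            grow_all(sens, sens, "N"),
            grow_all(both, both, "PN"))
  # PN polarity must mix both link kinds
  ek <- .ekey(enab$gene_a, enab$gene_b)
  sk <- .ekey(sens$gene_a, sens$gene_b)
  keep <- vapply(mods, function(mo) {
    if (mo$polarity != "PN") return(TRUE)
    keys <- unlist(lapply(mo$nodes, function(nd) {
      .ekey(nd, mo$nodes[mo$nodes > nd])
    }))
    any(keys %in% ek) && any(keys %in% sk)
  }, logical(1))
  mods <- mods[keep]
  # merge overlapping modules of the same polarity, best p first
  merged <- list()
  for (pol in c("P", "N", "PN")) {
    pm <- mods[vapply(mods, `[[`, "", "polarity") == pol]
    pm <- pm[order(vapply(pm, `[[`, 0, "p"))]
    acc <- list()
    for (mo in pm) {
      dup <- any(vapply(acc, function(a) {
        length(intersect(a$nodes, mo$nodes)) /
          length(union(a$nodes, mo$nodes)) > jaccard_max
      }, logical(1)))
      if (!dup) acc <- c(acc, list(mo))
    }
    merged <- c(merged, acc)
  }
  p <- vapply(merged, `[[`, 0, "p")
  q <- p.adjust(p, method = "BH")
  sel <- q < q_max
  merged <- merged[sel]
  q <- q[sel]
  counts <- c(P = 0L, N = 0L, PN = 0L)
  for (i in seq_along(merged)) {
    pol <- merged[[i]]$polarity
    counts[pol] <- counts[pol] + 1L
    merged[[i]]$id <- sprintf("%s-%d", pol, counts[pol])
    merged[[i]]$q <- q[i]
  }
  summ <- if (length(merged)) {
    data.frame(
      id = vapply(merged, `[[`, "", "id"),
      polarity = vapply(merged, `[[`, "", "polarity"),
      size = vapply(merged, function(m) length(m$nodes), 0L),
      n_edges = vapply(merged, `[[`, 0L, "n_edges"),
      n_del_edges = vapply(merged, `[[`, 0L, "n_del_edges"),
      p = vapply(merged, `[[`, 0, "p"),
      q = vapply(merged, `[[`, 0, "q"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0))
  }
  structure(list(modules = merged, summary = summ), class = "del_modules")
}

#' @export
print.del_modules <- function(x, ...) {
  cat(sprintf("del_modules: %d modules", length(x$modules)))
  if (length(x$modules)) {
    tab <- table(x$summary$polarity)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Export modules as TSV (and per-module SIF + node attributes)
#'
#' The node-attribute table marks core nodes (genes incident to an
#' internal DEL) so viewers can distinguish them from plain members.
#'
#' @param modules a `del_modules` object.
#' @param path summary TSV path (gains a `nodes` column).
#' @param network backbone igraph; needed for per-module SIF export.
#' @param sif_prefix if non-NULL, write `<prefix>_<id>.sif` and
#'   `<prefix>_<id>_nodes.tsv` per module.
#' @return Invisibly, `modules`.
#' @export
write_modules <- function(modules, path, network = NULL, sif_prefix = NULL) {
  stopifnot(inherits(modules, "del_modules"))
  summ <- modules$summary
  if (nrow(summ)) {
    summ$nodes <- vapply(modules$modules, function(m) {
      paste(m$nodes, collapse = ",")
    }, "")
  }
  write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sif_prefix) && !is.null(network)) {
    for (m in modules$modules) {
      sub <- igraph::induced_subgraph(network, m$nodes)
      write_sif(sub, sprintf("%s_%s.sif", sif_prefix, m$id))
      write.table(
        data.frame(gene = m$nodes, core = m$nodes %in% m$core_nodes),
        sprintf("%s_%s_nodes.tsv", sif_prefix, m$id),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(modules)
}

#' GO enrichment of a module
#'
#' Per GO term, upper-tail hypergeometric p-value for the overlap between
#' the module and the term's members within the universe of annotated
#' measured genes, with Benjamini-Hochberg correction across terms.
#'
#' @param module character vector of gene ids, or a module list from
#'   [find_modules()].
#' @param go_annotation a `go_map` object.
#' @param universe character vector of annotated measured genes.
#' @param q_max report terms with adjusted p below this (default 0.05);
#'   use 1 to report everything.
#' @return A data.frame: `term`, `name`, `overlap`, `term_size`,
#'   `module_size`, `p`, `q`, ordered by p.
#' @export
go_enrich_module <- function(module, go_annotation, universe, q_max = 0.05) {
  if (is.list(module) && !is.null(module$nodes)) module <- module$nodes
  members <- go_members(go_annotation, universe)
  if (!length(members)) {
    return(data.frame(term = character(0), name = character(0),
                      overlap = integer(0), term_size = integer(0),
                      module_size = integer(0), p = numeric(0),
                      q = numeric(0)))
  }
  mod <- intersect(module, universe)
  N <- length(universe)
  n <- length(mod)
  res <- data.frame(
    term = names(members),
    overlap = vapply(members, function(g) length(intersect(g, mod)), 0L),
    term_size = lengths(members),
    module_size = n,
    stringsAsFactors = FALSE, row.names = NULL)
  res$p <- phyper(res$overlap - 1, res$term_size, N - res$term_size, n,
                  lower.tail = FALSE)
  res$q <- p.adjust(res$p, method = "BH")
  nm <- go_annotation$term_names
  res$name <- if (!is.null(nm)) unname(nm[res$term]) else NA_character_
  res <- res[res$q < q_max, c("term", "name", "overlap", "term_size",
                              "module_size", "p", "q")]
  res[order(res$p), , drop = FALSE]
}
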