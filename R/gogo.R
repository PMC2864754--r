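# Temporal GO-GO "meta-flow" network: label eligible gene-gene links by
# day pattern, tally observed category-pair counts, compare with
# marginal-product expected counts, score with a one-cell chi-square and
# threshold.

#' The nine admissible day patterns
#'
#' Over a 5-day design there are exactly nine patterns of first-DE days
#' for a link: five same-day patterns (both genes first DE on day d) and
#' four consecutive patterns (one gene on day d, the other on day d+1,
#' oriented earlier to later). Links whose endpoints are first DE two or
#' more days apart carry no pattern.
#'
#' @return A data.frame with columns `a`, `b`, `kind`, `label`.
#' @export
day_patterns <- function() {
  same <- data.frame(a = 1:5, b = 1:5, kind = "same_day",
                     label = sprintf("d%d--d%d", 1:5, 1:5))
  consec <- data.frame(a = 1:4, b = 2:5, kind = "consecutive",
                       label = sprintf("d%d->d%d", 1:4, 2:5))
  out <- rbind(same, consec)
  out[order(out$a, out$b), , drop = FALSE]
}

#' Assign the day pattern of a link
#'
#' @param day_a,day_b first-DE days of the two endpoint genes (in 1..5).
#' @return A list `(kind, a, b, label)`, or `NULL` when the pair is not
#'   among the nine admissible patterns (days >= 2 apart).
#' @export
assign_pattern <- function(day_a, day_b) {
  if (!day_a %in% 1:5 || !day_b %in% 1:5) .stopf("days must be in 1..5")
  if (day_a == day_b) {
    return(list(kind = "same_day", a = day_a, b = day_b,
                label = sprintf("d%d--d%d", day_a, day_b)))
  }
  if (abs(day_a - day_b) == 1) {
    a <- min(day_a, day_b); b <- max(day_a, day_b)
    return(list(kind = "consecutive", a = a, b = b,
                label = sprintf("d%d->d%d", a, b)))
  }
  NULL
}

#' Eligible gene-gene links for the GO-GO network
#'
#' Backbone edges whose endpoints are both dioxin-regulated (DE on at
#' least one day), both GO-annotated, and whose confidence exceeds
#' `fbs_min` (strict, matching the backbone's confidence convention).
#' Each endpoint is labelled with its first-DE day.
#'
#' @param network backbone igraph.
#' @param de_calls a `de_calls` data.frame from [call_de()].
#' @param go_annotation a `go_map`.
#' @param fbs_min confidence floor (default 3, strict).
#' @return A data.frame: `gene_a`, `gene_b`, `day_a`, `day_b`.
#' @export
eligible_links <- function(network, de_calls, go_annotation, fbs_min = 3) {
  net <- .filter_fbs(network, fbs_min, strict = TRUE)
  ed <- igraph::as_data_frame(net, what = "edges")
  if (!nrow(ed)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      day_a = integer(0), day_b = integer(0)))
  }
  first <- setNames(de_calls$first_de_day, de_calls$gene)
  annotated <- names(go_annotation$gene2go)
  ok_gene <- function(g) {
    g %in% names(first) & !is.na(first[g]) & g %in% annotated
  }
  keep <- ok_gene(ed$from) & ok_gene(ed$to)
  ed <- ed[keep, , drop = FALSE]
  data.frame(gene_a = ed$from, gene_b = ed$to,
             day_a = as.integer(first[ed$from]),
             day_b = as.integer(first[ed$to]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally observed GO-pair link counts for one day pattern
#'
#' For a consecutive pattern a->b, `O[i, j]` counts links with one
#' endpoint first DE on day `a` belonging to category `i` and the other
#' first DE on day `b` belonging to category `j`; a gene in several
#' categories contributes to each. Same-day patterns are tallied with both
#' orientations (ordered double count); [build_metaflow()] halves them
#' back when folding to unordered pairs.
#'
#' @param links data.frame from [eligible_links()].
#' @param go_annotation a `go_map`.
#' @param pattern a pattern list from [assign_pattern()] or a row of
#'   [day_patterns()].
#' @return A list: `O` (matrix, source categories x target categories),
#'   `N_i` (row marginals), `N_j` (column marginals), `T` (grand total).
#' @export
tally <- function(links, go_annotation, pattern) {
  a <- pattern$a; b <- pattern$b
  g2g <- go_annotation$gene2go
  pairs_src <- character(0)
  pairs_tgt <- character(0)
  add <- function(src_gene, tgt_gene) {
    ci <- g2g[[src_gene]]; cj <- g2g[[tgt_gene]]
    if (is.null(ci) || is.null(cj)) return()
    grid <- expand.grid(ci, cj, stringsAsFactors = FALSE)
    pairs_src <<- c(pairs_src, grid[[1]])
    pairs_tgt <<- c(pairs_tgt, grid[[2]])
  }
  for (i in seq_len(nrow(links))) {
    da <- links$day_a[i]; db <- links$day_b[i]
    if (a == b) {
      if (da == a && db == a) {          # ordered double count
        add(links$gene_a[i], links$gene_b[i])
        add(links$gene_b[i], links$gene_a[i])
      }
    } else {
      if (da == a && db == b) add(links$gene_a[i], links$gene_b[i])
      else if (db == a && da == b) add(links$gene_b[i], links$gene_a[i])
    }
  }
  cats <- sort(unique(c(pairs_src, pairs_tgt)))
  O <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  if (length(pairs_src)) {
    tab <- table(factor(pairs_src, cats), factor(pairs_tgt, cats))
    O[] <- as.numeric(tab)
  }
  list(O = O, N_i = rowSums(O), N_j = colSums(O), T = sum(O))
}

#' Expected GO-pair link count
#'
#' Marginal-product expectation `E_ij = N_i(a) * N_j(b) / T`, where
#' `N_i(a)` and `N_j(b)` count occurrences of any pattern links involving
#' the two categories on days `a` and `b`, and `T` is the pattern total.
#' This normalisation makes expected counts reproduce observed counts in
#' aggregate (`sum(E) == sum(O)`). For same-day patterns the unordered
#' correction `E_ij = N_i N_j / (2T)` arises from the ordered
#' double-count-then-halve convention used in [build_metaflow()].
#'
#' @param N_i_a,N_j_b marginal counts.
#' @param T total pattern links (> 0).
#' @return The expected count.
#' @export
expected_count <- function(N_i_a, N_j_b, T) {
  if (T <= 0) .stopf("pattern total T must be > 0")
  N_i_a * N_j_b / T
}

#' One-cell chi-square enrichment score
#'
#' `(O - E)^2 / E`, interpreted against the 1-df chi-square distribution
#' (the 0.99 quantile, 6.64, is the default retention threshold).
#'
#' @param O observed count(s).
#' @param E expected count(s), > 0.
#' @return The score(s).
#' @export
chi_square_score <- function(O, E) {
  if (any(E <= 0)) .stopf("expected count must be > 0")
  (O - E)^2 / E
}

#' Parameters for the GO-GO meta-flow network
#'
#' @param chi_min chi-square retention threshold (default 6.64, the
#'   1-df 0.99 quantile, i.e. p < 0.01).
#' @param o_min minimum observed gene-gene links (default 3).
#' @param e_min minimum expected count (default 0.5, strict).
#' @param fbs_min backbone confidence floor for eligible links (default 3).
#' @return A list of class `gogo_params`.
#' @export
gogo_params <- function(chi_min = 6.64, o_min = 3, e_min = 0.5,
                        fbs_min = 3) {
  structure(list(chi_min = chi_min, o_min = o_min, e_min = e_min,
                 fbs_min = fbs_min), class = "gogo_params")
}

#' Build the temporal GO-GO meta-flow network
#'
#' Tallies eligible links per day pattern, computes marginal-product
#' expected counts and chi-square scores, and retains GO-GO edges with
#' `chi2 > chi_min`, `O >= o_min` and `E > e_min`. Consecutive patterns
#' are directed (earlier day is the source); same-day patterns are
#' unordered. Nodes are the GO terms incident to retained edges, annotated
#' with the fraction of their member genes regulated on any day.
#'
#' @param network backbone igraph.
#' @param de_calls a `de_calls` data.frame from [call_de()].
#' @param go_annotation a `go_map`.
#' @param params a [gogo_params()] object.
#' @return An object of class `gogo_network`: list with `edges`
#'   (data.frame `go_i`, `go_j`, `pattern`, `kind`, `day_a`, `day_b`,
#'   `observed`, `expected`, `chi2`), `nodes` (data.frame `go_id`,
#'   `n_genes`, `regulated_fraction`), `pattern_totals` and `params`.
#' @export
build_metaflow <- function(network, de_calls, go_annotation,
                           params = gogo_params()) {
  links <- eligible_links(network, de_calls, go_annotation,
                          fbs_min = params$fbs_min)
  pats <- day_patterns()
  edges <- list()
  totals <- numeric(0)
  for (r in seq_len(nrow(pats))) {
    pat <- as.list(pats[r, ])
    tl <- tally(links, go_annotation, pat)
    totals[pat$label] <- if (pat$kind == "same_day") tl$T / 2 else tl$T
    if (tl$T == 0) next
    E <- outer(tl$N_i, tl$N_j) / tl$T
    O <- tl$O
    if (pat$kind == "same_day") {
      # fold the ordered double count to unordered pairs: off-diagonal
      # cells already count each unordered link once (symmetric table);
      # diagonal cells count it twice and are halved
      diag(O) <- diag(O) / 2
      diag(E) <- diag(E) / 2
      sel_idx <- which(upper.tri(O, diag = TRUE), arr.ind = TRUE)
    } else {
      sel_idx <- which(O > -1, arr.ind = TRUE)
    }
    o <- O[sel_idx]; e <- E[sel_idx]
    keep <- e > params$e_min & o >= params$o_min
    chi <- ifelse(e > 0, (o - e)^2 / e, 0)
    keep <- keep & chi > params$chi_min
    if (!any(keep)) next
    edges[[pat$label]] <- data.frame(
      go_i = rownames(O)[sel_idx[keep, 1]],
      go_j = colnames(O)[sel_idx[keep, 2]],
      pattern = pat$label, kind = pat$kind,
      day_a = pat$a, day_b = pat$b,
      observed = o[keep], expected = e[keep], chi2 = chi[keep],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  edges <- if (length(edges)) do.call(rbind, c(edges, make.row.names = FALSE))
           else data.frame(go_i = character(0), go_j = character(0),
                           pattern = character(0), kind = character(0),
                           day_a = integer(0), day_b = integer(0),
                           observed = numeric(0), expected = numeric(0),
                           chi2 = numeric(0))
  terms <- sort(unique(c(edges$go_i, edges$go_j)))
  regulated <- de_calls$gene[!is.na(de_calls$first_de_day)]
  members <- go_members(go_annotation, de_calls$gene)
  nodes <- data.frame(
    go_id = terms,
    n_genes = vapply(terms, function(t) length(members[[t]]), 0L),
    regulated_fraction = vapply(terms, function(t) {
      g <- members[[t]]
      if (!length(g)) return(NA_real_)
      mean(g %in% regulated)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(edges = edges, nodes = nodes, pattern_totals = totals,
                 n_eligible_links = nrow(links), params = params),
            class = "gogo_network")
}

#' @export
print.gogo_network <- function(x, ...) {
  cat(sprintf(
    "gogo_network: %d retained GO-GO edges over %d GO terms (%d eligible gene links)\n",
    nrow(x$edges), nrow(x$nodes), x$n_eligible_links))
  if (nrow(x$edges)) print(table(pattern = x$edges$pattern))
  invisible(x)
}

#' Export a GO-GO network for Cytoscape-style viewers
#'
#' Writes a SIF (`GO_i <pattern> GO_j`), an edge attribute TSV (pattern,
#' observed, expected, chi-square) and a node attribute TSV (gene count,
#' regulated fraction).
#'
#' @param gogo a `gogo_network`.
#' @param prefix output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @return Invisibly, `gogo`.
#' @export
write_gogo <- function(gogo, prefix) {
  stopifnot(inherits(gogo, "gogo_network"))
  ed <- gogo$edges
  writeLines(paste(ed$go_i, ed$pattern, ed$go_j, sep = "\t"),
             paste0(prefix, ".sif"))
  write.table(ed, paste0(prefix, "_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gogo$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(gogo)
}
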