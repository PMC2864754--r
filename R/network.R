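#' Read a backbone network from a SIF file
#'
#' SIF lines are `nodeA<TAB>relation<TAB>nodeB`. The result is an
#' undirected [igraph::igraph] with a numeric `fbs` edge attribute holding
#' the per-edge functional-coupling confidence (Final Bayesian Score).
#' Duplicate A-B / B-A lines are collapsed keeping the maximum FBS;
#' self-loops are dropped with a warning. If no attribute table is given
#' every edge gets FBS 1.
#'
#' @param path path to the SIF file.
#' @param edge_attr_path optional path to a tab-separated edge attribute
#'   table with columns `edge` (key `"A (relation) B"`) and `fbs`.
#' @return An undirected igraph with edge attribute `fbs` and edge
#'   attribute `relation`.
#' @export
read_sif <- function(path, edge_attr_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    .stopf("SIF line %d has %d fields (expected 3)",
           which(nf != 3L)[1], nf[nf != 3L][1])
  }
  a <- vapply(parts, `[[`, "", 1L)
  rel <- vapply(parts, `[[`, "", 2L)
  b <- vapply(parts, `[[`, "", 3L)
  fbs <- rep(1, length(a))
  if (!is.null(edge_attr_path)) {
    attr_tab <- read.delim(edge_attr_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (!all(c("edge", "fbs") %in% names(attr_tab))) {
      .stopf("edge attribute table needs columns 'edge' and 'fbs'")
    }
    m <- regmatches(attr_tab$edge,
                    regexec("^(\\S+) \\((\\S+)\\) (\\S+)$", attr_tab$edge))
    if (any(lengths(m) != 4L)) .stopf("malformed edge key in attribute table")
    ka <- vapply(m, `[[`, "", 2L)
    kb <- vapply(m, `[[`, "", 4L)
    lut <- setNames(as.numeric(attr_tab$fbs), .ekey(ka, kb))
    hit <- lut[.ekey(a, b)]
    fbs[!is.na(hit)] <- hit[!is.na(hit)]
  }
  if (any(fbs < 0, na.rm = TRUE)) .stopf("negative FBS in edge attributes")
  loop <- a == b
  if (any(loop)) {
    .warnf("dropping %d self-loop(s)", sum(loop))
    a <- a[!loop]; b <- b[!loop]; rel <- rel[!loop]; fbs <- fbs[!loop]
  }
  key <- .ekey(a, b)
  ord <- order(key, -fbs)
  keep <- ord[!duplicated(key[ord])]
  ed <- data.frame(from = pmin(a, b)[keep], to = pmax(a, b)[keep],
                   relation = rel[keep], fbs = fbs[keep],
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE)
}

#' Write a backbone network as SIF (plus optional edge attributes)
#'
#' Edges are written in canonical order (lexicographically smaller endpoint
#' first, rows sorted) so that `read_sif(write_sif(g))` reproduces the node
#' set, edge set and FBS values exactly.
#'
#' @param network undirected igraph; edge attributes `relation` and `fbs`
#'   are used when present (defaults `"pp"` and 1).
#' @param path output SIF path.
#' @param edge_attr_path optional path for the `edge`/`fbs` attribute TSV.
#' @return Invisibly, the network.
#' @export
write_sif <- function(network, path, edge_attr_path = NULL) {
  ed <- igraph::as_data_frame(network, what = "edges")
  if (!nrow(ed)) {
    writeLines(character(0), path)
    if (!is.null(edge_attr_path)) {
      write.table(data.frame(edge = character(0), fbs = numeric(0)),
                  edge_attr_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    return(invisible(network))
  }
  rel <- if ("relation" %in% names(ed)) ed$relation else rep("pp", nrow(ed))
  fbs <- if ("fbs" %in% names(ed)) ed$fbs else rep(1, nrow(ed))
  a <- pmin(ed$from, ed$to)
  b <- pmax(ed$from, ed$to)
  ord <- order(a, b)
  writeLines(paste(a[ord], rel[ord], b[ord], sep = "\t"), path)
  if (!is.null(edge_attr_path)) {
    write.table(
      data.frame(edge = sprintf("%s (%s) %s", a[ord], rel[ord], b[ord]),
                 fbs = fbs[ord]),
      edge_attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(network)
}

#' Restrict a network to genes measured in a dataset
#'
#' Keeps the subgraph induced on genes that are present in the expression
#' dataset with at least one non-missing value. Idempotent, and monotone in
#' the measured gene set.
#'
#' @param network undirected igraph.
#' @param dataset an [expr_dataset()].
#' @return The induced igraph subgraph.
#' @export
restrict_to_measured <- function(network, dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  measured <- rownames(dataset$values)[
    rowSums(!is.na(dataset$values)) > 0]
  keep <- intersect(igraph::V(network)$name, measured)
  igraph::induced_subgraph(network, keep)
}

#' Merge curated extra edges into a backbone network
#'
#' Adds a (typically small) set of manually curated interactions, e.g.
#' literature-derived receptor-pathway edges, to a predicted backbone.
#' Merged edges receive a fixed confidence; where an edge already exists
#' the larger FBS wins.
#'
#' @param network undirected igraph with `fbs` edge attribute.
#' @param curated an igraph, or a path to a SIF file.
#' @param fbs confidence assigned to curated edges (default 10).
#' @return The merged igraph.
#' @export
merge_curated_edges <- function(network, curated, fbs = 10) {
  if (is.character(curated)) curated <- read_sif(curated)
  ed1 <- igraph::as_data_frame(network, what = "edges")
  ed2 <- igraph::as_data_frame(curated, what = "edges")
  if (!nrow(ed2)) return(network)
  ed2$fbs <- fbs
  if (!"relation" %in% names(ed2)) ed2$relation <- "curated"
  if (!"fbs" %in% names(ed1) && nrow(ed1)) ed1$fbs <- 1
  if (!"relation" %in% names(ed1) && nrow(ed1)) ed1$relation <- "pp"
  all_ed <- rbind(ed1[, c("from", "to", "relation", "fbs")],
                  ed2[, c("from", "to", "relation", "fbs")])
  key <- .ekey(all_ed$from, all_ed$to)
  ord <- order(key, -all_ed$fbs)
  keep <- ord[!duplicated(key[ord])]
  igraph::graph_from_data_frame(all_ed[keep, ], directed = FALSE)
}

# drop edges below an FBS floor; `strict` uses fbs > floor, else fbs >= floor
.filter_fbs <- function(network, fbs_min, strict = FALSE) {
  if (is.null(igraph::edge_attr(network, "fbs"))) return(network)
  fbs <- igraph::E(network)$fbs
  keep <- if (strict) fbs > fbs_min else fbs >= fbs_min
  igraph::subgraph_from_edges(network, igraph::E(network)[keep],
                              delete.vertices = FALSE)
}
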