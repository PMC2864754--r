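#' Read a gene-to-GO biological process map
#'
#' Accepts either a two-column tab-separated file (`gene`, `go_id`; a
#' header line is detected and skipped when the second field does not look
#' like a GO id) or a GAF 2.x association file, from which columns 2 (DB
#' object id) and 5 (GO id) are taken; GAF comment lines start with `!`.
#'
#' @param path path to the map file.
#' @param format `"auto"` (default), `"tsv"` or `"gaf"`.
#' @param term_names optional named character vector of GO term names.
#' @return An object of class `go_map`: list with `gene2go` (named list of
#'   character vectors) and `term_names`.
#' @export
read_go_map <- function(path, format = c("auto", "tsv", "gaf"),
                        term_names = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (any(startsWith(lines, "!")) ||
                  any(lengths(strsplit(head(lines[nzchar(lines)], 5),
                                       "\t")) >= 15)) "gaf" else "tsv"
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    if (any(lengths(parts) < 5)) .stopf("GAF line with fewer than 5 columns")
    gene <- vapply(parts, `[[`, "", 2L)
    term <- vapply(parts, `[[`, "", 5L)
  } else {
    if (any(lengths(parts) < 2)) .stopf("GO map line with fewer than 2 columns")
    gene <- vapply(parts, `[[`, "", 1L)
    term <- vapply(parts, `[[`, "", 2L)
    if (length(gene) && !grepl("^GO:", term[1]) && grepl("^GO:", term[-1])[1]) {
      gene <- gene[-1]; term <- term[-1]   # header row
    }
  }
  if (any(!nzchar(gene))) .stopf("empty gene id in GO map")
  go_annotation(split(term, gene), term_names)
}

#' Construct a gene-to-GO annotation object
#'
#' @param gene2go named list: gene id -> character vector of GO term ids.
#' @param term_names optional named character vector of term names.
#' @return A `go_map` object.
#' @export
go_annotation <- function(gene2go, term_names = NULL) {
  if (is.null(names(gene2go)) || any(!nzchar(names(gene2go)))) {
    .stopf("gene2go must be a named list with non-empty gene ids")
  }
  gene2go <- lapply(gene2go, function(x) unique(as.character(x)))
  if (any(lengths(gene2go) == 0)) .stopf("empty GO term set for a gene")
  structure(list(gene2go = gene2go, term_names = term_names),
            class = "go_map")
}

#' @export
print.go_map <- function(x, ...) {
  cat(sprintf("go_map: %d genes, %d GO terms\n",
              length(x$gene2go), length(unique(unlist(x$gene2go)))))
  invisible(x)
}

# invert: term -> genes
go_members <- function(go_map, universe = NULL) {
  genes <- names(go_map$gene2go)
  if (!is.null(universe)) genes <- intersect(genes, universe)
  if (!length(genes)) return(list())
  long <- data.frame(
    gene = rep(genes, lengths(go_map$gene2go[genes])),
    term = unlist(go_map$gene2go[genes], use.names = FALSE),
    stringsAsFactors = FALSE)
  split(long$gene, long$term)
}
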