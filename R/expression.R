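#' Construct an expression dataset
#'
#' Bundles a genes-by-samples matrix of log10 sample/reference ratios with
#' its sample metadata. Values are expression ratios on the log10 scale
#' relative to a common reference pool (universal reference design);
#' missing values are permitted and are dropped pairwise downstream.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `day` (integer 1-5),
#'   `treatment` (`"control"` or `"treated"`) and `replicate` (integer >= 1),
#'   one row per column of `values`.
#' @return An object of class `expr_dataset`: a list with elements `values`
#'   and `samples`.
#' @examples
#' d <- expr_dataset(
#'   matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
#'   data.frame(sample_id = paste0("s", 1:4), day = c(1, 1, 2, 2),
#'              treatment = rep(c("control", "treated"), 2), replicate = 1)
#' )
#' d
#' @export
expr_dataset <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    .stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    .stopf("`values` must have gene rownames and sample colnames")
  }
  samples <- validate_sample_sheet(samples)
  extra <- setdiff(colnames(values), samples$sample_id)
  if (length(extra)) {
    .stopf("samples in the table but not the sheet: %s",
           paste(extra, collapse = ", "))
  }
  miss <- setdiff(samples$sample_id, colnames(values))
  if (length(miss)) {
    .stopf("samples in the sheet but not the table: %s",
           paste(miss, collapse = ", "))
  }
  if (anyDuplicated(rownames(values))) .stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) .stopf("duplicate sample ids")
  values <- values[, samples$sample_id, drop = FALSE]
  structure(list(values = values, samples = samples),
            class = "expr_dataset")
}

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "day", "treatment", "replicate")
  if (!all(need %in% names(samples))) {
    .stopf("sample sheet needs columns: %s", paste(need, collapse = ", "))
  }
  samples <- as.data.frame(samples)[, need]
  samples$sample_id <- as.character(samples$sample_id)
  samples$day <- as.integer(samples$day)
  samples$treatment <- as.character(samples$treatment)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) .stopf("duplicate sample_id in sheet")
  if (!all(samples$day %in% 1:5)) .stopf("day must be an integer in 1..5")
  if (!all(samples$treatment %in% c("control", "treated"))) {
    .stopf("treatment must be 'control' or 'treated'")
  }
  if (any(samples$replicate < 1)) .stopf("replicate must be >= 1")
  key <- paste(samples$day, samples$treatment, samples$replicate)
  if (anyDuplicated(key)) {
    .stopf("duplicate (day, treatment, replicate) combination in sheet")
  }
  rownames(samples) <- NULL
  samples
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(day = x$samples$day, treatment = x$samples$treatment)
  cat("replicates per cell:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Read an expression table and its sample sheet
#'
#' The expression table is tab-separated with gene ids in the first column
#' and one column per sample; cells are log10 ratios with `"NA"` marking
#' missing values. The sample sheet is tab-separated with columns
#' `sample_id`, `day`, `treatment`, `replicate`. The two files must describe
#' exactly the same samples.
#'
#' @param table_path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return An [expr_dataset()].
#' @export
read_expression <- function(table_path, sample_sheet_path) {
  tab <- read.delim(table_path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) .stopf("malformed expression header: need >= 2 columns")
  genes <- tab[[1]]
  if (anyDuplicated(genes)) .stopf("duplicate gene ids in expression table")
  raw <- as.matrix(tab[, -1, drop = FALSE])
  bad <- raw != "NA" & is.na(suppressWarnings(as.numeric(raw)))
  if (any(bad, na.rm = TRUE)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    .stopf("non-numeric cell at gene '%s', sample '%s'",
           genes[w[1]], colnames(raw)[w[2]])
  }
  values <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw),
                   dimnames = list(genes, colnames(raw)))
  sheet <- read.delim(sample_sheet_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  expr_dataset(values, sheet)
}

#' Write an expression dataset back to TSV files
#'
#' @param dataset an [expr_dataset()].
#' @param table_path,sample_sheet_path output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression <- function(dataset, table_path, sample_sheet_path) {
  stopifnot(inherits(dataset, "expr_dataset"))
  out <- data.frame(gene = rownames(dataset$values),
                    dataset$values, check.names = FALSE)
  write.table(out, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$samples, sample_sheet_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Collapse probe-level rows to genes
#'
#' Microarray platforms carry several probes per gene; this keeps, for each
#' gene, the probe with the highest median absolute log-ratio (the most
#' responsive probe) and renames the row to the gene id.
#'
#' @param values probe-by-sample numeric matrix (rownames = probe ids).
#' @param probe2gene named character vector mapping probe id to gene id;
#'   probes without a mapping are dropped.
#' @return A gene-by-sample matrix.
#' @export
collapse_probes <- function(values, probe2gene) {
  probes <- intersect(rownames(values), names(probe2gene))
  if (!length(probes)) .stopf("no probes map to genes")
  values <- values[probes, , drop = FALSE]
  gene <- probe2gene[probes]
  score <- apply(abs(values), 1L, median, na.rm = TRUE)
  keep <- vapply(split(seq_along(probes), gene), function(idx) {
    idx[which.max(score[idx])]
  }, integer(1))
  out <- values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out
}

# samples of one condition, as column indices
.cond_cols <- function(dataset, treatment) {
  which(dataset$samples$treatment == treatment)
}
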