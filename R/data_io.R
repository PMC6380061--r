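# Readers/writers for expression matrices, clinical tables, probe maps and
# graph exports, plus the shared validation used everywhere downstream.

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

#' Read a gene expression matrix
#'
#' Reads a delimited table (first row = sample IDs, first column = gene or
#' probe IDs) into a numeric genes x samples matrix. If a probe map is given,
#' probe rows mapping to the same gene are collapsed by their per-sample
#' arithmetic mean. Rows containing any missing value are dropped with a
#' message.
#'
#' @param path Path to a `.tsv` (tab) or `.csv` (comma) file.
#' @param probe_map Optional probe-to-gene map: a named character vector
#'   (names = probe IDs, values = gene IDs) or a two-column data frame
#'   (probe, gene). Each probe must map to exactly one gene.
#' @return Numeric matrix with unique gene row names and sample column names.
#' @export
read_expression <- function(path, probe_map = NULL) {
  df <- read.table(path, header = TRUE, sep = delim_for(path),
                   check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "", quote = "\"")
  if (ncol(df) < 3) stop("expression table needs >= 2 sample columns")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]) &
                     !vals[[j]] %in% c("NA", ""))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     vals[[j]][bad[1]], ids[bad[1]], colnames(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (!is.null(probe_map)) mat <- collapse_probes(mat, probe_map)
  validate_expression(mat)
}

collapse_probes <- function(mat, probe_map) {
  if (is.data.frame(probe_map)) {
    probe_map <- setNames(as.character(probe_map[[2]]),
                          as.character(probe_map[[1]]))
  }
  if (anyDuplicated(names(probe_map)) > 0)
    stop("probe map assigns some probe to more than one gene")
  keep <- rownames(mat) %in% names(probe_map)
  if (!all(keep)) {
    message(sum(!keep), " probes absent from the probe map were dropped")
    mat <- mat[keep, , drop = FALSE]
  }
  gene <- probe_map[rownames(mat)]
  sums <- rowsum(mat, group = gene, reorder = TRUE)
  counts <- as.vector(table(gene)[rownames(sums)])
  sums / counts
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed downstream: numeric values, unique gene and
#' sample IDs, at least 2 samples. Rows with any missing value are dropped
#' with a message.
#'
#' @param mat Numeric matrix, genes in rows.
#' @return The validated (possibly row-filtered) matrix, invisibly usable.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(mat)) > 0)
    stop("duplicate gene IDs; supply a probe map to average probes per gene")
  if (anyDuplicated(colnames(mat)) > 0) stop("duplicate sample IDs")
  if (ncol(mat) < 2) stop("need at least 2 samples")
  incomplete <- rowSums(is.na(mat)) > 0
  if (any(incomplete)) {
    message(sum(incomplete), " genes with missing values were dropped")
    mat <- mat[!incomplete, , drop = FALSE]
  }
  mat
}

#' Read a clinical table
#'
#' Expects a delimited file with header columns `sample`, `time`, `event`
#' (survival/follow-up duration and event status, 1 = death observed,
#' 0 = censored).
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @return Data frame with columns `sample` (character), `time` (numeric),
#'   `event` (integer 0/1).
#' @export
read_clinical <- function(path) {
  df <- read.table(path, header = TRUE, sep = delim_for(path),
                   stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("clinical table must have columns sample, time, event")
  validate_clinical(data.frame(sample = as.character(df$sample),
                               time = as.numeric(df$time),
                               event = as.integer(df$event),
                               stringsAsFactors = FALSE))
}

#' @rdname read_clinical
#' @param clinical A clinical data frame to validate.
#' @export
validate_clinical <- function(clinical) {
  if (anyDuplicated(clinical$sample) > 0) stop("duplicate sample IDs in clinical table")
  if (any(is.na(clinical$time)) || any(clinical$time < 0))
    stop("survival time must be non-negative")
  if (!all(clinical$event %in% c(0L, 1L)))
    stop("event status must be 0 (censored) or 1 (death)")
  clinical
}

#' Write an expression matrix / clinical table
#'
#' Delimiter chosen from the file extension (`.csv` comma, otherwise tab).
#' `write_expression` emits the same layout `read_expression` reads
#' (first column `gene`).
#'
#' @param mat Expression matrix.
#' @param clinical Clinical data frame.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_clinical <- function(clinical, path) {
  write.table(clinical[, c("sample", "time", "event")], path,
              sep = delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column delimited file (probe, gene), header optional but recommended.
#'
#' @param path Path to the map file.
#' @return Named character vector: `map[probe] == gene`.
#' @export
read_probe_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = delim_for(path),
                   stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Restrict expression and clinical data to their common samples
#'
#' The intersection of matrix samples and clinical samples is used; dropped
#' counts are reported with a message.
#'
#' @param mat Expression matrix.
#' @param clinical Clinical data frame.
#' @return List with elements `expr` and `clinical`, sample-aligned.
#' @export
align_samples <- function(mat, clinical) {
  common <- intersect(colnames(mat), clinical$sample)
  if (length(common) == 0) stop("no samples shared by matrix and clinical table")
  lost <- (ncol(mat) - length(common)) + (nrow(clinical) - length(common))
  if (lost > 0)
    message(lost, " samples present in only one of matrix/clinical were dropped")
  list(expr = mat[, common, drop = FALSE],
       clinical = clinical[match(common, clinical$sample), , drop = FALSE])
}

#' Export a network to a standard graph format
#'
#' Writes a co-expression or module network to GraphML, GML, or a two-column
#' tab-separated edge list (vertex names). GraphML/GML preserve node and edge
#' attributes; non-atomic graph attributes (e.g. attached test tables) are
#' dropped before writing.
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param format One of `"graphml"`, `"gml"`, `"edgelist"`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "gml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(graph))
  for (a in igraph::graph_attr_names(graph)) {
    if (!is.atomic(igraph::graph_attr(graph, a)) ||
        length(igraph::graph_attr(graph, a)) != 1) {
      graph <- igraph::delete_graph_attr(graph, a)
    }
  }
  if (format == "edgelist") {
    el <- igraph::as_edgelist(graph, names = TRUE)
    write.table(el, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    igraph::write_graph(graph, path, format = format)
  }
  invisible(path)
}
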