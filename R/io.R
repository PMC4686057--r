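#' Read a log2 expression matrix from TSV or GEO series-matrix text
#'
#' The plain `tsv` dialect is a tab-delimited table whose header row holds
#' sample ids and whose first column holds gene/probeset ids. The
#' `geo-series-matrix` dialect is the same table embedded between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` sentinel
#' lines of a GEO series-matrix file, with optionally quoted identifiers;
#' all other `!`-prefixed metadata lines are ignored.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"geo-series-matrix"`.
#' @param groups either a named character vector (sample -> group) or the
#'   path of a two-column sample/group TSV (see [read_sample_groups()]).
#' @param linear if `TRUE` values are on the linear scale and `log2` is
#'   applied on load (values must then be positive).
#' @return an [expression_study()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "geo-series-matrix"),
                                   groups, linear = FALSE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  offset <- 0L
  if (dialect == "geo-series-matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1 || length(end) != 1 || end <= beg)
      stop("parse error: series-matrix sentinels not found in ", path)
    offset <- beg
    lines <- lines[(beg + 1):(end - 1)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("parse error: no data rows in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  cells <- lapply(cells, function(z) gsub('^"|"$', "", z))
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad + offset, widths[1], widths[bad]))
  }
  header <- cells[[1]][-1]
  if (anyDuplicated(header))
    stop("parse error: duplicate sample ids: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  body <- cells[-1]
  ids <- vapply(body, `[`, "", 1L)
  num <- suppressWarnings(
    vapply(body, function(z) as.numeric(z[-1]), numeric(length(header))))
  num <- matrix(num, nrow = length(header))   # guard the 1-sample case
  vals <- t(num)
  bad_cell <- which(is.na(vals) &
                    t(vapply(body, function(z) !(z[-1] %in% c("", "NA")),
                             logical(length(header)))), arr.ind = TRUE)
  if (nrow(bad_cell) > 0)
    stop(sprintf("parse error at line %d: non-numeric value",
                 bad_cell[1, 1] + 1L + offset))
  dimnames(vals) <- list(ids, header)
  if (linear) {
    if (any(vals <= 0, na.rm = TRUE))
      stop("`linear = TRUE` requires positive values")
    vals <- log2(vals)
  }
  if (is.character(groups) && length(groups) == 1 && file.exists(groups))
    groups <- read_sample_groups(groups)
  expression_study(vals, groups[colnames(vals)])
}

#' Write an expression study as a tab-delimited matrix
#'
#' Emits the `tsv` dialect accepted by [read_expression_matrix()]: UTF-8,
#' Unix newlines, header row of sample ids, first column `ID`.
#'
#' @param study an [expression_study()].
#' @param path output file.
#' @param digits significant digits used when formatting (the default 17 is
#'   lossless for doubles, so write/read roundtrips are exact).
#' @export
write_expression_matrix <- function(study, path, digits = 17) {
  m <- study$values
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c("ID", colnames(m)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = digits, format = "g")), collapse = "\t")
  }, "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a two-column sample-to-group TSV
#'
#' The mapping is deliberately explicit (never inferred from sample names,
#' which in public repositories are free text). Columns: sample id, group.
#'
#' @param path input file (no header).
#' @return named character vector, sample -> group.
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 2) stop("sample-group file must have exactly two columns")
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample ids in group file")
  stats::setNames(df[[2]], df[[1]])
}

#' Write a sample-to-group TSV
#' @param groups named character vector, sample -> group.
#' @param path output file.
#' @export
write_sample_groups <- function(groups, path) {
  utils::write.table(data.frame(names(groups), unname(groups)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probeset-to-gene annotation table
#'
#' Two-column TSV mapping probeset ids to gene symbols (many probesets per
#' gene allowed). Duplicate probeset rows with conflicting symbols are an
#' error; exact duplicate rows are collapsed.
#'
#' @param path input file (no header).
#' @return named character vector, probe -> gene symbol.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 2) stop("annotation file must have exactly two columns")
  df <- unique(df)
  if (any(!nzchar(df[[2]]))) stop("annotation contains empty gene symbols")
  dup <- df[[1]][duplicated(df[[1]])]
  if (length(dup) > 0)
    stop("conflicting annotation for probes: ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `name`, `description`, then one
#' field per member gene. A set with no members is an error.
#'
#' @param path input file.
#' @return named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !any(nzchar(f[-(1:2)])))
      stop(sprintf("parse error at line %d: GMT set '%s' has no members",
                   i, f[1]))
    out[[f[1]]] <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
  }
  out
}

#' Write a ranked gene list
#'
#' Emits the standard three-column layout of top-gene tables: gene symbol,
#' signed linear fold change, pfp/FDR; floats with 4 decimal places.
#'
#' @param gene_list `data.frame` with columns `gene`, `fc`, `pfp`.
#' @param path output file.
#' @export
write_gene_list <- function(gene_list, path) {
  stopifnot(all(c("gene", "fc", "pfp") %in% names(gene_list)))
  if (anyDuplicated(gene_list$gene))
    stop("duplicate gene symbols in gene list")
  df <- data.frame(`Gene symbol` = gene_list$gene,
                   FC = sprintf("%.4f", gene_list$fc),
                   FDR = sprintf("%.4f", gene_list$pfp),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a differential network for Cytoscape
#'
#' `sif` writes `gene_a <edge class> gene_b` triples. `graphml` writes a
#' GraphML document carrying per-edge attributes `r_patient`, `r_control`,
#' `p_patient`, `p_control`, `class` and, when supplied, a per-node `de`
#' attribute (differential-expression direction).
#'
#' @param network a `diffnet` object from [build_group_network()].
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @param node_de optional named character vector, gene -> DE direction.
#' @export
write_network <- function(network, path, format = c("sif", "graphml"),
                          node_de = NULL) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    lines <- if (nrow(e) > 0)
      sprintf("%s %s %s", e$gene_a, e$class, e$gene_b) else character()
    writeLines(lines, path)
    return(invisible(path))
  }
  nodes <- network$panel
  esc <- function(z) gsub("&", "&amp;", gsub("<", "&lt;", z))
  keys <- c(
    '<key id="class" for="edge" attr.name="class" attr.type="string"/>',
    '<key id="r_patient" for="edge" attr.name="r_patient" attr.type="double"/>',
    '<key id="r_control" for="edge" attr.name="r_control" attr.type="double"/>',
    '<key id="p_patient" for="edge" attr.name="p_patient" attr.type="double"/>',
    '<key id="p_control" for="edge" attr.name="p_control" attr.type="double"/>',
    '<key id="de" for="node" attr.name="de" attr.type="string"/>')
  node_xml <- vapply(nodes, function(nd) {
    de <- if (!is.null(node_de) && nd %in% names(node_de))
      sprintf('<data key="de">%s</data>', esc(node_de[[nd]])) else ""
    sprintf('<node id="%s">%s</node>', esc(nd), de)
  }, "")
  edge_xml <- if (nrow(e) > 0) vapply(seq_len(nrow(e)), function(i) {
    sprintf(paste0('<edge source="%s" target="%s">',
                   '<data key="class">%s</data>',
                   '<data key="r_patient">%.6g</data>',
                   '<data key="r_control">%.6g</data>',
                   '<data key="p_patient">%.6g</data>',
                   '<data key="p_control">%.6g</data></edge>'),
            esc(e$gene_a[i]), esc(e$gene_b[i]), e$class[i],
            e$r_patient[i], e$r_control[i], e$p_patient[i], e$p_control[i])
  }, "") else character()
  doc <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
           keys, '<graph id="diffnet" edgedefault="undirected">',
           node_xml, edge_xml, '</graph>', '</graphml>')
  writeLines(doc, path)
  invisible(path)
}

#' Re-import a GraphML differential network
#'
#' Inverse of `write_network(..., format = "graphml")`; used for roundtrip
#' validation and for re-loading exported networks.
#'
#' @param path GraphML file.
#' @return list with `nodes` (character) and `edges` (data frame with the
#'   exported attributes).
#' @export
read_graphml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  getd <- function(e, key) {
    v <- xml2::xml_text(
      xml2::xml_find_first(e, sprintf(".//g:data[@key='%s']", key), ns))
    v
  }
  df <- data.frame(
    gene_a = xml2::xml_attr(edges, "source"),
    gene_b = xml2::xml_attr(edges, "target"),
    r_patient = as.numeric(vapply(edges, getd, "", key = "r_patient")),
    r_control = as.numeric(vapply(edges, getd, "", key = "r_control")),
    p_patient = as.numeric(vapply(edges, getd, "", key = "p_patient")),
    p_control = as.numeric(vapply(edges, getd, "", key = "p_control")),
    class = vapply(edges, getd, "", key = "class"))
  list(nodes = nodes, edges = df)
}

#' Write a differential-expression table as TSV
#' @param fit a `rankprod` fit.
#' @param path output file.
#' @export
write_de_table <- function(fit, path) {
  df <- fit$table
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(z) sprintf("%.4f", z))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
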