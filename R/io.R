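# Tabular I/O: every writer has a reader that restores value equality,
# so pipeline artifacts can round-trip through plain TSV files.

#' Write a p-value matrix
#'
#' Long form: TSV with columns `gene`, `go_id`, `p` (stored pairs only).
#' Matrix form (optional): dense TSV with genes in rows, GO terms in
#' columns, and missing cells empty.
#'
#' @param pmat a [pvalue_matrix()].
#' @param path long-form TSV path.
#' @param matrix_path optional dense-matrix TSV path.
#' @return `path`, invisibly.
#' @export
write_pvalues_tsv <- function(pmat, path, matrix_path = NULL) {
  stopifnot(inherits(pmat, "pvalue_matrix"))
  m <- pmat$p
  sm <- Matrix::summary(m)
  df <- data.frame(gene = rownames(m)[sm$i], go_id = colnames(m)[sm$j],
                   p = sm$x, stringsAsFactors = FALSE)
  df <- df[order(df$gene, df$go_id), , drop = FALSE]
  # full precision so a read-back reproduces the values exactly
  df$p <- sprintf("%.17g", df$p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    dm <- pmat_dense(pmat)
    out <- cbind(gene = rownames(dm),
                 as.data.frame(ifelse(is.na(dm), "", sprintf("%.17g", dm))))
    colnames(out) <- c("gene", colnames(dm))
    utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a long-form p-value TSV written by [write_pvalues_tsv()]
#'
#' @param path long-form TSV path.
#' @param genes,gos index sets; default the ids present in the file.
#' @return a [pvalue_matrix()].
#' @export
read_pvalues_tsv <- function(path, genes = NULL, gos = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  genes <- genes %||% sort(unique(df$gene))
  gos <- gos %||% sort(unique(df$go_id))
  mat <- Matrix::sparseMatrix(
    i = match(df$gene, genes), j = match(df$go_id, gos), x = df$p,
    dims = c(length(genes), length(gos)), dimnames = list(genes, gos)
  )
  pvalue_matrix(mat)
}

#' Write a similarity matrix
#'
#' Long form: TSV `gene_a`, `gene_b`, `gamma`, `undefined` over
#' unordered pairs. Matrix form (optional): square TSV of gamma values.
#'
#' @param sim a [similarity_matrix()].
#' @param path long-form TSV path.
#' @param matrix_path optional square-matrix TSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path, matrix_path = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  g <- sim$gamma
  genes <- rownames(g)
  idx <- which(upper.tri(g), arr.ind = TRUE)
  df <- data.frame(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    gamma = sprintf("%.17g", g[idx]),
    undefined_a = unname(sim$undefined[idx[, 1]]),
    undefined_b = unname(sim$undefined[idx[, 2]]),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    out <- cbind(gene = genes,
                 as.data.frame(matrix(sprintf("%.17g", g), nrow(g),
                                      dimnames = dimnames(g))))
    utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a long-form similarity TSV written by [write_similarity_tsv()]
#'
#' @param path long-form TSV path.
#' @return a [similarity_matrix()].
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "logical", "logical"))
  genes <- sort(unique(c(df$gene_a, df$gene_b)))
  n <- length(genes)
  gamma <- matrix(0, n, n, dimnames = list(genes, genes))
  ia <- match(df$gene_a, genes); ib <- match(df$gene_b, genes)
  gamma[cbind(ia, ib)] <- df$gamma
  gamma[cbind(ib, ia)] <- df$gamma
  undefined <- logical(n)
  undefined[ia] <- df$undefined_a
  undefined[ib] <- df$undefined_b
  diag(gamma) <- ifelse(undefined, 0, 1)
  structure(list(gamma = gamma, undefined = stats::setNames(undefined, genes)),
            class = "similarity_matrix")
}

#' Write a gene network
#'
#' Edge list TSV (`gene_a`, `gene_b`, `gamma`) plus optional GraphML
#' with edge weights and, when a partition is given, a `community`
#' vertex attribute.
#'
#' @param net a [build_network()] result.
#' @param path edge-list TSV path.
#' @param graphml_path optional GraphML path.
#' @param partition optional [label_propagation()] partition to embed.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path, graphml_path = NULL, partition = NULL) {
  stopifnot(inherits(net, "gene_network"))
  df <- network_edges(net)
  ord <- order(df$gene_a, df$gene_b)
  df <- df[ord, , drop = FALSE]
  df$gamma <- sprintf("%.17g", df$gamma)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    graph <- net$graph
    if (!is.null(partition)) {
      graph <- igraph::set_vertex_attr(
        graph, "community",
        value = unclass(partition)[igraph::V(graph)$name])
    }
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge list written by [write_network_tsv()]
#'
#' @param path edge-list TSV path.
#' @param nodes node ids (isolated nodes are not recoverable from the
#'   edge list alone); default the ids present in the file.
#' @param cutoff cutoff to record on the restored network.
#' @return a `gene_network`.
#' @export
read_network_tsv <- function(path, nodes = NULL, cutoff = 0) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  nodes <- nodes %||% sort(unique(c(df$gene_a, df$gene_b)))
  graph <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  graph <- igraph::set_vertex_attr(graph, "name", value = nodes)
  if (nrow(df) > 0) {
    graph <- igraph::add_edges(graph, as.vector(rbind(df$gene_a, df$gene_b)),
                               weight = df$gamma)
  }
  structure(list(graph = graph, cutoff = cutoff), class = "gene_network")
}

#' Write a community partition to TSV
#'
#' @param partition a [label_propagation()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  stopifnot(inherits(partition, "community_partition"))
  df <- data.frame(gene = names(partition), community = unclass(partition),
                   stringsAsFactors = FALSE)
  utils::write.table(df[order(df$gene), ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a community partition written by [write_partition_tsv()]
#'
#' @param path file path.
#' @return a `community_partition` (seed attribute unset).
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer"))
  structure(stats::setNames(df$community, df$gene),
            class = "community_partition", seed = NA_integer_, converged = NA)
}

#' Write a community enrichment table to TSV
#'
#' @param enrichment a [community_enrichment()] data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  out <- enrichment
  out$mean_p <- sprintf("%.17g", out$mean_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enrichment table written by [write_enrichment_tsv()]
#'
#' @param path file path.
#' @return data frame `community`, `go_id`, `mean_p`.
#' @export
read_enrichment_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "numeric"))
}

#' Load a gene-synonym-to-HGNC mapping table
#'
#' Expects TSV columns `synonym` and `hgnc`. Synonyms are normalized by
#' case-folding and whitespace trimming; a normalized synonym mapping to
#' more than one HGNC symbol is a collision and rejects the load with a
#' report of the offending synonyms.
#'
#' @param path file path.
#' @return an object of class `synonym_table` (named character vector,
#'   normalized synonym -> HGNC symbol, with a `provenance` attribute).
#' @export
read_synonyms_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("synonym", "hgnc")
  if (!all(need %in% names(df))) {
    stop_(path, ": synonym TSV must have columns ", paste(need, collapse = ", "))
  }
  key <- tolower(squish(df$synonym))
  pairs <- unique(data.frame(key = key, hgnc = df$hgnc, stringsAsFactors = FALSE))
  dup <- unique(pairs$key[duplicated(pairs$key)])
  if (length(dup) > 0) {
    stop_(path, ": synonym collision(s): ",
          paste(utils::head(dup, 10), collapse = ", "),
          " map to more than one HGNC symbol")
  }
  structure(stats::setNames(pairs$hgnc, pairs$key), class = "synonym_table",
            provenance = path)
}

#' Map gene synonyms to HGNC symbols
#'
#' Exact lookup after normalization (case-folding and whitespace trim);
#' unmapped inputs are reported, never guessed.
#'
#' @param symbols character vector of input symbols.
#' @param table a [read_synonyms_tsv()] table.
#' @return list with `mapped` (data frame `input`, `hgnc`, in input
#'   order) and `unmapped` (character vector of inputs with no match).
#' @export
map_to_hgnc <- function(symbols, table) {
  stopifnot(inherits(table, "synonym_table"))
  symbols <- as.character(symbols)
  key <- tolower(squish(symbols))
  hit <- key %in% names(table)
  list(
    mapped = data.frame(input = symbols[hit], hgnc = unname(table[key[hit]]),
                        stringsAsFactors = FALSE),
    unmapped = symbols[!hit]
  )
}

#' Read a gene list (one id per line)
#'
#' @param path file path; blank lines and `#` comments are skipped.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- squish(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
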