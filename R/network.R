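# Thresholded gene-gene association networks, community detection by
# asynchronous label propagation, community GO enrichment, and the four
# query tables.

#' Build a thresholded gene network
#'
#' An edge joins two genes iff their similarity is at least `cutoff` and
#' neither gene's profile is flagged undefined. All input genes are kept
#' as nodes, so isolated genes remain visible in the network.
#'
#' @param sim a [similarity_matrix()].
#' @param cutoff similarity threshold c in \[0, 1\]; the boundary value is
#'   included (gamma >= c gives an edge).
#' @return an object of class `gene_network` wrapping an igraph graph
#'   (edge attribute `weight` holds gamma) and the cutoff used.
#' @export
build_network <- function(sim, cutoff) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!is_prob(cutoff)) stop_("`cutoff` must lie in [0, 1]")
  g <- sim$gamma
  keep_pair <- outer(!sim$undefined, !sim$undefined, `&`)
  adj <- (g >= cutoff) & keep_pair
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  genes <- rownames(g)
  graph <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  graph <- igraph::set_vertex_attr(graph, "name", value = genes)
  if (nrow(idx) > 0) {
    edges <- rbind(genes[idx[, 1]], genes[idx[, 2]])
    graph <- igraph::add_edges(graph, as.vector(edges),
                               weight = g[idx])
  }
  structure(list(graph = graph, cutoff = cutoff), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges, cutoff=%g\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$cutoff))
  invisible(x)
}

#' Edge list of a gene network
#' @param net a [build_network()] result.
#' @return data frame with columns `gene_a`, `gene_b`, `gamma`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_edgelist(net$graph)
  data.frame(
    gene_a = el[, 1], gene_b = el[, 2],
    gamma = if (igraph::ecount(net$graph) > 0)
      igraph::E(net$graph)$weight else numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Community detection by asynchronous label propagation
#'
#' Every node starts with a unique label. Sweeps visit the nodes in a
#' freshly shuffled random order; each visited node adopts the label
#' that is most frequent among its neighbours, breaking ties uniformly
#' at random. The algorithm stops when every node's label is already
#' among the most frequent labels of its neighbourhood, or after
#' `max_iter` sweeps with a convergence warning. Isolated nodes keep
#' their unique labels and come out as singleton communities. All
#' randomness is driven by `seed`; the caller's RNG state is untouched.
#'
#' @param net a [build_network()] result.
#' @param seed integer seed for the sweep order and tie-breaking.
#' @param max_iter maximum number of sweeps (default 100).
#' @return an object of class `community_partition`: a named integer
#'   vector of dense labels 0..K-1 with attributes `seed` and
#'   `converged`.
#' @export
label_propagation <- function(net, seed = 1L, max_iter = 100L) {
  stopifnot(inherits(net, "gene_network"))
  if (!is_count(max_iter) || max_iter < 1) stop_("`max_iter` must be >= 1")
  graph <- net$graph
  n <- igraph::vcount(graph)
  genes <- igraph::V(graph)$name
  nbrs <- igraph::adjacent_vertices(graph, igraph::V(graph))
  nbrs <- lapply(nbrs, as.integer)

  labels <- seq_len(n)
  converged <- FALSE
  local_seed(seed, {
    if (n > 0) {
      for (sweep in seq_len(max_iter)) {
        order_ <- sample.int(n)
        for (v in order_) {
          nb <- nbrs[[v]]
          if (length(nb) == 0) next
          tab <- tabulate(labels[nb], nbins = n)
          best <- which(tab == max(tab))
          labels[v] <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
        }
        stable <- vapply(seq_len(n), function(v) {
          nb <- nbrs[[v]]
          if (length(nb) == 0) return(TRUE)
          tab <- tabulate(labels[nb], nbins = n)
          tab[labels[v]] == max(tab)
        }, logical(1))
        if (all(stable)) {
          converged <- TRUE
          break
        }
      }
    } else {
      converged <- TRUE
    }
  })
  if (!converged) {
    warning(sprintf("label propagation did not converge in %d sweeps", max_iter))
  }
  dense <- as.integer(factor(labels, levels = unique(labels))) - 1L
  structure(stats::setNames(dense, genes), class = "community_partition",
            seed = seed, converged = converged)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d genes in %d communities (seed %s)\n",
              length(x), length(unique(unclass(x))), attr(x, "seed")))
  invisible(x)
}

#' Community GO enrichment by mean association p-value
#'
#' For every (community, GO term) pair, the mean of the gene-GO p-values
#' over the community's genes, with a missing p-value counted as 1 so
#' that unstudied pairs never inflate enrichment. Rows are sorted by
#' increasing mean p within each community.
#'
#' @param pmat a [pvalue_matrix()].
#' @param part a [label_propagation()] partition whose genes are all
#'   indexed by `pmat`.
#' @param gos GO ids to evaluate (default all GO terms in `pmat`).
#' @return data frame with columns `community`, `go_id`, `mean_p`.
#' @export
community_enrichment <- function(pmat, part, gos = NULL) {
  stopifnot(inherits(part, "community_partition"))
  genes <- names(part)
  unknown <- setdiff(genes, pmat_genes(pmat))
  if (length(unknown) > 0) {
    stop_("partition gene(s) not in p-value matrix: ",
          paste(unknown, collapse = ", "))
  }
  gos <- gos %||% pmat_gos(pmat)
  unknown_go <- setdiff(gos, pmat_gos(pmat))
  if (length(unknown_go) > 0) {
    stop_("unknown GO id(s): ", paste(unknown_go, collapse = ", "))
  }
  m <- pmat_dense(pmat, genes = genes, gos = gos)
  m[is.na(m)] <- 1
  labs <- sort(unique(unclass(part)))
  rows <- lapply(labs, function(lb) {
    mem <- genes[unclass(part) == lb]
    mp <- colMeans(m[mem, , drop = FALSE])
    ord <- order(mp, names(mp))
    data.frame(community = lb, go_id = names(mp)[ord], mean_p = unname(mp)[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment
#'
#' @param p p-value(s) in (0, 1].
#' @param m number of tests (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (!is_count(m) || m < 1) stop_("`m` must be a count >= 1")
  if (any(p <= 0 | p > 1)) stop_("`p` must lie in (0, 1]")
  pmin(1, m * p)
}

#' GO associations of one gene
#'
#' @param pmat a [pvalue_matrix()].
#' @param gene gene id.
#' @param m Bonferroni family size; defaults to the number of GO terms
#'   indexed by `pmat`.
#' @return data frame `go_id`, `p`, `p_bonferroni`, sorted by increasing
#'   p then GO id; GO terms with no stored p-value are omitted.
#' @export
gene_query <- function(pmat, gene, m = NULL) {
  if (!gene %in% pmat_genes(pmat)) stop_("unknown gene id(s): ", gene)
  m <- m %||% length(pmat_gos(pmat))
  p <- pmat_dense(pmat, genes = gene)[1, ]
  p <- p[!is.na(p)]
  ord <- order(p, names(p))
  data.frame(go_id = names(p)[ord], p = unname(p)[ord],
             p_bonferroni = bonferroni(unname(p)[ord], m),
             stringsAsFactors = FALSE)
}

#' Gene associations of one GO term
#'
#' @param pmat a [pvalue_matrix()].
#' @param go GO id.
#' @param m Bonferroni family size; defaults to the number of genes
#'   indexed by `pmat`.
#' @return data frame `gene`, `p`, `p_bonferroni`, sorted by increasing
#'   p then gene id; genes with no stored p-value are omitted.
#' @export
go_query <- function(pmat, go, m = NULL) {
  if (!go %in% pmat_gos(pmat)) stop_("unknown GO id(s): ", go)
  m <- m %||% length(pmat_genes(pmat))
  p <- pmat_dense(pmat, gos = go)[, 1]
  p <- p[!is.na(p)]
  if (length(p) == 0) {
    return(data.frame(gene = character(), p = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE))
  }
  ord <- order(p, names(p))
  data.frame(gene = names(p)[ord], p = unname(p)[ord],
             p_bonferroni = bonferroni(unname(p)[ord], m),
             stringsAsFactors = FALSE)
}

#' Gene x GO association table and matrix
#'
#' @param pmat a [pvalue_matrix()].
#' @param genes gene ids to include.
#' @param gos GO ids to include, or `"all"` for every GO term in `pmat`.
#' @param k optional: restrict the GO terms to the `k` with the smallest
#'   average p over `genes` (see [select_top_go()]).
#' @return list with `long` (data frame `gene`, `go_id`, `p`, missing
#'   pairs omitted, sorted by p then ids) and `matrix` (dense genes x GO
#'   p-value matrix with `NA` for missing pairs).
#' @export
gene_go_query <- function(pmat, genes, gos = "all", k = NULL) {
  genes <- unique(genes)
  unknown <- setdiff(genes, pmat_genes(pmat))
  if (length(unknown) > 0) {
    stop_("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  if (identical(gos, "all")) gos <- pmat_gos(pmat)
  unknown_go <- setdiff(gos, pmat_gos(pmat))
  if (length(unknown_go) > 0) {
    stop_("unknown GO id(s): ", paste(unknown_go, collapse = ", "))
  }
  if (!is.null(k)) gos <- intersect(select_top_go(pmat, genes, k), gos)
  m <- pmat_dense(pmat, genes = genes, gos = gos)
  idx <- which(!is.na(m), arr.ind = TRUE)
  long <- data.frame(
    gene = rownames(m)[idx[, 1]], go_id = colnames(m)[idx[, 2]],
    p = m[idx], stringsAsFactors = FALSE
  )
  long <- long[order(long$p, long$gene, long$go_id), , drop = FALSE]
  rownames(long) <- NULL
  list(long = long, matrix = m)
}

#' GO terms shared by two genes
#'
#' @param pmat a [pvalue_matrix()].
#' @param gene_a,gene_b gene ids.
#' @param top_n number of rows to return (>= 1; default all).
#' @return data frame `go_id`, `p_a`, `p_b` over GO terms with a stored
#'   p-value for both genes, sorted by the smaller of the two p-values.
#' @export
shared_go <- function(pmat, gene_a, gene_b, top_n = Inf) {
  unknown <- setdiff(c(gene_a, gene_b), pmat_genes(pmat))
  if (length(unknown) > 0) {
    stop_("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  if (!(is.infinite(top_n) || is_count(top_n)) || top_n < 1) {
    stop_("`top_n` must be >= 1")
  }
  m <- pmat_dense(pmat, genes = c(gene_a, gene_b))
  both <- !is.na(m[1, ]) & !is.na(m[2, ])
  df <- data.frame(go_id = colnames(m)[both], p_a = m[1, both], p_b = m[2, both],
                   stringsAsFactors = FALSE)
  df <- df[order(pmin(df$p_a, df$p_b), df$go_id), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_n)
}

#' Layout configuration for force-directed drawing
#'
#' @param k optimal node spacing (> 0); larger values spread the drawing
#'   out. Default `1/sqrt(n)` at layout time when `NULL`.
#' @param seed integer seed for the initial node positions.
#' @param iterations number of cooling iterations.
#' @return an object of class `layout_config`.
#' @export
layout_config <- function(k = NULL, seed = 1L, iterations = 50L) {
  if (!is.null(k) && (!is.numeric(k) || length(k) != 1L || k <= 0)) {
    stop_("`k` must be a positive number")
  }
  if (!is_count(iterations) || iterations < 1) stop_("`iterations` must be >= 1")
  structure(list(k = k, seed = as.integer(seed), iterations = as.integer(iterations)),
            class = "layout_config")
}

#' Fruchterman-Reingold force-directed layout
#'
#' Spring-embedder drawing: connected nodes attract (force d^2/k) and
#' all node pairs repel (force k^2/d), with displacements capped by a
#' linearly decreasing temperature. The spacing parameter k sets the
#' optimal inter-node distance, so the mean pairwise distance of the
#' drawing grows with k. Deterministic for a fixed seed.
#'
#' @param net a [build_network()] result.
#' @param cfg a [layout_config()].
#' @return numeric matrix (nodes x 2) of coordinates, rownames = genes.
#' @export
fr_layout <- function(net, cfg = layout_config()) {
  stopifnot(inherits(net, "gene_network"), inherits(cfg, "layout_config"))
  graph <- net$graph
  n <- igraph::vcount(graph)
  genes <- igraph::V(graph)$name
  if (n == 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  }
  k <- cfg$k %||% (1 / sqrt(n))
  el <- igraph::as_edgelist(graph, names = FALSE)
  pos <- local_seed(cfg$seed, matrix(stats::runif(2 * n), n, 2))
  if (n > 1) {
    t0 <- 0.1
    for (iter in seq_len(cfg$iterations)) {
      temp <- t0 * (1 - (iter - 1) / cfg$iterations)
      disp <- matrix(0, n, 2)
      # repulsion between all pairs
      dx <- outer(pos[, 1], pos[, 1], `-`)
      dy <- outer(pos[, 2], pos[, 2], `-`)
      d2 <- dx^2 + dy^2
      d <- sqrt(d2)
      d[d < 1e-9] <- 1e-9
      rep_f <- k^2 / d^2  # (k^2/d) / d: unit vector times force
      diag(rep_f) <- 0
      disp[, 1] <- rowSums(dx * rep_f)
      disp[, 2] <- rowSums(dy * rep_f)
      # attraction along edges
      if (nrow(el) > 0) {
        a <- el[, 1]; b <- el[, 2]
        ex <- pos[a, 1] - pos[b, 1]
        ey <- pos[a, 2] - pos[b, 2]
        ed <- sqrt(ex^2 + ey^2)
        ed[ed < 1e-9] <- 1e-9
        att <- ed / k  # (d^2/k) / d
        fx <- ex * att; fy <- ey * att
        for (e in seq_along(a)) {
          disp[a[e], ] <- disp[a[e], ] - c(fx[e], fy[e])
          disp[b[e], ] <- disp[b[e], ] + c(fx[e], fy[e])
        }
      }
      dl <- sqrt(rowSums(disp^2))
      dl[dl < 1e-9] <- 1e-9
      step <- pmin(dl, temp) / dl
      pos <- pos + disp * step
    }
  }
  dimnames(pos) <- list(genes, c("x", "y"))
  pos
}

#' Edge counts at matched percentile cutoffs
#'
#' For each percentile q, each similarity measure contributes a cutoff
#' taken from its *own* corpus-wide distribution of defined pairwise
#' values -- the way percentile presets calibrate a confidence level --
#' and the edge count is the number of pairs at or above that cutoff.
#' When `genes` is given, edges are counted only among those genes (the
#' queried gene signature) while the cutoffs still come from the full
#' distributions; this is the comparison that shows whether GO-guided
#' similarity links signature genes that rarely co-occur directly.
#'
#' @param sim_go GO-guided [similarity_matrix()].
#' @param sim_base baseline [similarity_matrix()]
#'   (e.g. [cooccurrence_similarity()]) over the same genes.
#' @param percentiles probabilities in \[0, 1\].
#' @param genes optional gene subset whose pairs are counted; default
#'   all defined pairs.
#' @return data frame `percentile`, `cutoff_go`, `cutoff_baseline`,
#'   `edges_go`, `edges_baseline`.
#' @export
edge_richness <- function(sim_go, sim_base,
                          percentiles = seq(0.90, 1.00, by = 0.02),
                          genes = NULL) {
  v_go <- similarity_values(sim_go)
  v_base <- similarity_values(sim_base)
  c_go <- similarity_percentiles(v_go, percentiles)
  c_base <- similarity_percentiles(v_base, percentiles)
  if (!is.null(genes)) {
    sub <- function(sim) {
      keep <- intersect(genes, names(sim$undefined)[!sim$undefined])
      g <- sim$gamma[keep, keep, drop = FALSE]
      g[upper.tri(g)]
    }
    v_go <- sub(sim_go)
    v_base <- sub(sim_base)
  }
  data.frame(
    percentile = percentiles,
    cutoff_go = c_go,
    cutoff_baseline = c_base,
    edges_go = vapply(c_go, function(c) sum(v_go >= c), numeric(1)),
    edges_baseline = vapply(c_base, function(c) sum(v_base >= c), numeric(1))
  )
}
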