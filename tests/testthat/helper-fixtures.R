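# Shared fixtures, all built in code.

# Sparse p-value matrix from explicit (gene, go, p) triples.
make_pmat <- function(gene, go, p, genes = NULL, gos = NULL) {
  genes <- genes %||% sort(unique(gene))
  gos <- gos %||% sort(unique(go))
  litgonet::pvalue_matrix(Matrix::sparseMatrix(
    i = match(gene, genes), j = match(go, gos), x = p,
    dims = c(length(genes), length(gos)), dimnames = list(genes, gos)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# similarity_matrix object from an explicit symmetric gamma matrix.
make_sim <- function(gamma, undefined = NULL) {
  genes <- rownames(gamma)
  undefined <- undefined %||% stats::setNames(rep(FALSE, nrow(gamma)), genes)
  structure(list(gamma = gamma, undefined = undefined),
            class = "similarity_matrix")
}

# Similarity matrix encoding disjoint cliques: genes grouped in blocks,
# within-block gamma = 0.9, between-block 0.
clique_sim <- function(sizes) {
  n <- sum(sizes)
  genes <- sprintf("g%02d", seq_len(n))
  gamma <- matrix(0, n, n, dimnames = list(genes, genes))
  offset <- 0
  for (s in sizes) {
    idx <- offset + seq_len(s)
    gamma[idx, idx] <- 0.9
    offset <- offset + s
  }
  diag(gamma) <- 1
  make_sim(gamma)
}

# Random sparse p-value matrix for property tests.
random_pmat <- function(n_genes, n_go, density = 0.4, seed = 1) {
  withr::with_seed(seed, {
    n <- rbinom(1, n_genes * n_go, density)
    cells <- sample.int(n_genes * n_go, max(n, 1))
    make_pmat(
      gene = sprintf("g%02d", (cells - 1) %% n_genes + 1),
      go = sprintf("GO:%07d", (cells - 1) %/% n_genes + 1),
      p = runif(length(cells), min = 1e-8, max = 1),
      genes = sprintf("g%02d", seq_len(n_genes)),
      gos = sprintf("GO:%07d", seq_len(n_go))
    )
  })
}

# End-to-end run on one synthetic corpus; memoised across test files so
# the planted-recovery and edge-richness checks share the same corpora.
.recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  cfg <- litgonet::synthetic_corpus_config(seed = seed)
  simc <- litgonet::simulate_corpus(cfg)
  counts <- litgonet::tally_counts(simc$records)
  pmat <- litgonet::build_pvalue_matrix(counts)
  sim <- litgonet::similarity_matrix(pmat)
  res <- list(truth = simc$truth, counts = counts, pmat = pmat, sim = sim,
              sim_base = litgonet::cooccurrence_similarity(counts))
  .recovery_cache[[key]] <- res
  res
}

module_genes_of <- function(truth) {
  names(truth$gene_module)[truth$gene_module > 0]
}

# ARI of the label-propagation partition at a percentile cutoff,
# restricted to the planted module genes.
recovery_ari <- function(run, percentile, seed) {
  cutoff <- litgonet::similarity_percentiles(
    litgonet::similarity_values(run$sim), percentile)
  net <- litgonet::build_network(run$sim, cutoff)
  part <- litgonet::label_propagation(net, seed = seed)
  mg <- module_genes_of(run$truth)
  mclust::adjustedRandIndex(unclass(part)[mg], run$truth$gene_module[mg])
}

# Exact-rational oracle grid for the mid-p statistic (see inst/oracle).
midp_oracle_grid <- function(nmax) {
  script <- system.file("oracle", "midp_oracle.py", package = "litgonet",
                        mustWork = TRUE)
  out <- tempfile(fileext = ".tsv")
  status <- system2("python", c(shQuote(script), nmax), stdout = out)
  stopifnot(status == 0)
  data.table::fread(out, sep = "\t")
}
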