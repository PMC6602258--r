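# Synthetic literature corpora with planted functional modules.
#
# The generator emulates the statistical structure the mining pipeline
# assumes: genes of a functional module are studied in abstracts that
# preferentially co-mention the module's GO terms, while any gene or GO
# term can also appear as background noise. Each topical abstract has a
# single focal gene; other genes of the same module co-occur directly
# only rarely. This is exactly the regime where GO-guided inference can
# link genes that are almost never mentioned together.

#' Configuration for a synthetic corpus
#'
#' @param n_genes,n_go,n_abstracts corpus dimensions.
#' @param n_modules number of planted modules.
#' @param genes_per_module,gos_per_module module sizes; module
#'   memberships are disjoint and must fit inside the gene/GO universes.
#' @param p_signal_gene probability that an abstract is topical (about
#'   one module, chosen uniformly); the remaining share is background.
#' @param p_signal_go probability that a topical abstract mentions each
#'   of its module's GO terms.
#' @param p_background probability that any given gene or GO term is
#'   mentioned in an abstract as background noise.
#' @param p_direct_cooccurrence probability that a topical abstract
#'   mentions each non-focal gene of its module (direct gene-gene
#'   co-occurrence).
#' @param seed integer seed; the corpus is fully reproducible from it.
#' @return an object of class `synthetic_corpus_config`.
#' @export
synthetic_corpus_config <- function(n_genes = 40L, n_go = 80L,
                                    n_abstracts = 2000L, n_modules = 4L,
                                    genes_per_module = 5L, gos_per_module = 8L,
                                    p_signal_gene = 0.8, p_signal_go = 0.6,
                                    p_background = 0.01,
                                    p_direct_cooccurrence = 0.05, seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_go = n_go, n_abstracts = n_abstracts,
    n_modules = n_modules, genes_per_module = genes_per_module,
    gos_per_module = gos_per_module, p_signal_gene = p_signal_gene,
    p_signal_go = p_signal_go, p_background = p_background,
    p_direct_cooccurrence = p_direct_cooccurrence, seed = seed
  )
  for (f in c("n_genes", "n_go", "n_abstracts", "n_modules",
              "genes_per_module", "gos_per_module")) {
    if (!is_count(cfg[[f]])) stop_("`", f, "` must be a non-negative integer")
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  for (f in c("p_signal_gene", "p_signal_go", "p_background",
              "p_direct_cooccurrence")) {
    if (!is_prob(cfg[[f]])) stop_("`", f, "` must be a probability in [0, 1]")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_("`seed` must be a single integer")
  }
  cfg$seed <- as.integer(seed)
  if (cfg$n_modules * cfg$genes_per_module > cfg$n_genes) {
    stop_("`genes_per_module` x `n_modules` exceeds `n_genes`")
  }
  if (cfg$n_modules * cfg$gos_per_module > cfg$n_go) {
    stop_("`gos_per_module` x `n_modules` exceeds `n_go`")
  }
  structure(cfg, class = "synthetic_corpus_config")
}

#' Simulate a synthetic mention corpus with planted modules
#'
#' Per abstract: a topic is drawn (one of the modules with total
#' probability `p_signal_gene`, uniformly; otherwise background). A
#' topical abstract mentions one focal gene drawn uniformly from its
#' module, each other module gene independently with
#' `p_direct_cooccurrence`, and each module GO term independently with
#' `p_signal_go`. Independently, every gene and GO term is mentioned
#' with probability `p_background`. Records with no mentions at all are
#' kept (they carry an abstract id but contribute nothing to tallies).
#'
#' @param cfg a [synthetic_corpus_config()].
#' @return list with `records` (list of [abstract_record()]s) and
#'   `truth` (an object of class `synthetic_truth`: named integer
#'   vectors `gene_module` and `go_module`, module numbers 1..M with 0
#'   meaning background).
#' @export
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_corpus_config"))
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  gos <- sprintf("GO:%07d", seq_len(cfg$n_go))

  gene_module <- integer(cfg$n_genes)
  go_module <- integer(cfg$n_go)
  if (cfg$n_modules > 0) {
    gene_module[seq_len(cfg$n_modules * cfg$genes_per_module)] <-
      rep(seq_len(cfg$n_modules), each = cfg$genes_per_module)
    go_module[seq_len(cfg$n_modules * cfg$gos_per_module)] <-
      rep(seq_len(cfg$n_modules), each = cfg$gos_per_module)
  }
  names(gene_module) <- genes
  names(go_module) <- gos

  records <- local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_abstracts), function(a) {
      g_hit <- stats::runif(cfg$n_genes) < cfg$p_background
      t_hit <- stats::runif(cfg$n_go) < cfg$p_background
      topical <- cfg$n_modules > 0 && stats::runif(1) < cfg$p_signal_gene
      if (topical) {
        mod <- sample.int(cfg$n_modules, 1)
        mod_genes <- which(gene_module == mod)
        mod_gos <- which(go_module == mod)
        focal <- mod_genes[sample.int(length(mod_genes), 1)]
        g_hit[focal] <- TRUE
        others <- setdiff(mod_genes, focal)
        g_hit[others] <- g_hit[others] |
          (stats::runif(length(others)) < cfg$p_direct_cooccurrence)
        t_hit[mod_gos] <- t_hit[mod_gos] |
          (stats::runif(length(mod_gos)) < cfg$p_signal_go)
      }
      abstract_record(sprintf("S%05d", a), genes[g_hit], gos[t_hit])
    })
  })

  truth <- structure(list(gene_module = gene_module, go_module = go_module),
                     class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes, %d GO terms, %d modules\n",
              length(x$gene_module), length(x$go_module),
              length(setdiff(unique(x$gene_module), 0L))))
  invisible(x)
}

#' Write a synthetic truth table to TSV
#'
#' @param truth a `synthetic_truth` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- rbind(
    data.frame(term_kind = "gene", term_id = names(truth$gene_module),
               module = unname(truth$gene_module), stringsAsFactors = FALSE),
    data.frame(term_kind = "go", term_id = names(truth$go_module),
               module = unname(truth$go_module), stringsAsFactors = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a synthetic truth table written by [write_truth_tsv()]
#'
#' @param path file path.
#' @return a `synthetic_truth` object.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  structure(
    list(
      gene_module = with(df[df$term_kind == "gene", ],
                         stats::setNames(module, term_id)),
      go_module = with(df[df$term_kind == "go", ],
                       stats::setNames(module, term_id))
    ),
    class = "synthetic_truth"
  )
}
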