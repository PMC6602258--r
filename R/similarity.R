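# Gene-gene similarity from GO-association profiles.
#
# Each gene carries a weight profile over GO terms, w_j = -log p_ij after
# truncating p at a floor (default 1e-6, so a handful of extremely small
# p-values cannot dominate the geometry); pairs with no stored p-value
# contribute weight zero. The similarity between two genes is the cosine
# of the angle between their weight profiles, taken over the union of
# their supports, so gamma lies in [0, 1] and depends only on ratios of
# weights -- in particular it is invariant to the logarithm base.

.weight_matrix <- function(pmat, genes = NULL, floor = 1e-6, log_base = exp(1)) {
  if (!is_prob(floor) || floor <= 0 || floor >= 1) {
    stop_("`floor` must lie strictly between 0 and 1")
  }
  if (!is.numeric(log_base) || log_base <= 1) stop_("`log_base` must exceed 1")
  W <- pmat$p
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(W))
    if (length(unknown) > 0) {
      stop_("unknown gene id(s): ", paste(unknown, collapse = ", "))
    }
    W <- W[genes, , drop = FALSE]
  }
  W@x <- -log(pmax(W@x, floor)) / log(log_base)
  Matrix::drop0(W)
}

#' Weight profile of one gene
#'
#' @param pmat a [pvalue_matrix()].
#' @param gene gene id.
#' @param floor truncation floor applied to p before taking logs.
#' @param log_base logarithm base (default natural log; the cosine
#'   similarity is unaffected by this choice).
#' @return named numeric vector of nonzero weights `-log(max(p, floor))`
#'   over GO terms; GO terms without a stored p-value carry weight 0 and
#'   are omitted.
#' @export
weight_profile <- function(pmat, gene, floor = 1e-6, log_base = exp(1)) {
  W <- .weight_matrix(pmat, genes = gene, floor = floor, log_base = log_base)
  w <- W[1, ]
  w[w > 0]
}

#' Cosine similarity of two weight profiles
#'
#' Profiles are sparse named vectors over the same GO index space; the
#' sum runs over the union of the two supports (entries absent from a
#' profile are zero). If either profile is all-zero the similarity is
#' undefined: 0 is returned with attribute `undefined = TRUE`.
#'
#' @param a,b named numeric weight vectors (as from [weight_profile()]).
#' @return similarity in \[0, 1\], with attribute `undefined` when either
#'   norm is zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    return(structure(0, undefined = TRUE))
  }
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) {
      stop_("unnamed profiles must have equal length")
    }
    dot <- sum(a * b)
  } else {
    shared <- intersect(names(a), names(b))
    dot <- sum(a[shared] * b[shared])
  }
  min(1, dot / (na * nb))
}

#' Pairwise gene-gene similarity matrix
#'
#' @param pmat a [pvalue_matrix()].
#' @param genes gene ids to include (default all genes in `pmat`). Genes
#'   unknown to `pmat` are an error listing the offending ids.
#' @inheritParams weight_profile
#' @return an object of class `similarity_matrix`: a symmetric `gamma`
#'   matrix in \[0, 1\] with unit diagonal for genes with a nonzero
#'   profile, plus a logical `undefined` vector flagging genes whose
#'   profile is all-zero (their similarities are stored as 0).
#' @export
similarity_matrix <- function(pmat, genes = NULL, floor = 1e-6,
                              log_base = exp(1)) {
  W <- .weight_matrix(pmat, genes = genes, floor = floor, log_base = log_base)
  S <- as.matrix(Matrix::tcrossprod(W))
  norms <- sqrt(diag(S))
  undefined <- norms == 0
  denom <- outer(norms, norms)
  gamma <- ifelse(denom > 0, S / denom, 0)
  gamma <- pmin(gamma, 1)
  diag(gamma) <- ifelse(undefined, 0, 1)
  gamma <- (gamma + t(gamma)) / 2  # enforce exact symmetry
  structure(
    list(gamma = gamma, undefined = stats::setNames(undefined, rownames(gamma))),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d genes (%d with undefined profiles)\n",
              nrow(x$gamma), sum(x$undefined)))
  invisible(x)
}

#' Upper-triangle similarity values of defined gene pairs
#'
#' The multiset of pairwise similarities used for percentile-based cutoff
#' selection; pairs involving a gene with an all-zero profile are
#' excluded (their similarity is undefined, not small).
#'
#' @param sim a [similarity_matrix()].
#' @return numeric vector of gamma values, one per unordered defined pair.
#' @export
similarity_values <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  keep <- !sim$undefined
  g <- sim$gamma[keep, keep, drop = FALSE]
  g[upper.tri(g)]
}

#' Empirical percentiles of a similarity distribution
#'
#' Linear interpolation between order statistics (the default, type 7 in
#' [stats::quantile()]); the rule is configurable.
#'
#' @param values non-empty numeric vector of similarity values.
#' @param qs probabilities in \[0, 1\].
#' @param type interpolation rule passed to [stats::quantile()].
#' @return numeric vector of cutoffs, one per `qs`, non-decreasing in q.
#' @export
similarity_percentiles <- function(values, qs, type = 7) {
  if (length(values) == 0) stop_("`values` must be non-empty")
  if (any(qs < 0 | qs > 1)) stop_("`qs` must lie in [0, 1]")
  unname(stats::quantile(values, probs = qs, type = type, names = FALSE))
}

#' Co-occurrence-only baseline similarity
#'
#' Ignores GO terms entirely: two genes are similar to the extent that
#' they appear in the same abstracts. This is the cosine of the two
#' genes' 0/1 abstract-incidence vectors, n_ab / sqrt(n_a. * n_b.),
#' the baseline against which GO-guided inference is compared.
#'
#' @param counts a [tally_counts()] result (gene-gene joints included).
#' @return a [similarity_matrix()] over the tallied genes; genes with a
#'   zero margin are flagged undefined.
#' @export
cooccurrence_similarity <- function(counts) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  genes <- names(counts$n_gene)
  n <- length(genes)
  gamma <- matrix(0, n, n, dimnames = list(genes, genes))
  jg <- counts$joint_gene
  if (nrow(jg) > 0) {
    val <- jg$n / sqrt(counts$n_gene[jg$gene_a] * counts$n_gene[jg$gene_b])
    ia <- match(jg$gene_a, genes); ib <- match(jg$gene_b, genes)
    gamma[cbind(ia, ib)] <- val
    gamma[cbind(ib, ia)] <- val
  }
  undefined <- counts$n_gene == 0
  diag(gamma) <- ifelse(undefined, 0, 1)
  gamma <- pmin(gamma, 1)
  structure(
    list(gamma = gamma, undefined = stats::setNames(as.logical(undefined), genes)),
    class = "similarity_matrix"
  )
}

#' Probit transform of association p-values
#'
#' Maps p to the standard-normal quantile after clamping p into
#' \[1e-6, 1 - 1e-6\]; a missing p (no stored pair) is treated as 1 and
#' then clamped. Small p-values map to large negative values, making
#' p-value matrices normal-like and unbounded for downstream clustering.
#'
#' @param p numeric vector of p-values in (0, 1]; `NA` means missing.
#' @return transformed values in \[-4.7534, 4.7534\].
#' @examples
#' probit_transform(0.5) # 0
#' @export
probit_transform <- function(p) {
  if (is.logical(p) && all(is.na(p))) p <- as.numeric(p)
  if (!is.numeric(p)) stop_("`p` must be numeric")
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad)) stop_("`p` must lie in (0, 1] (or be NA for missing)")
  p[is.na(p)] <- 1
  stats::qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6))
}

#' Select GO terms with the smallest average p-values over a gene set
#'
#' For each GO term the p-values of the given genes are averaged with
#' missing entries counted as 1 (conservative); the `k` terms with the
#' smallest averages are returned, ties broken lexicographically by GO
#' id. Only GO terms with at least one stored pair among the given genes
#' are ranked; if `k` exceeds their number, all are returned with a
#' warning.
#'
#' @param pmat a [pvalue_matrix()].
#' @param genes non-empty character vector of gene ids.
#' @param k number of GO terms to return (>= 1).
#' @return character vector of GO ids, ordered by increasing average p.
#' @export
select_top_go <- function(pmat, genes, k) {
  if (length(genes) == 0) stop_("`genes` must be non-empty")
  if (!is_count(k) || k < 1) stop_("`k` must be a count >= 1")
  genes <- unique(genes)
  unknown <- setdiff(genes, pmat_genes(pmat))
  if (length(unknown) > 0) {
    stop_("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  m <- pmat_dense(pmat, genes = genes)
  stored <- colSums(!is.na(m)) > 0
  m[is.na(m)] <- 1
  avg <- colMeans(m)[stored]
  if (k > length(avg)) {
    warning(sprintf("k = %d exceeds the %d GO terms with stored pairs; returning all",
                    k, length(avg)))
    k <- length(avg)
  }
  ord <- order(avg, names(avg))
  names(avg)[ord][seq_len(k)]
}
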