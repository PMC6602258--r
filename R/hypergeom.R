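# Gene-GO association strength: upper-tail hypergeometric test with a
# mid-p continuity correction.
#
# Under the null that mentions of gene i and GO term j fall independently
# across the n_tot abstracts, the co-occurrence count X is hypergeometric
# with population n_tot, n_j "success" abstracts and n_i draws. The
# association p-value is P(X > n_ij) + 0.5 * P(X = n_ij): counting only
# half the mass of the observed outcome removes much of the conservatism
# of a discrete tail test. Evaluation goes through the survival function
# and log-space PMF, so it is stable for corpus sizes in the millions.

#' Mid-p hypergeometric association p-value
#'
#' @param n_ij observed co-occurrence count(s).
#' @param n_i abstracts mentioning the gene (draws).
#' @param n_j abstracts mentioning the GO term (successes in population).
#' @param n_tot abstracts mentioning at least one gene or GO term
#'   (population size).
#' @return p-value(s) in (0, 1): `P(X > n_ij) + 0.5 * P(X = n_ij)`.
#'   All arguments recycle to a common length.
#' @examples
#' hypergeom_midp(4, 4, 5, 10) # 1/84
#' hypergeom_midp(2, 4, 5, 10) # exactly 0.5
#' @export
hypergeom_midp <- function(n_ij, n_i, n_j, n_tot) {
  n <- max(length(n_ij), length(n_i), length(n_j), length(n_tot))
  n_ij <- rep_len(as.numeric(n_ij), n)
  n_i <- rep_len(as.numeric(n_i), n)
  n_j <- rep_len(as.numeric(n_j), n)
  n_tot <- rep_len(as.numeric(n_tot), n)

  chk <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0) || any(x != trunc(x))) {
      stop_("`", nm, "` must contain non-negative integers")
    }
  }
  chk(n_ij, "n_ij"); chk(n_i, "n_i"); chk(n_j, "n_j"); chk(n_tot, "n_tot")
  if (any(n_tot < 1)) stop_("`n_tot` must be >= 1")
  if (any(n_i > n_tot)) stop_("`n_i` exceeds `n_tot`")
  if (any(n_j > n_tot)) stop_("`n_j` exceeds `n_tot`")
  if (any(n_ij > pmin(n_i, n_j))) stop_("`n_ij` exceeds min(`n_i`, `n_j`)")

  stats::phyper(n_ij, m = n_j, n = n_tot - n_j, k = n_i, lower.tail = FALSE) +
    0.5 * stats::dhyper(n_ij, m = n_j, n = n_tot - n_j, k = n_i)
}

#' Build the sparse gene x GO p-value matrix
#'
#' Exactly the pairs with a positive joint count get an entry; a pair
#' absent from the matrix means no abstract mentions that gene and GO
#' term together (this is distinct from p = 1). Row and column index
#' sets are all genes / GO terms seen in the tally margins.
#'
#' @param counts a [tally_counts()] result.
#' @return an object of class `pvalue_matrix` wrapping a sparse matrix
#'   `p` (genes x GO terms; structural zero = no stored p-value).
#' @export
build_pvalue_matrix <- function(counts) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  genes <- names(counts$n_gene)
  gos <- names(counts$n_go)
  jt <- counts$joint
  if (nrow(jt) > 0 && any(jt$n < 1)) stop_("joint table stores a zero count")
  p <- if (nrow(jt) > 0) {
    hypergeom_midp(jt$n, counts$n_gene[jt$gene], counts$n_go[jt$go],
                   counts$n_total)
  } else {
    numeric(0)
  }
  # Extremely strong associations can underflow double precision to 0;
  # clamp so stored p-values stay strictly positive (the similarity floor
  # of 1e-6 makes the clamp value immaterial downstream).
  p <- pmax(p, 1e-300)
  mat <- Matrix::sparseMatrix(
    i = match(jt$gene, genes), j = match(jt$go, gos), x = p,
    dims = c(length(genes), length(gos)), dimnames = list(genes, gos)
  )
  pvalue_matrix(mat)
}

#' Construct a p-value matrix object from a sparse matrix
#'
#' @param p sparse numeric matrix (genes in rows, GO terms in columns)
#'   whose stored entries are p-values in (0, 1]; structural zeros mean
#'   "no stored p-value".
#' @return an object of class `pvalue_matrix`.
#' @export
pvalue_matrix <- function(p) {
  p <- methods::as(methods::as(p, "CsparseMatrix"), "generalMatrix")
  x <- p@x
  if (any(x <= 0 | x > 1)) stop_("stored p-values must lie in (0, 1]")
  if (is.null(rownames(p)) || is.null(colnames(p))) {
    stop_("p-value matrix needs gene rownames and GO colnames")
  }
  structure(list(p = p), class = "pvalue_matrix")
}

#' @export
print.pvalue_matrix <- function(x, ...) {
  cat(sprintf("<pvalue_matrix> %d genes x %d GO terms, %d stored p-values\n",
              nrow(x$p), ncol(x$p), length(x$p@x)))
  invisible(x)
}

#' Genes indexed by a p-value matrix
#' @param pmat a [pvalue_matrix()].
#' @return character vector of gene ids.
#' @export
pmat_genes <- function(pmat) rownames(pmat$p)

#' GO terms indexed by a p-value matrix
#' @param pmat a [pvalue_matrix()].
#' @return character vector of GO ids.
#' @export
pmat_gos <- function(pmat) colnames(pmat$p)

# Dense gene x GO matrix with NA for unstored pairs (internal).
pmat_dense <- function(pmat, genes = NULL, gos = NULL) {
  m <- as.matrix(pmat$p)
  m[m == 0] <- NA_real_
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(gos)) m <- m[, gos, drop = FALSE]
  m
}
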