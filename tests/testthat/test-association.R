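test_that("mid-p hypergeometric matches hand-derived rational values", {
  # upper tail empty; 0 + (1/2) * C(5,4)C(5,0)/C(10,4) = 1/84
  expect_equal(hypergeom_midp(4, 4, 5, 10), 1 / 84, tolerance = 1e-12)
  # (P(3) + P(4)) + P(2)/2 = 105/210 = 1/2 exactly
  expect_equal(hypergeom_midp(2, 4, 5, 10), 0.5)
  # degenerate draw: X = 0 surely, so 0 + 1/2
  expect_equal(hypergeom_midp(0, 0, 5, 10), 0.5)
})

test_that("mid-p rejects invalid margins by name", {
  expect_error(hypergeom_midp(3, 2, 5, 10), "n_ij")
  expect_error(hypergeom_midp(1, 11, 5, 10), "n_i")
  expect_error(hypergeom_midp(1, 2, 11, 10), "n_j")
  expect_error(hypergeom_midp(0, 0, 0, 0), "n_tot")
})

test_that("upper and lower mid-p are complementary on a small grid", {
  for (n_tot in c(1, 5, 12, 25)) {
    grid <- expand.grid(n_i = 0:n_tot, n_j = 0:n_tot)
    for (r in seq_len(nrow(grid))) {
      n_i <- grid$n_i[r]; n_j <- grid$n_j[r]
      k <- 0:min(n_i, n_j)
      upper <- hypergeom_midp(k, n_i, n_j, n_tot)
      lower <- stats::phyper(k - 1, n_j, n_tot - n_j, n_i) +
        0.5 * stats::dhyper(k, n_j, n_tot - n_j, n_i)
      expect_true(all(abs(upper + lower - 1) < 1e-12))
    }
  }
})

test_that("mid-p is strictly decreasing in the joint count", {
  for (margins in list(c(10, 8, 30), c(5, 5, 10), c(20, 15, 60))) {
    k <- 0:min(margins[1], margins[2])
    p <- hypergeom_midp(k, margins[1], margins[2], margins[3])
    expect_true(all(diff(p) < 0))
  }
})

test_that("p-value matrix stores exactly the co-mentioned pairs", {
  recs <- list(
    abstract_record("A1", genes = "g1", gos = "t1"),
    abstract_record("A2", genes = "g1"),
    abstract_record("A3", genes = "g2", gos = "t2")
  )
  pm <- build_pvalue_matrix(tally_counts(recs))
  expect_equal(length(pm$p@x), 2L)
  # g1-t2 never co-mentioned: absent, not p = 1
  expect_equal(pm$p["g1", "t2"], 0)
  expect_true(is.na(litgonet:::pmat_dense(pm)["g1", "t2"]))

  # a tally reproducing the (4, 4, 5, 10) margins yields that mid-p
  recs2 <- lapply(1:10, function(i) {
    abstract_record(sprintf("B%02d", i),
                    genes = if (i <= 4) "gA" else character(),
                    gos = if (i <= 4 || i == 5) "tA" else "tPad")
  })
  ct2 <- tally_counts(recs2)
  pm2 <- build_pvalue_matrix(ct2)
  expect_equal(ct2$n_total, 10)
  expect_equal(pm2$p["gA", "tA"], 1 / 84, tolerance = 1e-12)
})

test_that("weight profiles truncate at the floor and drop missing pairs", {
  pm <- make_pmat(gene = c("g1", "g1", "g2"), go = c("t1", "t2", "t1"),
                  p = c(1e-8, 1, 0.1))
  w <- weight_profile(pm, "g1")
  expect_equal(w[["t1"]], -log(1e-6))
  expect_false("t2" %in% names(w))  # p = 1 gives weight 0
  w2 <- weight_profile(pm, "g2")
  expect_equal(w2, c(t1 = -log(0.1)))
})

test_that("cosine similarity reproduces closed-form cases", {
  w <- c(t1 = 2, t2 = 3)
  expect_equal(cosine_similarity(w, w), 1)
  expect_equal(cosine_similarity(c(t1 = 2), c(t2 = 5)), 0)
  # -log 0.01 = 2 * (-log 0.1) in any base: cosine of (2b, b) vs (b, 2b) = 4/5
  a <- -log(c(t1 = 0.01, t2 = 0.1))
  b <- -log(c(t1 = 0.1, t2 = 0.01))
  expect_equal(cosine_similarity(a, b), 0.8, tolerance = 1e-12)
  # all-zero profile: undefined, reported as 0 with a flag
  u <- cosine_similarity(numeric(0), w)
  expect_equal(as.numeric(u), 0)
  expect_true(attr(u, "undefined"))
})

test_that("cosine similarity is scale-invariant and 1 iff proportional", {
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- stats::setNames(runif(6), sprintf("t%d", 1:6))
      b <- stats::setNames(runif(6), sprintf("t%d", 1:6))
      expect_equal(cosine_similarity(a, b), cosine_similarity(3.7 * a, 0.2 * b),
                   tolerance = 1e-12)
      expect_lt(cosine_similarity(a, b), 1)
      expect_equal(cosine_similarity(a, 2.5 * a), 1, tolerance = 1e-12)
    }
  })
})

test_that("similarity matrix assembles pairwise cosines with flags", {
  # g1/g2 realize the 0.8 closed form; g3 is orthogonal to both
  pm <- make_pmat(
    gene = c("g1", "g1", "g2", "g2", "g3"),
    go = c("t1", "t2", "t1", "t2", "t3"),
    p = c(0.01, 0.1, 0.1, 0.01, 0.5)
  )
  sm <- similarity_matrix(pm)
  expected <- matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3,
                     dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  expect_equal(sm$gamma, expected, tolerance = 1e-12)
  expect_false(any(sm$undefined))

  # identical profiles give off-diagonal 1
  pm2 <- make_pmat(gene = c("a", "b"), go = c("t1", "t1"), p = c(0.2, 0.2))
  expect_equal(similarity_matrix(pm2)$gamma["a", "b"], 1)

  # a gene with no stored pairs is flagged undefined with 0 similarities
  pm3 <- make_pmat(gene = "a", go = "t1", p = 0.2,
                   genes = c("a", "z"), gos = "t1")
  sm3 <- similarity_matrix(pm3)
  expect_true(sm3$undefined[["z"]])
  expect_equal(sm3$gamma["a", "z"], 0)
  expect_equal(sm3$gamma["z", "z"], 0)

  expect_error(similarity_matrix(pm3, genes = c("a", "nope")), "nope")
})

test_that("similarity is invariant to the logarithm base", {
  pm <- random_pmat(8, 12, seed = 3)
  e <- similarity_matrix(pm, log_base = exp(1))
  ten <- similarity_matrix(pm, log_base = 10)
  expect_equal(e$gamma, ten$gamma, tolerance = 1e-12)
  expect_identical(e$undefined, ten$undefined)
})

test_that("similarity percentiles follow linear order-statistic interpolation", {
  vals <- c(rep(0.1, 50), rep(0.9, 50))
  expect_equal(similarity_percentiles(vals, 0.5), 0.5)
  expect_equal(similarity_percentiles(rep(0.3, 20), c(0, 0.4, 1)), rep(0.3, 3))
  expect_equal(similarity_percentiles(c(0.2, 0.8, 0.5), 1), 0.8)
  qs <- seq(0, 1, by = 0.1)
  expect_true(!is.unsorted(similarity_percentiles(runif(100), qs)))
  expect_error(similarity_percentiles(numeric(0), 0.5), "non-empty")
})

test_that("co-occurrence baseline is the incidence-vector cosine", {
  recs <- c(
    lapply(1:2, function(i) abstract_record(paste0("J", i), genes = c("ga", "gb"))),
    lapply(1:2, function(i) abstract_record(paste0("K", i), genes = "ga")),
    lapply(1:7, function(i) abstract_record(paste0("L", i), genes = "gb")),
    list(abstract_record("M1", genes = "gc"))
  )
  ct <- tally_counts(recs)
  bs <- cooccurrence_similarity(ct)
  # n_ab = 2, n_a = 4, n_b = 9 -> 2/6
  expect_equal(bs$gamma["ga", "gb"], 2 / 6, tolerance = 1e-12)
  expect_equal(bs$gamma["ga", "gc"], 0)
  # identical incidence vectors -> 1
  recs2 <- lapply(1:5, function(i) abstract_record(paste0("N", i), genes = c("gx", "gy")))
  expect_equal(cooccurrence_similarity(tally_counts(recs2))$gamma["gx", "gy"], 1)
})

test_that("probit transform is clamped and treats missing as 1", {
  expect_equal(probit_transform(0.5), 0)
  # frozen from an independent high-precision normal quantile evaluation
  expect_equal(probit_transform(1e-9), -4.753424308822899, tolerance = 1e-9)
  expect_equal(probit_transform(NA), 4.753424308822899, tolerance = 1e-6)
  expect_equal(probit_transform(1e-6), probit_transform(1e-12))
  expect_error(probit_transform(0), "0, 1")
  expect_error(probit_transform(1.2), "0, 1")
})

test_that("top-GO selection averages with missing = 1 and ranks deterministically", {
  pm <- make_pmat(
    gene = c("g1", "g2", "g1", "g2", "g1"),
    go = c("tA", "tA", "tB", "tB", "tC"),
    p = c(0.1, 0.3, 0.5, 0.7, 0.01)
  )
  # tA avg 0.2, tB avg 0.6
  expect_equal(select_top_go(pm, c("g1", "g2"), 1), "tA")
  # tC: p(g1) = 0.01, g2 missing -> (0.01 + 1)/2 = 0.505
  expect_equal(select_top_go(pm, c("g1", "g2"), 3), c("tA", "tC", "tB"))
  # invariant to gene-set order
  expect_equal(select_top_go(pm, c("g2", "g1"), 3),
               select_top_go(pm, c("g1", "g2"), 3))
  expect_warning(out <- select_top_go(pm, "g1", 10), "exceeds")
  expect_equal(out, c("tC", "tA", "tB"))
  # ties break lexicographically by GO id
  pm2 <- make_pmat(gene = c("g", "g"), go = c("tZ", "tA"), p = c(0.2, 0.2))
  expect_equal(select_top_go(pm2, "g", 2), c("tA", "tZ"))
})
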