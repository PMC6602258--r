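test_that("network thresholding includes the boundary and keeps isolated nodes", {
  gamma <- matrix(c(1, 0.3, 0.6, 0.3, 1, 0.45, 0.6, 0.45, 1), 3,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sim <- make_sim(gamma)

  net <- build_network(sim, 0.45)
  ed <- network_edges(net)
  expect_equal(nrow(ed), 2)  # a-c at 0.6 and b-c exactly at the cutoff
  expect_true(any(ed$gene_a == "b" & ed$gene_b == "c" | ed$gene_a == "c" & ed$gene_b == "b"))

  expect_equal(igraph::ecount(build_network(sim, 0.61)$graph), 0)
  expect_equal(igraph::vcount(build_network(sim, 0.61)$graph), 3)
  expect_equal(igraph::ecount(build_network(sim, 0)$graph), 3)

  # undefined genes never contribute edges but stay as nodes
  sim2 <- make_sim(gamma, undefined = c(a = FALSE, b = FALSE, c = TRUE))
  net2 <- build_network(sim2, 0)
  expect_equal(igraph::vcount(net2$graph), 3)
  expect_equal(nrow(network_edges(net2)), 1)  # only a-b survives
})

test_that("raising the cutoff never adds an edge", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- 8
      g <- matrix(runif(n * n), n)
      g <- (g + t(g)) / 2
      diag(g) <- 1
      dimnames(g) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
      sim <- make_sim(g)
      cuts <- sort(runif(4))
      key <- function(net) {
        e <- network_edges(net)
        paste(e$gene_a, e$gene_b)
      }
      for (i in seq_along(cuts)[-1]) {
        lo <- key(build_network(sim, cuts[i - 1]))
        hi <- key(build_network(sim, cuts[i]))
        expect_true(all(hi %in% lo))
      }
    }
  })
})

test_that("label propagation recovers disjoint cliques exactly", {
  sim <- clique_sim(c(3, 3))
  for (seed in 1:20) {
    part <- label_propagation(build_network(sim, 0.5), seed = seed)
    expect_equal(length(unique(unclass(part))), 2)
    expect_equal(length(unique(unclass(part)[1:3])), 1)
    expect_equal(length(unique(unclass(part)[4:6])), 1)
  }
})

test_that("isolated nodes become singleton communities with dense labels", {
  sim <- make_sim(diag(1, 4, 4) |>
                    (\(m) {dimnames(m) <- list(letters[1:4], letters[1:4]); m})())
  part <- label_propagation(build_network(sim, 0.5), seed = 1)
  expect_equal(sort(unique(unclass(part))), 0:3)
  expect_equal(length(unique(unclass(part))), 4)
})

test_that("a single edge collapses to one community", {
  gamma <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (seed in 1:5) {
    part <- label_propagation(build_network(make_sim(gamma), 0.5), seed = seed)
    expect_equal(as.integer(part), c(0L, 0L))
  }
})

test_that("at termination every label is maximal among its neighbours", {
  sim <- clique_sim(c(4, 3, 2))
  net <- build_network(sim, 0.5)
  part <- label_propagation(net, seed = 9)
  labs <- unclass(part)
  for (v in names(labs)) {
    nb <- names(igraph::neighbors(net$graph, v))
    if (length(nb) == 0) next
    tab <- table(labs[nb])
    expect_equal(unname(tab[as.character(labs[[v]])]), max(tab),
                 ignore_attr = TRUE)
  }
  # independent cross-check: communities coincide with igraph's components
  comp <- igraph::components(net$graph)$membership
  expect_equal(length(unique(labs)), length(unique(comp)))
  expect_true(all(tapply(comp[names(labs)], labs, function(x) length(unique(x))) == 1))
})

test_that("label propagation never merges connected components", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      sizes <- sample(2:5, 3, replace = TRUE)
      sim <- clique_sim(sizes)
      net <- build_network(sim, 0.5)
      part <- label_propagation(net, seed = rep)
      comp <- igraph::components(net$graph)$membership
      cross <- tapply(comp[names(part)], unclass(part),
                      function(x) length(unique(x)))
      expect_true(all(cross == 1))
    }
  })
})

test_that("community enrichment averages with missing counted as one", {
  pm <- make_pmat(gene = c("g1", "g1", "g2"), go = c("tA", "tB", "tB"),
                  p = c(0.01, 0.2, 0.4))
  part <- structure(c(g1 = 0L, g2 = 0L), class = "community_partition",
                    seed = 1L, converged = TRUE)
  en <- community_enrichment(pm, part)
  # tA: (0.01 + 1)/2 = 0.505; tB: (0.2 + 0.4)/2 = 0.3
  expect_equal(en$mean_p[en$go_id == "tA"], 0.505)
  expect_equal(en$mean_p[en$go_id == "tB"], 0.3)
  expect_equal(en$go_id, c("tB", "tA"))  # ascending mean p within community

  # all-missing pair -> exactly 1
  pm2 <- make_pmat(gene = "g1", go = "tA", p = 0.2,
                   genes = c("g1", "g2"), gos = c("tA", "tB"))
  en2 <- community_enrichment(pm2, part, gos = "tB")
  expect_equal(en2$mean_p, 1)

  # singleton community: its own p values unchanged
  single <- structure(c(g1 = 0L), class = "community_partition",
                      seed = 1L, converged = TRUE)
  en3 <- community_enrichment(pm, single)
  expect_equal(en3$mean_p[en3$go_id == "tA"], 0.01)

  # equals an independent loop when every entry is present
  pm3 <- make_pmat(gene = rep(c("g1", "g2"), 2), go = rep(c("tA", "tB"), each = 2),
                   p = c(0.1, 0.3, 0.5, 0.9))
  en4 <- community_enrichment(pm3, part)
  dense <- litgonet:::pmat_dense(pm3)
  for (t in c("tA", "tB")) {
    expect_equal(en4$mean_p[en4$go_id == t], mean(dense[, t]))
  }
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.001, 100), 0.1)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0.37, 1), 0.37)
  expect_error(bonferroni(0.1, 0), "m")
})

test_that("gene, GO and gene-GO queries order deterministically", {
  pm <- make_pmat(gene = c("g1", "g1", "g2"), go = c("t1", "t2", "t1"),
                  p = c(0.01, 0.2, 0.3))
  gq <- gene_query(pm, "g1", m = 2)
  expect_equal(gq, data.frame(go_id = c("t1", "t2"), p = c(0.01, 0.2),
                              p_bonferroni = c(0.02, 0.4)))
  # default family size: all GO terms in the matrix
  expect_equal(gene_query(pm, "g1")$p_bonferroni, c(0.02, 0.4))

  tq <- go_query(pm, "t1", m = 2)
  expect_equal(tq$gene, c("g1", "g2"))
  expect_equal(tq$p_bonferroni, c(0.02, 0.6))

  # GO with no stored genes: legal empty table
  pm2 <- make_pmat(gene = "g1", go = "t1", p = 0.5, gos = c("t1", "tEmpty"))
  expect_equal(nrow(go_query(pm2, "tEmpty")), 0)

  gg <- gene_go_query(pm, c("g1", "g2"))
  expect_equal(gg$long$p, c(0.01, 0.2, 0.3))
  expect_true(is.na(gg$matrix["g2", "t2"]))
  # k restricts to the top-average GO terms
  gg1 <- gene_go_query(pm, c("g1", "g2"), k = 1)
  expect_equal(colnames(gg1$matrix), "t1")

  expect_error(gene_query(pm, "nope"), "nope")
  expect_error(gene_go_query(pm, c("g1", "bad1", "bad2")), "bad1.*bad2")
})

test_that("shared-GO comparison sorts by the smaller p-value", {
  pm <- make_pmat(
    gene = c("a", "a", "a", "b", "b", "b"),
    go = c("t1", "t2", "t3", "t2", "t3", "t4"),
    p = c(0.5, 0.01, 0.4, 0.6, 0.3, 0.2)
  )
  sg <- shared_go(pm, "a", "b")
  expect_equal(sg$go_id, c("t2", "t3"))
  expect_equal(sg$p_a, c(0.01, 0.4))
  expect_equal(shared_go(pm, "a", "b", top_n = 1)$go_id, "t2")

  pm2 <- make_pmat(gene = c("a", "b"), go = c("t1", "t2"), p = c(0.1, 0.2))
  expect_equal(nrow(shared_go(pm2, "a", "b")), 0)
})

test_that("force-directed layout is seeded and spreads with the spacing parameter", {
  sim <- clique_sim(c(3, 2))
  net <- build_network(sim, 0.5)
  l1 <- fr_layout(net, layout_config(seed = 4))
  l2 <- fr_layout(net, layout_config(seed = 4))
  expect_identical(l1, l2)
  expect_true(all(is.finite(l1)))
  expect_equal(rownames(l1), sprintf("g%02d", 1:5))

  single <- build_network(make_sim(matrix(1, 1, 1, dimnames = list("a", "a"))), 0.5)
  expect_equal(dim(fr_layout(single, layout_config(seed = 1))), c(1, 2))

  # doubling k increases mean pairwise distance for most seeds
  withr::with_seed(77, {
    n <- 20
    g <- matrix(runif(n * n) < 0.15, n)
    g <- g | t(g)
    gamma <- ifelse(g, 0.9, 0)
    diag(gamma) <- 1
    dimnames(gamma) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  })
  rnet <- build_network(make_sim(gamma), 0.5)
  wins <- 0
  for (seed in 1:50) {
    d1 <- mean(dist(fr_layout(rnet, layout_config(k = 0.2, seed = seed))))
    d2 <- mean(dist(fr_layout(rnet, layout_config(k = 0.4, seed = seed))))
    wins <- wins + (d2 > d1)
  }
  expect_gte(wins, 40)
})
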