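# star with a pendant path hanging off one leaf, plus an isolated node
star_net <- function() {
  center <- "hub"
  leaves <- sprintf("leaf%02d", 1:12)
  path <- sprintf("path%02d", 1:6)
  e <- rbind(
    data.frame(gene_a = pmin(center, leaves), gene_b = pmax(center, leaves),
               weight = seq(0.99, 0.8, length.out = 12)),
    data.frame(gene_a = pmin(leaves[1], path[1]),
               gene_b = pmax(leaves[1], path[1]), weight = 0.7),
    data.frame(gene_a = pmin(path[-6], path[-1]),
               gene_b = pmax(path[-6], path[-1]), weight = 0.6))
  e$rho <- e$weight
  build_pmfg(e, nodes = c(center, leaves, path, "lonely"))
}

test_that("neighborhood matches breadth-first search and is monotone in h", {
  net <- star_net()
  expect_identical(neighborhood(net, "lonely", h = 1), character(0))
  expect_identical(neighborhood(net, "hub", h = 1),
                   sort(sprintf("leaf%02d", 1:12)))
  expect_message(res <- neighborhood(net, "absent"), "not in network")
  expect_null(res)

  ## h = 2 equals an independent BFS enumeration on a random PMFG
  set.seed(3)
  genes <- sprintf("n%02d", 1:25)
  rnet <- build_pmfg(complete_candidates(genes, runif(choose(25, 2))))
  adj <- lapply(setNames(genes, genes), function(g)
    c(rnet$edges$gene_b[rnet$edges$gene_a == g],
      rnet$edges$gene_a[rnet$edges$gene_b == g]))
  bfs2 <- function(g) {
    l1 <- unique(adj[[g]])
    sort(setdiff(unique(c(l1, unlist(adj[l1]))), g))
  }
  for (g in genes[c(1, 7, 20)]) {
    expect_identical(neighborhood(rnet, g, h = 2), bfs2(g))
    expect_true(all(neighborhood(rnet, g, h = 1) %in%
                      neighborhood(rnet, g, h = 2)))
  }
})

test_that("driver scoring flags enriched neighborhoods and only those", {
  net <- star_net()
  up <- sprintf("leaf%02d", 1:12)          # exactly the hub's neighborhood
  down <- "lonely"                         # in nobody's neighborhood
  rec <- score_drivers(net, up, down, h = 1, min_neighbors = 3)
  hub_row <- rec[rec$gene_id == "hub", ]
  expect_lt(hub_row$fdr_up, 0.05)
  expect_true(hub_row$is_driver)
  ## a signature disjoint from every neighborhood scores p = 1 throughout
  expect_true(all(rec$p_down == 1))
  ## the isolated node is never tested
  expect_false("lonely" %in% rec$gene_id)
  expect_false(any(rec$p_up > 1 | rec$p_up <= 0))
  expect_true(all(rec$n_neighbors >= 3))
})

test_that("pan-cancer ranking is totally ordered and order-invariant", {
  mk <- function(genes, drv, hub, fup) {
    data.frame(gene_id = genes, n_neighbors = 10, p_up = fup, p_down = 1,
               fdr_up = fup, fdr_down = 1, is_hub = hub, is_driver = drv,
               stringsAsFactors = FALSE)
  }
  recs <- list(
    A = mk(c("g1", "g2", "g3"), c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
           c(0.001, 0.01, 0.5)),
    B = mk(c("g1", "g2", "g3"), c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
           c(0.002, 0.01, 0.01)),
    C = mk(c("g1", "g2", "g3"), c(TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE),
           c(0.003, 0.2, 0.9)))
  rk <- rank_pan_cancer(recs)
  ## driver in 3/3 cohorts outranks drivers in 2/3 and 1/3
  expect_identical(rk$gene_id, c("g1", "g2", "g3"))
  expect_identical(rk$n_cohorts_driver, c(3L, 2L, 1L))
  expect_identical(rk$rank, 1:3)
  ## invariant to cohort input order
  rk2 <- rank_pan_cancer(recs[c("C", "A", "B")])
  expect_identical(rk, rk2)
  ## full tie on counts and fdr falls back to gene id: total order
  recs_tie <- list(A = mk(c("ga", "gb"), c(TRUE, TRUE), c(FALSE, FALSE),
                          c(0.01, 0.01)),
                   B = mk(c("ga", "gb"), c(TRUE, TRUE), c(FALSE, FALSE),
                          c(0.01, 0.01)))
  rk3 <- rank_pan_cancer(recs_tie)
  expect_identical(rk3$gene_id, c("ga", "gb"))
})
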