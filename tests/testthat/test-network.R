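test_that("PMFG reproduces small planar graphs and the Euler bound", {
  ## K4 is planar: all 6 candidate edges accepted
  set.seed(1)
  e4 <- complete_candidates(sprintf("n%d", 1:4), runif(6, 0.1, 0.9))
  net4 <- build_pmfg(e4)
  expect_identical(nrow(net4$edges), 6L)
  expect_true(net4$embedding_certified)

  ## K5 is not: exactly 3(5-2) = 9 of 10 edges survive
  e5 <- complete_candidates(sprintf("n%d", 1:5), runif(10, 0.1, 0.9))
  net5 <- build_pmfg(e5)
  expect_identical(nrow(net5$edges), 9L)

  ## complete candidates at n = 10: bound attained, certified planar
  e10 <- complete_candidates(sprintf("n%02d", 1:10), runif(45, 0.1, 0.9))
  net10 <- build_pmfg(e10)
  expect_identical(nrow(net10$edges), 3L * 8L)
  expect_true(net10$embedding_certified)

  ## fewer than 3 nodes: complete graph
  e2 <- data.frame(gene_a = "a", gene_b = "b", rho = 0.5, weight = 0.5)
  expect_identical(nrow(build_pmfg(e2)$edges), 1L)
})

test_that("PMFG edge set matches the independently coded networkx oracle", {
  set.seed(23)
  genes <- sprintf("n%02d", 1:30)
  e <- complete_candidates(genes, runif(choose(30, 2), 0.01, 0.99))
  net <- build_pmfg(e)
  srt <- panpronet:::sort_candidates(e)
  keep_oracle <- nx_greedy_pmfg(30, match(srt$gene_a, genes) - 1L,
                                match(srt$gene_b, genes) - 1L)
  oracle_edges <- srt[keep_oracle, c("gene_a", "gene_b")]
  got <- net$edges[order(net$edges$gene_a, net$edges$gene_b), 1:2]
  want <- oracle_edges[order(oracle_edges$gene_a, oracle_edges$gene_b), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("PMFG output is invariant to candidate row order", {
  set.seed(5)
  e <- complete_candidates(sprintf("n%02d", 1:12), runif(66, 0.1, 0.9))
  net1 <- build_pmfg(e)
  net2 <- build_pmfg(e[sample(nrow(e)), ])
  expect_identical(net1$edges, net2$edges)
})

test_that("correlation screen keeps real structure and rejects noise", {
  set.seed(31)
  meta_n <- 30
  ## duplicated gene row: rho = 1, survives any screen
  x <- matrix(rnorm(40 * meta_n), 40, meta_n,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("s%02d", 1:meta_n)))
  x["g02", ] <- x["g01", ]
  ## constant row is dropped with a record
  x["g03", ] <- 7
  edges <- correlation_screen(x, n_perm = 30, fdr_cut = 0.05, seed = 1)
  expect_identical(attr(edges, "dropped_genes"), "g03")
  top <- edges[1, ]
  expect_identical(c(top$gene_a, top$gene_b), c("g01", "g02"))
  expect_equal(top$weight, 1)

  ## independent Gaussian matrix: retained fraction stays within the cutoff
  y <- matrix(rnorm(50 * meta_n), 50, meta_n,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%02d", 1:meta_n)))
  null_edges <- correlation_screen(y, n_perm = 30, fdr_cut = 0.05, seed = 2)
  expect_lte(nrow(null_edges) / choose(50, 2), 0.05 + 0.01)

  ## near-zero-noise planted module: every within-module pair retained
  specs <- list(cohort_spec("C1", 20, 3, noise_sd = 1e-6))
  plan <- plan_modules(40, 10, list("C1"), "C1")
  panel <- generate_cohort_panel(specs, 40, plan, seed = 3, n_extra_dep = 0)
  mem <- sort(plan[[1]]$member_genes)
  ed <- correlation_screen(tumor_matrix(panel, "C1"), 30, 0.05, 4)
  within <- ed[ed$gene_a %in% mem & ed$gene_b %in% mem, ]
  expect_identical(nrow(within), 45L)
})

test_that("two planted cliques split into exactly the planted modules at alpha 1", {
  for (s in 1:2) {
    net <- build_pmfg(two_clique_candidates(s))
    hier <- multiscale_cluster(net, min_size = 10, n_perm = 100, seed = s)
    mods <- modules_at(hier, alpha = 1)
    expect_identical(length(mods), 2L)
    sets <- lapply(mods, sort)
    expect_setequal(vapply(sets, paste, character(1), collapse = ","),
                    c(paste(sprintf("A%02d", 1:20), collapse = ","),
                      paste(sprintf("B%02d", 1:20), collapse = ",")))
  }
})

test_that("hierarchy satisfies the tree contracts and alpha monotonicity", {
  panel <- small_panel(seed = 6)
  net <- build_pmfg(correlation_screen(tumor_matrix(panel, "C1"),
                                       30, 0.05, 6))
  hier <- multiscale_cluster(net, min_size = 10, n_perm = 50, seed = 6)
  ids <- vapply(hier$modules, `[[`, character(1), "id")
  for (m in hier$modules) {
    if (m$id != "M1") expect_gte(length(m$members), 10)
    if (!is.na(m$parent)) {
      parent <- hier$modules[[match(m$parent, ids)]]
      expect_true(all(m$members %in% parent$members))
    }
  }
  ## siblings are disjoint
  parents <- vapply(hier$modules, `[[`, character(1), "parent")
  for (pid in unique(parents[!is.na(parents)])) {
    sibs <- hier$modules[which(parents == pid)]
    all_members <- unlist(lapply(sibs, `[[`, "members"))
    expect_false(anyDuplicated(all_members) > 0)
  }
  ## raising alpha never yields more modules
  n_by_alpha <- vapply(c(0.5, 1, 2), function(a)
    length(modules_at(hier, a)), integer(1))
  expect_true(all(diff(n_by_alpha) <= 0))
})

test_that("hub calls respond to degree extremes", {
  ## star: center is a hub, leaves are not
  genes <- sprintf("n%02d", 0:29)
  star <- data.frame(gene_a = pmin(genes[1], genes[-1]),
                     gene_b = pmax(genes[1], genes[-1]),
                     rho = seq(0.9, 0.6, length.out = 29))
  star$weight <- star$rho
  net <- build_pmfg(star)
  hubs <- call_hubs(net, n_perm = 50, seed = 1)
  expect_true(hubs$is_hub[hubs$gene_id == "n00"])
  expect_false(any(hubs$is_hub[hubs$gene_id != "n00"]))

  ## regular ring: all degrees equal, no hubs
  ring <- data.frame(gene_a = genes, gene_b = genes[c(2:30, 1)],
                     rho = seq(0.9, 0.6, length.out = 30))
  swap <- ring$gene_a > ring$gene_b
  tmp <- ring$gene_a[swap]
  ring$gene_a[swap] <- ring$gene_b[swap]; ring$gene_b[swap] <- tmp
  ring$weight <- ring$rho
  rnet <- build_pmfg(ring)
  rhubs <- call_hubs(rnet, n_perm = 50, seed = 2)
  expect_false(any(rhubs$is_hub))
})
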