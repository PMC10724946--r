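fake_pres <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(cohort = r[1], module_id = r[2], target = r[3],
               best_match = r[4], klass = r[5], stringsAsFactors = FALSE)
  }))
  df$overlap <- 10L; df$fold <- 3; df$p <- 1e-6; df$fdr <- 1e-5
  df
}

test_that("overlap graph links only strong cross-cohort pairs", {
  pres <- fake_pres(list(
    c("C1", "m1", "C2", "a", "strong"),
    c("C1", "m1", "C3", "x", "weak"),
    c("C2", "a", "C1", "m1", "strong"),
    c("C2", "b", "C3", "x", "none"),
    c("C1", "m2", "C1_rna", "r1", "strong")))  # rna target ignored
  g <- build_overlap_graph(pres)
  el <- igraph::as_edgelist(g)
  expect_identical(nrow(el), 1L)
  expect_setequal(as.vector(el), c("C1::m1", "C2::a"))
  ## never an edge within the same cohort
  coh <- sub("::.*$", "", el)
  expect_false(any(coh[, 1] == coh[, 2]))

  ## no strong calls at all: edgeless graph
  pres0 <- fake_pres(list(c("C1", "m1", "C2", "a", "weak")))
  expect_identical(as.integer(igraph::ecount(build_overlap_graph(pres0))), 0L)
})

test_that("communities require the cohort span and never merge disjoint seeds", {
  pres <- fake_pres(list(
    c("C1", "m1", "C2", "a", "strong"),
    c("C2", "a", "C3", "x", "strong"),
    c("C4", "q", "C5", "r", "strong")))
  g <- build_overlap_graph(pres)
  ## span_min larger than any component's span: everything discarded
  out7 <- detect_communities(g, span_min = 7)
  expect_identical(length(out7), 0L)
  expect_identical(attr(out7, "discarded"), 2L)
  ## two disjoint seeds remain two communities
  out2 <- detect_communities(g, span_min = 2)
  expect_identical(length(out2), 2L)
  spans <- vapply(out2, function(p) length(p$cohorts_spanned), integer(1))
  expect_setequal(spans, c(3L, 2L))
  ## every module belongs to at most one community
  all_members <- unlist(lapply(out2, function(p)
    paste(p$members$cohort, p$members$module_id)))
  expect_false(anyDuplicated(all_members) > 0)
  expect_error(detect_communities(g, span_min = 1))
})

test_that("core extraction counts distinct cohorts and is monotone", {
  skel <- list(community_id = "PCPIC1",
               members = data.frame(
                 cohort = c("C1", "C2", "C3"),
                 module_id = c("m1", "m2", "m3"),
                 stringsAsFactors = FALSE),
               cohorts_spanned = c("C1", "C2", "C3"))
  sets <- list(C1 = list(m1 = c("g1", "g2", "g3")),
               C2 = list(m2 = c("g1", "g2", "g4")),
               C3 = list(m3 = c("g1", "g5")))
  expect_identical(extract_core(skel, sets, core_min = 1),
                   sort(c("g1", "g2", "g3", "g4", "g5")))
  expect_identical(extract_core(skel, sets, core_min = 2), c("g1", "g2"))
  expect_identical(extract_core(skel, sets, core_min = 3), "g1")
  ## default core_min is the majority of spanned cohorts
  expect_identical(extract_core(skel, sets), c("g1", "g2"))
  ## raising core_min never grows the core
  cores <- lapply(1:3, function(k) extract_core(skel, sets, core_min = k))
  for (k in 2:3) expect_true(all(cores[[k]] %in% cores[[k - 1]]))
  expect_error(extract_core(skel, sets, core_min = 4))
})

test_that("summaries track the latent factor and recover edge signs", {
  set.seed(41)
  n <- 40
  f <- rnorm(n)
  samples <- sprintf("s%02d", 1:n)
  make_prot <- function(fa, fb) {
    x <- matrix(rnorm(30 * n, sd = 0.2), 30, n,
                dimnames = list(sprintf("g%02d", 1:30), samples))
    for (i in 1:10) x[i, ] <- fa + rnorm(n, sd = 0.05)
    for (i in 11:20) x[i, ] <- fb + rnorm(n, sd = 0.05)
    x
  }
  pcpics <- list(
    list(community_id = "PCPIC1", cohorts_spanned = c("C1", "C2"),
         core = sprintf("g%02d", 1:10)),
    list(community_id = "PCPIC2", cohorts_spanned = c("C1", "C2"),
         core = sprintf("g%02d", 11:20)))
  ## anti-correlated factors: negative edge
  g <- rnorm(n)
  fb <- -0.8 * scale(f)[, 1] + sqrt(1 - 0.64) * g
  f2 <- rnorm(n)
  prots <- list(C1 = make_prot(f, fb),
                C2 = make_prot(f2, -0.8 * f2 + 0.6 * rnorm(n)))
  res <- summarize_and_correlate(pcpics, prots, p_edge = 0.05)
  ## degenerate core: summary correlates ~1 with each core gene row
  s1 <- res$pcpics[[1]]$summary_expression$C1
  for (i in 1:3)
    expect_gt(cor(s1, prots$C1[i, ]), 0.95)
  expect_identical(nrow(res$network), 1L)
  expect_identical(res$network$sign, "-")
  expect_lt(res$network$rho, 0)

  ## flipping the second factor's sign flips the recovered edge sign
  prots_flip <- list(C1 = make_prot(f, -fb),
                     C2 = make_prot(f2, 0.8 * f2 + 0.6 * rnorm(n)))
  res2 <- summarize_and_correlate(pcpics, prots_flip, p_edge = 0.05)
  expect_identical(res2$network$sign, "+")

  ## a core planted inside the up signature is detected as enriched
  sigs <- list(C1_up = sprintf("g%02d", 1:12), C1_down = sprintf("g%02d", 25:30),
               C2_up = character(0), C2_down = character(0))
  res3 <- summarize_and_correlate(pcpics, prots, signatures = sigs)
  enr <- res3$pcpics[[1]]$dep_enrichment$C1
  expect_lt(enr$up$p, 0.05)
  expect_gt(enr$down$p, 0.05)
})
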