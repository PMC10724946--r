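make_meta <- function(n_tumor, n_normal, cid = "C1") {
  data.frame(
    sample_id = c(sprintf("%s_T%02d", cid, seq_len(n_tumor)),
                  sprintf("%s_N%02d", cid, seq_len(n_normal))),
    cohort = cid,
    condition = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
    stringsAsFactors = FALSE)
}

test_that("call_deps handles null, degenerate and no-normal inputs", {
  meta <- make_meta(5, 5)
  x <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), meta$sample_id))
  x[3, ] <- rep(c(1, 2, 3, 4, 1), 2)  # identical tumor/normal values
  tab <- call_deps(x, meta)
  expect_identical(tab$statistic[3], 0)
  expect_identical(tab$p[3], 1)
  expect_identical(as.character(tab$direction[3]), "ns")

  ## no normal samples: explicit no-DEP result, not an exception
  xm <- x[, meta$condition == "tumor"]
  tabn <- call_deps(xm, meta[meta$condition == "tumor", ])
  expect_true(attr(tabn, "no_dep"))
  expect_true(all(tabn$direction == "ns"))

  ## genes with < 3 finite values in a group are dropped and recorded
  x[2, 1:4] <- NA
  tab2 <- call_deps(x, meta)
  expect_identical(attr(tab2, "dropped_genes"), "g2")
  expect_true(is.na(tab2$fdr[2]))
})

test_that("call_deps matches t.test and p.adjust gene by gene", {
  set.seed(42)
  meta <- make_meta(12, 10)
  x <- matrix(rnorm(40 * 22), 40, 22,
              dimnames = list(sprintf("g%02d", 1:40), meta$sample_id))
  x[1:5, 1:12] <- x[1:5, 1:12] + 2.5
  tab <- call_deps(x, meta)
  for (i in c(1, 3, 17, 40)) {
    tt <- t.test(x[i, 1:12], x[i, 13:22])
    expect_equal(tab$statistic[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(tab$log2fc[i],
                 unname(tt$estimate[1] - tt$estimate[2]), tolerance = 1e-12)
  }
  expect_equal(tab$fdr, p.adjust(tab$p, "BH"), tolerance = 1e-15)
  ## planted shifts at this n are called with the right sign
  expect_true(all(tab$direction[1:5] == "up"))
  expect_true(all(tab$direction[6:40] != "down"))
})

test_that("BH adjustment agrees with a brute-force implementation", {
  set.seed(9)
  for (n in c(7, 40, 100)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("proteome_specific applies the two-layer FDR rule per direction", {
  dep <- function(genes, fdr, lfc) {
    data.frame(gene_id = genes, log2fc = lfc, statistic = lfc, p = fdr,
               fdr = fdr, direction = "ns", stringsAsFactors = FALSE)
  }
  prot <- dep(c("a", "b", "c", "d"), c(0.01, 0.01, 0.5, 0.01),
              c(2, 2, 2, -2))
  rna <- dep(c("a", "b", "c", "d"), c(0.5, 0.01, 0.01, 0.9),
             c(2, 2, 2, -2))
  res <- proteome_specific(prot, rna)
  expect_identical(res$up, "a")      # protein hit, mRNA quiet
  expect_false("b" %in% res$up)      # significant on both layers
  expect_identical(res$down, "d")
  expect_identical(attr(res, "universe_size"), 4L)
  expect_error(proteome_specific(prot, dep("z", 0.5, 1)), "universe")
})

test_that("planted proteome-specific genes are recovered accurately", {
  specs <- list(cohort_spec("C1", 50, 50))
  panel <- generate_cohort_panel(specs, 300, list(), dep_effect = 2,
                                 frac_proteome_specific = 0.3, seed = 11,
                                 n_extra_dep = 150)
  meta <- panel$metadata
  dp <- call_deps(panel$proteome$C1, meta)
  dr <- call_deps(panel$transcriptome$C1, meta)
  res <- proteome_specific(dp, dr)
  found <- union(res$up, res$down)
  planted <- panel$truth$proteome_specific_genes$C1
  recall <- length(intersect(found, planted)) / length(planted)
  precision <- length(intersect(found, planted)) / length(found)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.8)
})

test_that("multiset intersection test is exact, symmetric and bounded", {
  ## expected overlap: n * prod(n_i / n)
  sets <- list(letters[1:13], letters[7:19], letters[c(1:5, 10:17)])
  universe <- c(letters, LETTERS)[1:40]
  r <- multiset_intersection_test(sets, 40)
  expect_equal(r$expected_overlap, 40 * prod(lengths(sets) / 40))
  expect_identical(r$observed_overlap,
                   length(Reduce(intersect, sets)))
  ## permutation invariance
  r2 <- multiset_intersection_test(rev(sets), 40)
  expect_equal(r2$p, r$p, tolerance = 1e-14)
  expect_true(r$p > 0 && r$p <= 1)

  ## m = 2 reduces to the one-sided hypergeometric tail
  a <- letters[1:10]; b <- letters[6:14]
  r3 <- multiset_intersection_test(list(a, b), 26)
  ph <- phyper(length(intersect(a, b)) - 1, 10, 16, 9, lower.tail = FALSE)
  expect_equal(r3$p, ph, tolerance = 1e-10)

  ## empty observed intersection gives p = 1
  r4 <- multiset_intersection_test(list(letters[1:3], letters[4:6]), 26)
  expect_identical(r4$observed_overlap, 0L)
  expect_equal(r4$p, 1)

  expect_error(multiset_intersection_test(list(letters, letters[1:5]), 10),
               "larger than the universe")
  expect_error(multiset_intersection_test(list(letters[1:3]), 26))
})

test_that("multiset expected overlap matches direct Monte-Carlo sampling", {
  set.seed(21)
  draws <- panpronet:::.rmultiset_overlap(30L, c(12L, 15L, 9L), 20000L)
  exp_mc <- mean(draws)
  se <- sd(draws) / sqrt(length(draws))
  r <- multiset_intersection_test(
    list(sprintf("g%02d", 1:12), sprintf("g%02d", 1:15),
         sprintf("g%02d", 1:9)), 30)
  expect_lt(abs(r$expected_overlap - exp_mc), 3 * se)
})

test_that("recurrent proteome-specific DEPs are counted and ranked", {
  universe <- sprintf("g%02d", 1:40)
  sets <- list(C1 = c("g01", "g02", "g03"),
               C2 = c("g01", "g02", "g10"),
               C3 = c("g01", "g02"),
               C4 = c("g01", "g11"),
               C5 = c("g12"), C6 = character(0), C7 = c("g01"))
  res <- recurrent_specific_deps(sets, universe, min_cohorts = 3)
  expect_identical(res$gene_id, c("g01", "g02"))
  expect_identical(res$recurrence, c(5L, 3L))
  expect_true(all(res$p >= 0 & res$p <= 1))
  ## gene in exactly 3 of 7 sets retained with recurrence 3
  expect_identical(res$recurrence[res$gene_id == "g02"], 3L)
  ## min_cohorts above the number of cohorts: empty result, no error
  res8 <- recurrent_specific_deps(sets, universe, min_cohorts = 8)
  expect_identical(nrow(res8), 0L)
})
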