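# Shared synthetic fixtures, built in code at test time.

seven_cohorts <- sprintf("C%d", 1:7)

# study-scale reference panel: one pan-cohort module of 40, a second
# pan-cohort module of 30 anti-correlated with the first, and one
# cohort-specific module of 30
reference_plan <- function(n_genes = 500, cohorts = seven_cohorts) {
  plan_modules(n_genes, sizes = c(40, 30, 30),
               cohorts = list(cohorts, cohorts, cohorts[1]),
               all_cohorts = cohorts,
               couple_to = list(NULL, "PM01", NULL),
               couple_rho = list(NULL, -0.4, NULL))
}

reference_panel <- function(seed = 1, cohorts = seven_cohorts,
                            n_genes = 500) {
  specs <- lapply(cohorts, cohort_spec, n_tumor = 30, n_normal = 15)
  generate_cohort_panel(specs, n_genes, reference_plan(n_genes, cohorts),
                        seed = seed)
}

# small panel for fast unit tests
small_panel <- function(seed = 1, cohorts = sprintf("C%d", 1:3),
                        n_genes = 150, sizes = c(25, 15),
                        module_cohorts = list(cohorts, cohorts[1]), ...) {
  specs <- lapply(cohorts, cohort_spec, n_tumor = 25, n_normal = 10)
  plan <- plan_modules(n_genes, sizes = sizes, cohorts = module_cohorts,
                       all_cohorts = cohorts)
  generate_cohort_panel(specs, n_genes, plan, seed = seed,
                        n_extra_dep = 20, ...)
}

# tumor-only expression for one cohort of a panel
tumor_matrix <- function(panel, cid) {
  m <- panel$metadata
  panel$proteome[[cid]][, m$sample_id[m$cohort == cid &
                                        m$condition == "tumor"]]
}

# complete candidate edge list between named nodes with given weights
complete_candidates <- function(genes, weights) {
  pr <- t(combn(genes, 2))
  data.frame(gene_a = pr[, 1], gene_b = pr[, 2], rho = weights,
             weight = abs(weights), stringsAsFactors = FALSE)
}

# two cliques with strong internal weights joined by one weak edge
two_clique_candidates <- function(seed) {
  set.seed(seed)
  g1 <- sprintf("A%02d", 1:20)
  g2 <- sprintf("B%02d", 1:20)
  clique <- function(genes) {
    pr <- t(combn(genes, 2))
    data.frame(gene_a = pr[, 1], gene_b = pr[, 2],
               rho = runif(nrow(pr), 0.8, 0.9), stringsAsFactors = FALSE)
  }
  e <- rbind(clique(g1), clique(g2),
             data.frame(gene_a = "A01", gene_b = "B01", rho = 0.2))
  e$weight <- abs(e$rho)
  e
}

# per-cohort ground-truth labels over the full gene universe: modules
# carried by the cohort, everything else background
planted_labels <- function(plan, n_genes, cid) {
  lab <- setNames(rep("bg", n_genes), sprintf("G%04d", seq_len(n_genes)))
  for (m in plan) if (cid %in% m$cohorts) lab[m$member_genes] <- m$module_id
  lab
}

# detected labels at a resolution over the full gene universe
detected_labels <- function(module_sets, n_genes) {
  lab <- setNames(rep("bg", n_genes), sprintf("G%04d", seq_len(n_genes)))
  for (m in names(module_sets)) lab[module_sets[[m]]] <- m
  lab
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# memoised full pipeline run on the reference panel (shared by the
# preservation / community acceptance checks)
.ref_cache <- new.env(parent = emptyenv())
reference_run <- function() {
  if (is.null(.ref_cache$res)) {
    panel <- reference_panel(seed = 1)
    out <- file.path(tempdir(), "panpronet-reference-run")
    .ref_cache$panel <- panel
    .ref_cache$res <- run_pipeline(
      panel, run_config(seed = 1, include_rna = FALSE), out)
  }
  list(panel = .ref_cache$panel, res = .ref_cache$res)
}
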