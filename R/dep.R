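#' Call differentially expressed proteins for one cohort
#'
#' Per-gene Welch two-sample t-test of tumor versus normal samples on
#' log-scale values. The effect size is the tumor minus normal mean
#' difference (log2 fold change for log2 data); p-values are adjusted by
#' Benjamini-Hochberg across all tested genes. Genes with fewer than 3
#' finite values in either group are dropped and recorded in the
#' `dropped_genes` attribute. A cohort without normal samples yields an
#' explicit no-DEP table (all directions `ns`, `no_dep` attribute set)
#' rather than an error.
#'
#' @param expr genes x samples numeric matrix (log scale).
#' @param metadata data.frame with `sample_id` and `condition`
#'   (`tumor`/`normal`) covering the columns of `expr`.
#' @param q_dep FDR threshold used to assign the `up`/`down` direction.
#' @return a `dep_table` data.frame: `gene_id`, `log2fc`, `statistic`, `p`,
#'   `fdr`, `direction`.
#' @export
call_deps <- function(expr, metadata, q_dep = 0.05) {
  check_expression_matrix(expr)
  stopifnot(all(c("sample_id", "condition") %in% names(metadata)))
  meta <- metadata[match(colnames(expr), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing some samples of expr")
  tumor <- expr[, meta$condition == "tumor", drop = FALSE]
  normal <- expr[, meta$condition == "normal", drop = FALSE]

  empty_direction <- factor(rep("ns", nrow(expr)),
                            levels = c("up", "down", "ns"))
  if (ncol(normal) == 0) {
    out <- data.frame(gene_id = rownames(expr), log2fc = NA_real_,
                      statistic = NA_real_, p = NA_real_, fdr = NA_real_,
                      direction = empty_direction, stringsAsFactors = FALSE)
    attr(out, "no_dep") <- TRUE
    class(out) <- c("dep_table", class(out))
    return(out)
  }
  if (ncol(tumor) < 3 || ncol(normal) < 3)
    stop("need at least 3 tumor and 3 normal samples")

  n1 <- rowSums(is.finite(tumor))
  n2 <- rowSums(is.finite(normal))
  tested <- n1 >= 3 & n2 >= 3
  t1 <- tumor; t1[!is.finite(t1)] <- NA
  t2 <- normal; t2[!is.finite(t2)] <- NA
  m1 <- rowMeans(t1, na.rm = TRUE)
  m2 <- rowMeans(t2, na.rm = TRUE)
  v1 <- rowSums((t1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((t2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  stat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) +
                   (v2 / n2)^2 / pmax(n2 - 1, 1))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  ## degenerate rows: zero variance in both groups
  zero_se <- se2 == 0
  stat[zero_se & diff == 0] <- 0
  p[zero_se & diff == 0] <- 1
  stat[zero_se & diff != 0] <- sign(diff[zero_se & diff != 0]) * Inf
  p[zero_se & diff != 0] <- 0

  stat[!tested] <- NA; p[!tested] <- NA; diff[!tested] <- NA
  fdr <- rep(NA_real_, nrow(expr))
  fdr[tested] <- p.adjust(p[tested], method = "BH")
  direction <- empty_direction
  direction[tested & fdr < q_dep & diff > 0] <- "up"
  direction[tested & fdr < q_dep & diff < 0] <- "down"

  out <- data.frame(gene_id = rownames(expr), log2fc = unname(diff),
                    statistic = unname(stat), p = unname(p),
                    fdr = unname(fdr), direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "no_dep") <- FALSE
  attr(out, "dropped_genes") <- rownames(expr)[!tested]
  class(out) <- c("dep_table", class(out))
  out
}

#' Derive proteome-specific DEPs against the matched transcriptome
#'
#' A gene is proteome-specific when it is a DEP at the protein level
#' (protein FDR < `q_dep`) while showing no mRNA-level differential
#' expression (mRNA FDR >= `q_rna`), evaluated separately for up- and
#' down-regulation. The two tables are first restricted to their shared
#' gene universe (size stored in the `universe_size` attribute); genes the
#' mRNA test dropped count as not mRNA-differential.
#'
#' @param dep_prot,dep_rna `dep_table`s for the proteome and transcriptome.
#' @param q_dep protein-side FDR threshold.
#' @param q_rna mRNA-side FDR threshold.
#' @return list with character vectors `up` and `down`.
#' @export
proteome_specific <- function(dep_prot, dep_rna, q_dep = 0.05, q_rna = 0.05) {
  shared <- intersect(dep_prot$gene_id, dep_rna$gene_id)
  if (length(shared) == 0) stop("empty shared gene universe")
  pr <- dep_prot[match(shared, dep_prot$gene_id), ]
  rn <- dep_rna[match(shared, dep_rna$gene_id), ]
  rna_ns <- is.na(rn$fdr) | rn$fdr >= q_rna
  res <- list(
    up = shared[!is.na(pr$fdr) & pr$fdr < q_dep & pr$log2fc > 0 & rna_ns],
    down = shared[!is.na(pr$fdr) & pr$fdr < q_dep & pr$log2fc < 0 & rna_ns])
  attr(res, "universe_size") <- length(shared)
  res
}

#' Exact multi-set intersection test
#'
#' Upper-tail probability that m independent uniformly drawn subsets of a
#' common universe, with the observed set sizes, intersect in at least the
#' observed number of elements. The exact distribution of the intersection
#' size is computed by chaining hypergeometric kernels: conditional on the
#' running intersection having i elements, intersecting with the next
#' random subset of size n_k follows Hypergeometric(n, i, n_k). The expected
#' intersection size is n * prod(n_i / n). For m = 2 the p-value reduces to
#' the one-sided hypergeometric (Fisher) tail.
#'
#' @param sets list of m >= 2 character vectors (gene sets).
#' @param universe_size size of the common universe (>= the largest set).
#' @return list with `expected_overlap`, `observed_overlap`, `p`.
#' @export
multiset_intersection_test <- function(sets, universe_size) {
  stopifnot(length(sets) >= 2)
  sets <- lapply(sets, unique)
  sizes <- lengths(sets)
  n <- as.integer(universe_size)
  if (any(sizes > n)) stop("a set is larger than the universe")
  observed <- length(Reduce(intersect, sets))
  dist <- multiset_intersection_dist(sizes, n)
  p <- sum(dist[(observed + 1L):length(dist)])  # dist indexed from size 0
  list(expected_overlap = n * prod(sizes / n),
       observed_overlap = observed,
       p = min(max(p, .Machine$double.xmin), 1))
}

# exact pmf of the m-set intersection size (index j+1 = P(size == j))
multiset_intersection_dist <- function(sizes, n) {
  sizes <- as.integer(sizes)
  pmf <- numeric(n + 1L)
  pmf[sizes[1] + 1L] <- 1
  for (k in 2:length(sizes)) {
    new <- numeric(n + 1L)
    support <- which(pmf > 0) - 1L
    for (i in support) {
      j <- 0:min(i, sizes[k])
      new[j + 1L] <- new[j + 1L] + pmf[i + 1L] * dhyper(j, i, n - i, sizes[k])
    }
    pmf <- new
  }
  pmf
}

#' Recurrent proteome-specific DEPs across cohorts
#'
#' Counts, for every gene, the cohorts whose proteome-specific sets contain
#' it; genes recurring in at least `min_cohorts` cohorts are retained and
#' annotated with the exact multi-set intersection p-value over the sets in
#' which they appear. Ranking is by recurrence (descending), then p
#' (ascending), then gene id.
#'
#' @param per_cohort_sets named list (cohort -> character vector of genes).
#' @param universe character vector, the shared gene universe.
#' @param min_cohorts minimum recurrence (>= 2).
#' @return data.frame: `gene_id`, `recurrence`, `cohorts`, `p`.
#' @export
recurrent_specific_deps <- function(per_cohort_sets, universe,
                                    min_cohorts = 3) {
  stopifnot(min_cohorts >= 2, !is.null(names(per_cohort_sets)))
  per_cohort_sets <- lapply(per_cohort_sets, intersect, x = universe)
  counts <- table(unlist(lapply(per_cohort_sets, unique)))
  genes <- names(counts)[counts >= min_cohorts]
  if (length(genes) == 0)
    return(data.frame(gene_id = character(0), recurrence = integer(0),
                      cohorts = character(0), p = numeric(0)))
  combo <- vapply(genes, function(g) {
    paste(sort(names(per_cohort_sets)[vapply(per_cohort_sets, function(s)
      g %in% s, logical(1))]), collapse = ",")
  }, character(1))
  p_by_combo <- vapply(unique(combo), function(cm) {
    ids <- strsplit(cm, ",", fixed = TRUE)[[1]]
    multiset_intersection_test(per_cohort_sets[ids], length(universe))$p
  }, numeric(1))
  out <- data.frame(gene_id = genes,
                    recurrence = as.integer(counts[genes]),
                    cohorts = combo, p = unname(p_by_combo[combo]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$recurrence, out$p, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Collect DEP signatures from per-cohort DEP tables
#'
#' @param dep_tables named list (cohort -> `dep_table`).
#' @return named list of gene sets keyed `<cohort>_up` / `<cohort>_down`,
#'   with the shared universe in the `universe` attribute.
#' @export
dep_signatures <- function(dep_tables) {
  stopifnot(!is.null(names(dep_tables)))
  sets <- list()
  for (cid in names(dep_tables)) {
    tab <- dep_tables[[cid]]
    sets[[paste0(cid, "_up")]] <- tab$gene_id[tab$direction == "up"]
    sets[[paste0(cid, "_down")]] <- tab$gene_id[tab$direction == "down"]
  }
  attr(sets, "universe") <- unique(unlist(lapply(dep_tables, `[[`,
                                                 "gene_id")))
  sets
}
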