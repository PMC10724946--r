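#' Network neighborhood of a gene
#'
#' All nodes within `h` edges of `gene` on the PMFG, excluding the gene
#' itself.
#'
#' @param net a `planar_network`.
#' @param gene gene id.
#' @param h neighborhood depth (>= 1).
#' @return character vector of neighbor gene ids; `NULL` (with a message)
#'   when the gene is not in the network.
#' @export
neighborhood <- function(net, gene, h = 2) {
  stopifnot(inherits(net, "planar_network"), h >= 1)
  if (!gene %in% net$nodes) {
    message("gene not in network: ", gene)
    return(NULL)
  }
  g <- pmfg_igraph(net)
  nb <- igraph::ego(g, order = h, nodes = gene, mindist = 1)[[1]]
  sort(nb$name)
}

# mid-p one-sided hypergeometric tail: half the probability mass of the
# observed overlap is counted, which makes the null distribution of the
# p-value close to Uniform(0,1) despite the discreteness of the table
# (the plain tail is markedly super-uniform at neighborhood-sized tables);
# zero overlap keeps p = 1 by convention
fisher_midp <- function(query, target, universe) {
  N <- length(universe)
  K <- length(target)
  n <- length(query)
  if (K == 0 || n == 0) return(1)
  ov <- length(intersect(query, target))
  if (ov == 0) return(1)
  p <- phyper(ov - 1L, K, N - K, n, lower.tail = FALSE) -
    0.5 * dhyper(ov, K, N - K, n)
  min(max(p, .Machine$double.xmin), 1)
}

#' Score candidate key regulators by neighborhood signature enrichment
#'
#' For every network node with at least `min_neighbors` neighbors within
#' depth `h`, the neighborhood is tested by Fisher's exact test (mid-p
#' variant, so null p-values are calibrated despite the discreteness of
#' small overlap tables) against the cohort's up- and down-regulated DEP
#' signatures (universe = network nodes); FDR is adjusted per signature
#' across tested nodes. A node is a driver when min(fdr_up, fdr_down) <
#' `q_driver`. Hub status is joined from [call_hubs()] when supplied; a
#' driver need not be a hub.
#'
#' @param net a `planar_network`.
#' @param up_set,down_set character vectors: the cohort's DEP signatures.
#' @param h neighborhood depth.
#' @param q_driver FDR threshold for driver status.
#' @param min_neighbors minimum neighborhood size for testing.
#' @param hubs optional `hub_call` data.frame for the same network.
#' @return a `driver_records` data.frame: `gene_id`, `n_neighbors`,
#'   `p_up`, `p_down`, `fdr_up`, `fdr_down`, `is_hub`, `is_driver`.
#' @export
score_drivers <- function(net, up_set, down_set, h = 2, q_driver = 0.05,
                          min_neighbors = 5, hubs = NULL) {
  stopifnot(inherits(net, "planar_network"), min_neighbors >= 1)
  universe <- net$nodes
  up_set <- intersect(up_set, universe)
  down_set <- intersect(down_set, universe)
  g <- pmfg_igraph(net)
  nbs <- igraph::ego(g, order = h, nodes = igraph::V(g), mindist = 1)
  sizes <- lengths(nbs)
  tested <- which(sizes >= min_neighbors)
  if (length(tested) == 0)
    stop("no node has >= min_neighbors neighbors")
  p_up <- p_down <- rep(1, length(tested))
  for (i in seq_along(tested)) {
    nb <- nbs[[tested[i]]]$name
    p_up[i] <- fisher_midp(nb, up_set, universe)
    p_down[i] <- fisher_midp(nb, down_set, universe)
  }
  fdr_up <- p.adjust(p_up, method = "BH")
  fdr_down <- p.adjust(p_down, method = "BH")
  genes <- igraph::V(g)$name[tested]
  is_hub <- rep(NA, length(genes))
  if (!is.null(hubs)) is_hub <- hubs$is_hub[match(genes, hubs$gene_id)]
  out <- data.frame(gene_id = genes, n_neighbors = sizes[tested],
                    p_up = p_up, p_down = p_down, fdr_up = fdr_up,
                    fdr_down = fdr_down, is_hub = is_hub,
                    is_driver = pmin(fdr_up, fdr_down) < q_driver,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("driver_records", class(out))
  out
}

#' Aggregate per-cohort driver records into a pan-cancer ranking
#'
#' Genes are ordered by the number of cohorts in which they are drivers
#' (descending), then the number of cohorts in which they are hubs
#' (descending), then their best FDR across cohorts (ascending), then gene
#' id; the gene id tie-break makes the order total and invariant to cohort
#' input order.
#'
#' @param records named list: cohort -> `driver_records`.
#' @param q_driver FDR threshold used for the per-direction counts.
#' @return data.frame: `gene_id`, `n_cohorts_driver`, `n_cohorts_hub`,
#'   `n_up`, `n_down`, `best_fdr`, `rank`.
#' @export
rank_pan_cancer <- function(records, q_driver = 0.05) {
  stopifnot(length(records) >= 2, !is.null(names(records)))
  all_genes <- sort(unique(unlist(lapply(records, `[[`, "gene_id"))))
  n_driver <- n_hub <- n_up <- n_down <- setNames(integer(length(all_genes)),
                                                  all_genes)
  best_fdr <- setNames(rep(1, length(all_genes)), all_genes)
  for (rec in records) {
    idx <- match(rec$gene_id, all_genes)
    n_driver[idx] <- n_driver[idx] + as.integer(rec$is_driver)
    n_hub[idx] <- n_hub[idx] + as.integer(rec$is_hub %in% TRUE)
    n_up[idx] <- n_up[idx] + as.integer(rec$fdr_up < q_driver)
    n_down[idx] <- n_down[idx] + as.integer(rec$fdr_down < q_driver)
    best_fdr[idx] <- pmin(best_fdr[idx], pmin(rec$fdr_up, rec$fdr_down))
  }
  out <- data.frame(gene_id = all_genes,
                    n_cohorts_driver = unname(n_driver),
                    n_cohorts_hub = unname(n_hub),
                    n_up = unname(n_up), n_down = unname(n_down),
                    best_fdr = unname(best_fdr), stringsAsFactors = FALSE)
  out <- out[order(-out$n_cohorts_driver, -out$n_cohorts_hub, out$best_fdr,
                   out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
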