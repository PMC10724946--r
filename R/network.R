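#' Significance-screened Spearman correlation edge list
#'
#' Computes Spearman correlation for all gene pairs and estimates a
#' permutation FDR for every |rho| threshold from sample-permutation nulls
#' (each gene's values permuted independently, which breaks all gene-gene
#' dependence while preserving marginals). The FDR at threshold w is the
#' ratio of the expected null count of pairs with |rho| >= w to the observed
#' count, made monotone in w in the usual step-up fashion. Edges with
#' `perm_fdr < fdr_cut` are retained, sorted by weight descending with ties
#' broken lexicographically by (gene_a, gene_b).
#'
#' Constant gene rows cannot be ranked and are dropped (recorded in the
#' `dropped_genes` attribute).
#'
#' @param expr genes x samples numeric matrix (>= 10 samples).
#' @param n_perm number of permutations (>= 20).
#' @param fdr_cut permutation-FDR cutoff for retaining an edge.
#' @param seed seed for the permutation stream.
#' @return a `similarity_edges` data.frame: `gene_a`, `gene_b`, `rho`,
#'   `weight` (= |rho|), `perm_fdr`.
#' @export
correlation_screen <- function(expr, n_perm = 50, fdr_cut = 0.05, seed = 1) {
  check_expression_matrix(expr)
  stopifnot(ncol(expr) >= 10, n_perm >= 20)
  constant <- apply(expr, 1, function(r) {
    v <- r[is.finite(r)]
    length(v) < 3 || max(v) == min(v)
  })
  dropped <- rownames(expr)[constant]
  expr <- expr[!constant, , drop = FALSE]
  n_genes <- nrow(expr)
  if (n_genes < 2) stop("fewer than 2 usable gene rows")

  ## rank-transform rows, standardize; Pearson on ranks = Spearman
  rk <- t(apply(expr, 1, rank, na.last = "keep"))
  rs <- (rk - rowMeans(rk)) / sqrt(rowSums((rk - rowMeans(rk))^2))
  rho_mat <- tcrossprod(rs)
  iu <- which(upper.tri(rho_mat))
  rho <- rho_mat[iu]
  pairs_idx <- arrayInd(iu, dim(rho_mat))
  w_obs <- abs(rho)
  ord <- order(-w_obs)
  w_sorted <- w_obs[ord]

  ## permutation null: shuffle each gene's ranks independently
  set.seed(derive_seed(seed, "correlation_screen"))
  null_ge <- numeric(length(w_sorted))
  n_s <- ncol(rs)
  for (b in seq_len(n_perm)) {
    rp <- rs
    for (i in seq_len(n_genes)) rp[i, ] <- rs[i, sample.int(n_s)]
    null_w <- sort(abs(tcrossprod(rp)[iu]))
    ## count of null values >= each observed threshold
    null_ge <- null_ge +
      (length(null_w) - findInterval(w_sorted, null_w, left.open = TRUE))
  }
  fdr_raw <- pmin((null_ge / n_perm) / seq_along(w_sorted), 1)
  fdr_mono <- rev(cummin(rev(fdr_raw)))  # monotone non-decreasing as w drops

  genes <- rownames(expr)
  keep_sorted <- fdr_mono < fdr_cut
  sel <- ord[keep_sorted]
  a <- genes[pairs_idx[sel, 1]]
  b <- genes[pairs_idx[sel, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, rho = rho[sel],
                    weight = w_obs[sel], perm_fdr = fdr_mono[keep_sorted],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  attr(out, "dropped_genes") <- dropped
  attr(out, "n_genes") <- n_genes
  class(out) <- c("similarity_edges", class(out))
  out
}

# canonical candidate order: weight descending, ties lexicographic
sort_candidates <- function(edges) {
  edges[order(-edges$weight, edges$gene_a, edges$gene_b), , drop = FALSE]
}

#' Planar maximally filtered graph (PMFG)
#'
#' Greedy construction of the planar backbone of a similarity edge list:
#' candidate edges are visited in decreasing weight order (ties broken
#' lexicographically by gene pair, which makes the output invariant to input
#' row order) and an edge is accepted iff the growing graph remains planar
#' under the left-right planarity criterion. Construction stops when the
#' planar edge bound 3(n - 2) is reached or candidates are exhausted; the
#' final graph is re-certified planar. With fewer than 3 nodes the complete
#' graph is returned.
#'
#' @param edges `similarity_edges` (or any data.frame with `gene_a`,
#'   `gene_b`, `weight` and optionally `rho`).
#' @param nodes optional node universe; defaults to genes present in
#'   `edges`.
#' @return a `planar_network`: list with `nodes`, `edges` (`gene_a`,
#'   `gene_b`, `weight`, `rho`, `sign`), `embedding_certified`,
#'   `n_components`, and the candidate list in `candidates`.
#' @export
build_pmfg <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (is.null(edges$rho)) edges$rho <- edges$weight
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  else nodes <- sort(unique(as.character(nodes)))
  edges <- sort_candidates(edges)
  n <- length(nodes)
  ia <- match(edges$gene_a, nodes) - 1L
  ib <- match(edges$gene_b, nodes) - 1L
  if (anyNA(ia) || anyNA(ib)) stop("edge endpoints outside node universe")
  keep <- .pmfg_select(n, ia, ib)
  acc <- edges[keep, , drop = FALSE]
  acc$sign <- ifelse(acc$rho >= 0, 1L, -1L)
  rownames(acc) <- NULL
  certified <- .lr_is_planar(n, ia[keep], ib[keep])
  g <- igraph::graph_from_data_frame(
    acc[, c("gene_a", "gene_b", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  structure(list(nodes = nodes,
                 edges = acc[, c("gene_a", "gene_b", "weight", "rho",
                                 "sign")],
                 embedding_certified = certified,
                 n_components = igraph::components(g)$no,
                 candidates = edges),
            class = "planar_network")
}

#' @export
print.planar_network <- function(x, ...) {
  cat(sprintf(
    "planar_network: %d nodes, %d edges (planar bound %d), %d component(s)\n",
    length(x$nodes), nrow(x$edges),
    if (length(x$nodes) >= 3) 3 * (length(x$nodes) - 2) else
      length(x$nodes) * (length(x$nodes) - 1) / 2,
    x$n_components))
  invisible(x)
}

# igraph view of a planar network, with `length` = 1 - weight for paths
pmfg_igraph <- function(net) {
  e <- net$edges
  e$length <- pmax(1 - e$weight, 0)
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# mean within-cluster similarity over all within-cluster pairs
split_compactness <- function(S, labels) {
  tot <- 0; cnt <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    if (length(idx) > 1) {
      sub <- S[idx, idx]
      tot <- tot + sum(sub[upper.tri(sub)])
      cnt <- cnt + length(idx) * (length(idx) - 1) / 2
    }
  }
  if (cnt == 0) return(0)
  tot / cnt
}

#' Multiscale module detection on a planar network
#'
#' Recursive top-down splitting of the PMFG. Within a parent module,
#' all-pairs shortest-path distances are computed on the PMFG restricted to
#' the module (edge length = 1 - weight) and k-way splits (k = 2..4) are
#' proposed by k-medoids partitioning of that distance matrix. A split's
#' compactness is the mean within-child similarity, where similarity is one
#' minus the path distance normalized by the parent's diameter. The best
#' split is calibrated against an optimized configuration-model null:
#' `n_perm` degree-preserving rewirings of the parent subgraph with
#' permuted edge lengths (degree sequence and weight multiset kept, any
#' real grouping destroyed), each re-partitioned by the same k-medoids
#' search, giving a null distribution of achievable compactness. With q95
#' its 95th
#' percentile, a split is accepted at resolution alpha iff compactness >
#' alpha * q95 and every child has at least `min_size` members; the ratio
#' compactness / q95 is recorded as the split's critical resolution. Larger
#' alpha therefore demands more strongly separated modules. Splits are
#' enumerated at the calibration level alpha = 1 (the 5% permutation test),
#' so reporting resolutions below 1 coincide with 1; each module's alpha is
#' clamped by its parent so cuts are nested. A disconnected parent is split
#' into its connected components directly. Deterministic given `seed`.
#'
#' @param net a `planar_network`.
#' @param alphas ascending resolution grid; splits are explored down to
#'   `min(alphas)`.
#' @param min_size minimum module size (>= 3).
#' @param n_perm permutations for the compactness null (>= 50).
#' @param seed seed for the permutation streams.
#' @return a `module_hierarchy`: list of modules (`id`, `parent`,
#'   `members`, `alpha`, `compactness`, `split_p`) plus the call parameters.
#' @export
multiscale_cluster <- function(net, alphas = c(0.5, 1, 2), min_size = 10,
                               n_perm = 100, seed = 1) {
  stopifnot(inherits(net, "planar_network"), min_size >= 3, n_perm >= 50,
            !is.unsorted(alphas), all(alphas > 0))
  g <- pmfg_igraph(net)
  alpha_floor <- min(alphas)
  modules <- list()
  counter <- 0L

  add_module <- function(id, parent, members, alpha, compactness, split_p) {
    modules[[length(modules) + 1L]] <<- list(
      id = id, parent = parent, members = sort(members), alpha = alpha,
      compactness = compactness, split_p = split_p)
  }

  recurse <- function(id, members, alpha_ctx) {
    if (length(members) < 2 * min_size) return(invisible(NULL))
    sub <- igraph::induced_subgraph(g, members)
    comp <- igraph::components(sub)
    if (comp$no > 1) {
      sizes <- tabulate(comp$membership)
      kids <- which(sizes >= min_size)
      if (length(kids) < 1) return(invisible(NULL))
      for (ci in kids) {
        counter <<- counter + 1L
        cid <- sprintf("%s_%d", id, counter)
        mem <- igraph::V(sub)$name[comp$membership == ci]
        add_module(cid, id, mem, alpha_ctx, NA_real_, NA_real_)
        recurse(cid, mem, alpha_ctx)
      }
      return(invisible(NULL))
    }
    D <- igraph::distances(sub, weights = igraph::E(sub)$length)
    dmax <- max(D)
    if (!is.finite(dmax) || dmax <= 0) return(invisible(NULL))
    S <- 1 - D / dmax
    vnames <- igraph::V(sub)$name
    dd <- stats::as.dist(D)
    kmax <- min(4, floor(length(members) / min_size))
    ## k chosen by average silhouette width (raw compactness always grows
    ## with k); the null below mirrors the same selection
    pick_split <- function(d, sim, enforce_min) {
      best <- NULL
      for (k in 2:kmax) {
        fit <- tryCatch(cluster::pam(d, k, diss = TRUE, pamonce = 5),
                        error = function(e) NULL)
        if (is.null(fit)) next
        if (enforce_min && min(tabulate(fit$clustering, k)) < min_size) next
        asw <- fit$silinfo$avg.width
        if (is.null(best) || asw > best$asw)
          best <- list(asw = asw, labels = fit$clustering, k = k,
                       cp = split_compactness(sim, fit$clustering))
      }
      best
    }
    best <- pick_split(dd, S, enforce_min = TRUE)
    if (is.null(best)) return(invisible(NULL))
    ## optimized configuration-model null: rewire the parent subgraph
    ## preserving degrees, permute edge lengths, re-run the same search
    lens <- igraph::E(sub)$length
    set.seed(derive_seed(seed, paste0("split:", id)))
    null_cp <- vapply(seq_len(n_perm), function(b) {
      gp <- igraph::rewire(
        sub, igraph::keeping_degseq(niter = 10 * igraph::ecount(sub)))
      gp <- igraph::set_edge_attr(gp, "length", value = sample(lens))
      Dp <- igraph::distances(gp, weights = igraph::E(gp)$length)
      dmaxp <- max(Dp[is.finite(Dp)])
      if (!is.finite(dmaxp) || dmaxp <= 0) return(1)
      Dp[!is.finite(Dp)] <- dmaxp
      Sp <- 1 - Dp / dmaxp
      nb <- pick_split(stats::as.dist(Dp), Sp, enforce_min = FALSE)
      if (is.null(nb)) return(1)
      nb$cp
    }, numeric(1))
    q95 <- unname(quantile(null_cp, 0.95))
    split_p <- (1 + sum(null_cp >= best$cp)) / (n_perm + 1)
    alpha_crit <- if (q95 <= 0) Inf else best$cp / q95
    alpha_eff <- min(alpha_crit, alpha_ctx)
    if (alpha_eff <= max(alpha_floor, 1)) return(invisible(NULL))
    for (lv in sort(unique(best$labels))) {
      idx <- which(best$labels == lv)
      mem <- vnames[idx]
      child_cp <- mean(S[idx, idx][upper.tri(S[idx, idx])])
      counter <<- counter + 1L
      cid <- sprintf("%s_%d", id, counter)
      add_module(cid, id, mem, alpha_eff, child_cp, split_p)
      recurse(cid, mem, alpha_eff)
    }
    invisible(NULL)
  }

  add_module("M1", NA_character_, net$nodes, Inf, NA_real_, NA_real_)
  recurse("M1", net$nodes, Inf)
  structure(list(modules = modules, alphas = alphas, min_size = min_size,
                 n_perm = n_perm, seed = seed),
            class = "module_hierarchy")
}

#' Modules at a given resolution
#'
#' Cuts the module hierarchy at resolution `alpha`: starting from the root,
#' splits are followed while their acceptance alpha is at least `alpha`; the
#' leaves of that descent are the modules reported at this resolution.
#'
#' @param hierarchy a `module_hierarchy`.
#' @param alpha resolution at which to report modules.
#' @param drop_root drop the root when it has accepted children (default
#'   TRUE; the root is returned alone when nothing split).
#' @return named list of member-gene character vectors.
#' @export
modules_at <- function(hierarchy, alpha = 1, drop_root = TRUE) {
  mods <- hierarchy$modules
  ids <- vapply(mods, `[[`, character(1), "id")
  parent <- vapply(mods, `[[`, character(1), "parent")
  alph <- vapply(mods, `[[`, numeric(1), "alpha")
  leaves <- list()
  descend <- function(i) {
    kids <- which(!is.na(parent) & parent == ids[i] & alph >= alpha)
    if (length(kids) == 0) {
      leaves[[ids[i]]] <<- mods[[i]]$members
    } else {
      for (j in kids) descend(j)
    }
  }
  root <- which(is.na(parent))
  descend(root)
  if (drop_root && length(leaves) > 1) leaves <- leaves[names(leaves) != "M1"]
  leaves
}

#' Permutation-calibrated hub calling
#'
#' Builds a null degree distribution by re-running the PMFG construction on
#' `n_perm` weight-shuffled copies of the candidate similarity list (pair
#' set fixed, weights permuted) and pooling all node degrees. A node is a
#' hub iff its observed PMFG degree exceeds the (1 - `hub_q`) quantile of
#' the null; `null_quantile` reports each node's position in the null.
#'
#' @param net a `planar_network` (must carry its candidate list).
#' @param n_perm number of weight shuffles (>= 50).
#' @param hub_q null tail probability defining a hub.
#' @param seed seed for the shuffles.
#' @return a `hub_call` data.frame: `gene_id`, `degree`, `weighted_degree`,
#'   `is_hub`, `null_quantile`.
#' @export
call_hubs <- function(net, n_perm = 50, hub_q = 0.05, seed = 1) {
  stopifnot(inherits(net, "planar_network"), n_perm >= 50)
  cand <- net$candidates
  if (is.null(cand)) cand <- net$edges
  nodes <- net$nodes
  n <- length(nodes)
  if (n == 0 || nrow(cand) == 0) {
    out <- data.frame(gene_id = nodes, degree = integer(n),
                      weighted_degree = numeric(n), is_hub = logical(n),
                      null_quantile = rep(NA_real_, n),
                      stringsAsFactors = FALSE)
    class(out) <- c("hub_call", class(out))
    return(out)
  }
  deg <- setNames(integer(n), nodes)
  wdeg <- setNames(numeric(n), nodes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[i]; b <- net$edges$gene_b[i]
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    wdeg[a] <- wdeg[a] + net$edges$weight[i]
    wdeg[b] <- wdeg[b] + net$edges$weight[i]
  }
  set.seed(derive_seed(seed, "call_hubs"))
  null_deg <- integer(0)
  for (b in seq_len(n_perm)) {
    sh <- cand
    sh$weight <- sample(sh$weight)
    sh <- sort_candidates(sh)
    ia <- match(sh$gene_a, nodes) - 1L
    ib <- match(sh$gene_b, nodes) - 1L
    keep <- .pmfg_select(n, ia, ib)
    nd <- tabulate(c(ia[keep], ib[keep]) + 1L, n)
    null_deg <- c(null_deg, nd)
  }
  thr <- unname(quantile(null_deg, 1 - hub_q))
  fn <- ecdf(null_deg)
  out <- data.frame(gene_id = nodes, degree = unname(deg),
                    weighted_degree = unname(wdeg),
                    is_hub = unname(deg > thr),
                    null_quantile = fn(unname(deg)),
                    stringsAsFactors = FALSE)
  attr(out, "degree_threshold") <- thr
  class(out) <- c("hub_call", class(out))
  out
}
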