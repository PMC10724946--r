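#' Module overlap graph from preservation calls
#'
#' One node per (cohort, module); an undirected edge links two modules of
#' different cohorts when the preservation call of one onto the other is
#' strong in at least one direction. Transcriptome targets (`*_rna`) are
#' ignored: the graph is built on proteome module sets only.
#'
#' @param preservation data.frame from [preservation_matrix()].
#' @return an igraph graph; vertex names are `<cohort>::<module_id>` and
#'   vertices carry `cohort` and `module_id` attributes.
#' @export
build_overlap_graph <- function(preservation) {
  pres <- preservation[!grepl("_rna$", preservation$target), , drop = FALSE]
  v_from <- paste0(pres$cohort, "::", pres$module_id)
  v_to <- paste0(pres$target, "::", pres$best_match)
  nodes <- unique(c(v_from, v_to))
  strong <- pres$klass == "strong"
  edges <- unique(data.frame(
    a = pmin(v_from[strong], v_to[strong]),
    b = pmax(v_from[strong], v_to[strong]), stringsAsFactors = FALSE))
  vert <- data.frame(name = nodes,
                     cohort = sub("::.*$", "", nodes),
                     module_id = sub("^.*::", "", nodes),
                     stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vert)
  igraph::simplify(g)
}

#' Detect pan-cancer protein interaction communities (PCPICs)
#'
#' Connected components of the module overlap graph; a component becomes a
#' PCPIC when it spans at least `span_min` distinct cohorts. Discarded
#' components are reported in the `discarded` attribute.
#'
#' @param g module overlap graph from [build_overlap_graph()].
#' @param span_min minimum number of distinct cohorts (default: every
#'   cohort present in the graph, i.e. fully pan-cohort semantics).
#' @return list of PCPIC skeletons: `community_id`, `members` (data.frame
#'   `cohort`, `module_id`), `cohorts_spanned`.
#' @export
detect_communities <- function(g, span_min = NULL) {
  cohorts_all <- unique(igraph::V(g)$cohort)
  if (is.null(span_min)) span_min <- length(cohorts_all)
  stopifnot(span_min >= 2)
  comp <- igraph::components(g)
  out <- list()
  discarded <- 0L
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    cohorts <- unique(igraph::V(g)$cohort[idx])
    if (length(cohorts) >= span_min) {
      out[[length(out) + 1L]] <- list(
        community_id = sprintf("PCPIC%d", length(out) + 1L),
        members = data.frame(cohort = igraph::V(g)$cohort[idx],
                             module_id = igraph::V(g)$module_id[idx],
                             stringsAsFactors = FALSE),
        cohorts_spanned = sort(cohorts))
    } else {
      discarded <- discarded + 1L
    }
  }
  attr(out, "discarded") <- discarded
  out
}

#' Core protein set of a PCPIC
#'
#' The core is the set of genes that occur in the community's member
#' modules from at least `core_min` distinct cohorts (default: a majority
#' of the spanned cohorts). An empty core is retained with a warning.
#'
#' @param skeleton one element of [detect_communities()] output.
#' @param module_sets named list: cohort -> named list of module gene sets.
#' @param core_min minimum number of distinct cohorts a core gene must
#'   appear in (<= number of spanned cohorts).
#' @return character vector of core genes.
#' @export
extract_core <- function(skeleton, module_sets, core_min = NULL) {
  span <- length(skeleton$cohorts_spanned)
  if (is.null(core_min)) core_min <- ceiling(span / 2)
  stopifnot(core_min <= span)
  ## gene -> number of distinct cohorts whose member modules contain it
  per_cohort <- lapply(unique(skeleton$members$cohort), function(cid) {
    mods <- skeleton$members$module_id[skeleton$members$cohort == cid]
    unique(unlist(module_sets[[cid]][mods]))
  })
  counts <- table(unlist(per_cohort))
  core <- sort(names(counts)[counts >= core_min])
  if (length(core) == 0)
    warning("empty core for ", skeleton$community_id)
  core
}

#' Summarize PCPIC cores and build the signed cross-talk network
#'
#' For each PCPIC and cohort, the summary expression is the mean of the
#' z-scored core-gene rows over the cohort's samples (cohorts measuring
#' fewer than 2 core genes are skipped for that PCPIC). Pairwise Spearman
#' correlations between PCPIC summaries are computed within each cohort and
#' combined across cohorts by the median rho and Fisher's method on the
#' per-cohort p-values; an edge is kept when the combined p is below
#' `p_edge`, signed by the median rho. When DEP signatures are supplied,
#' each core is tested for enrichment in every cohort's up and down sets
#' (universe = the cohort's measured genes).
#'
#' @param pcpics list of PCPIC skeletons with a `core` element (see
#'   [extract_core()]).
#' @param proteomes named list of cohort proteome matrices.
#' @param signatures optional named gene-set list keyed `<cohort>_up` /
#'   `<cohort>_down` (see [dep_signatures()]).
#' @param p_edge combined-p threshold for keeping a cross-talk edge.
#' @return list: `pcpics` (input augmented with `summary_expression` and
#'   `dep_enrichment`), `network` (data.frame `a`, `b`, `rho`, `sign`,
#'   `p`).
#' @export
summarize_and_correlate <- function(pcpics, proteomes, signatures = NULL,
                                    p_edge = 0.05) {
  for (i in seq_along(pcpics)) {
    core <- pcpics[[i]]$core
    stopifnot(!is.null(core))
    summaries <- list()
    for (cid in intersect(pcpics[[i]]$cohorts_spanned, names(proteomes))) {
      x <- proteomes[[cid]]
      genes <- intersect(core, rownames(x))
      if (length(genes) < 2) next
      z <- t(scale(t(x[genes, , drop = FALSE])))
      summaries[[cid]] <- colMeans(z, na.rm = TRUE)
    }
    pcpics[[i]]$summary_expression <- summaries
    if (!is.null(signatures)) {
      enr <- list()
      for (cid in names(summaries)) {
        uni <- rownames(proteomes[[cid]])
        enr[[cid]] <- list(
          up = fisher_enrichment(core, signatures[[paste0(cid, "_up")]],
                                 uni),
          down = fisher_enrichment(core, signatures[[paste0(cid, "_down")]],
                                   uni))
      }
      pcpics[[i]]$dep_enrichment <- enr
    }
  }

  net <- data.frame(a = character(0), b = character(0), rho = numeric(0),
                    sign = character(0), p = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(pcpics) >= 2) {
    ids <- vapply(pcpics, `[[`, character(1), "community_id")
    for (i in seq_len(length(pcpics) - 1)) {
      for (j in (i + 1):length(pcpics)) {
        common <- intersect(names(pcpics[[i]]$summary_expression),
                            names(pcpics[[j]]$summary_expression))
        if (length(common) == 0) next
        rhos <- numeric(0); ps <- numeric(0)
        for (cid in common) {
          a <- pcpics[[i]]$summary_expression[[cid]]
          b <- pcpics[[j]]$summary_expression[[cid]]
          ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                          exact = FALSE))
          rhos <- c(rhos, unname(ct$estimate))
          ps <- c(ps, max(ct$p.value, .Machine$double.xmin))
        }
        p_comb <- pchisq(-2 * sum(log(ps)), df = 2 * length(ps),
                         lower.tail = FALSE)
        med_rho <- median(rhos)
        if (p_comb < p_edge) {
          net <- rbind(net, data.frame(
            a = ids[i], b = ids[j], rho = med_rho,
            sign = if (med_rho >= 0) "+" else "-", p = p_comb,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(pcpics = pcpics, network = net)
}

#' Full PCPIC extraction from preservation calls
#'
#' Convenience wrapper chaining [build_overlap_graph()],
#' [detect_communities()], [extract_core()] and
#' [summarize_and_correlate()].
#'
#' @param preservation data.frame from [preservation_matrix()].
#' @param module_sets named list: cohort -> named list of module gene sets.
#' @param proteomes named list of cohort proteome matrices.
#' @param signatures optional DEP signature list.
#' @param span_min,core_min,p_edge see the individual steps.
#' @return as [summarize_and_correlate()].
#' @export
pcpic_analysis <- function(preservation, module_sets, proteomes,
                           signatures = NULL, span_min = NULL,
                           core_min = NULL, p_edge = 0.05) {
  g <- build_overlap_graph(preservation)
  skel <- detect_communities(g, span_min)
  skel <- lapply(skel, function(s) {
    s$core <- extract_core(s, module_sets, core_min)
    s
  })
  summarize_and_correlate(skel, proteomes, signatures, p_edge)
}
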