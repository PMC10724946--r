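#' Fisher's exact overlap enrichment of two gene sets
#'
#' One-sided (upper tail) hypergeometric test on the 2x2 overlap table of
#' `query` and `target` inside `universe`; `fold` is observed over expected
#' overlap. Empty query or target yields p = 1 and fold = 0 by convention.
#'
#' @param query,target character vectors (restricted to `universe`).
#' @param universe character vector, the background gene universe.
#' @return list: `overlap`, `fold`, `p`, plus the restricted set sizes.
#' @export
fisher_enrichment <- function(query, target, universe) {
  stopifnot(length(universe) > 0)
  universe <- unique(universe)
  q <- intersect(unique(query), universe)
  t_ <- intersect(unique(target), universe)
  N <- length(universe)
  if (length(q) == 0 || length(t_) == 0)
    return(list(overlap = 0L, fold = 0, p = 1,
                n_query = length(q), n_target = length(t_), n_universe = N))
  ov <- length(intersect(q, t_))
  expected <- length(q) * length(t_) / N
  p <- phyper(ov - 1L, length(t_), N - length(t_), length(q),
              lower.tail = FALSE)
  list(overlap = ov, fold = ov / expected, p = min(max(p, 0), 1),
       n_query = length(q), n_target = length(t_), n_universe = N)
}

#' Best-match preservation call for one module
#'
#' Tests the module against every target module by Fisher's exact test,
#' adjusts across targets by Benjamini-Hochberg, and classifies the best
#' match (smallest FDR, ties by raw p then target name): `strong` when the
#' best FDR < `q_strong` and fold >= `fold_min`; otherwise `weak` when the
#' best FDR < `p_weak`; otherwise `none`. Both thresholds act on the
#' adjusted scale so that a module compared against many targets is not
#' declared preserved on multiplicity alone.
#'
#' @param module character vector of member genes.
#' @param target_modules named list of target module gene sets.
#' @param universe background universe for the comparison (module members
#'   outside it are dropped).
#' @param q_strong FDR threshold for strong preservation.
#' @param p_weak raw-p threshold for weak preservation.
#' @param fold_min minimum fold enrichment for strong preservation.
#' @return a one-row data.frame (`preservation_call`): `best_match`,
#'   `overlap`, `fold`, `p`, `fdr`, `klass`.
#' @export
best_match_preservation <- function(module, target_modules, universe,
                                    q_strong = 0.05, p_weak = 0.05,
                                    fold_min = 2) {
  stopifnot(length(target_modules) > 0, !is.null(names(target_modules)))
  res <- lapply(target_modules, fisher_enrichment, query = module,
                universe = universe)
  p <- vapply(res, `[[`, numeric(1), "p")
  fdr <- p.adjust(p, method = "BH")
  ord <- order(fdr, p, names(target_modules))
  best <- ord[1]
  klass <- if (fdr[best] < q_strong && res[[best]]$fold >= fold_min) "strong"
  else if (fdr[best] < p_weak) "weak"
  else "none"
  data.frame(best_match = names(target_modules)[best],
             overlap = res[[best]]$overlap, fold = res[[best]]$fold,
             p = p[best], fdr = fdr[best], klass = klass,
             stringsAsFactors = FALSE)
}

#' Cross-cohort (and transcriptome) module preservation matrix
#'
#' Scores every module of every cohort against every other cohort's module
#' set, and optionally against the same cohort's transcriptome module set
#' (target labelled `<cohort>_rna`). The universe of each comparison is the
#' intersection of the two networks' node sets.
#'
#' @param module_sets named list: cohort -> named list of module gene sets
#'   (typically [modules_at()] output at alpha = 1).
#' @param universes named list: cohort -> node universe of its network.
#' @param rna_module_sets optional named list like `module_sets` for the
#'   matched transcriptome networks.
#' @param rna_universes optional named list of transcriptome universes.
#' @param ... thresholds passed to [best_match_preservation()].
#' @return data.frame with one row per (module, target): `cohort`,
#'   `module_id`, `target`, `best_match`, `overlap`, `fold`, `p`, `fdr`,
#'   `klass`.
#' @export
preservation_matrix <- function(module_sets, universes,
                                rna_module_sets = NULL,
                                rna_universes = NULL, ...) {
  stopifnot(length(module_sets) >= 2, !is.null(names(module_sets)))
  rows <- list()
  for (cid in names(module_sets)) {
    for (mid in names(module_sets[[cid]])) {
      mod <- module_sets[[cid]][[mid]]
      targets <- setdiff(names(module_sets), cid)
      for (tid in targets) {
        uni <- intersect(universes[[cid]], universes[[tid]])
        call <- best_match_preservation(mod, module_sets[[tid]], uni, ...)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(cohort = cid, module_id = mid, target = tid,
                     stringsAsFactors = FALSE), call)
      }
      if (!is.null(rna_module_sets) && cid %in% names(rna_module_sets)) {
        uni <- intersect(universes[[cid]],
                         if (!is.null(rna_universes)) rna_universes[[cid]]
                         else universes[[cid]])
        call <- best_match_preservation(mod, rna_module_sets[[cid]], uni,
                                        ...)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(cohort = cid, module_id = mid,
                     target = paste0(cid, "_rna"),
                     stringsAsFactors = FALSE), call)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
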