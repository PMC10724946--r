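default_run_config <- function() {
  list(
    q_dep = 0.05,        # DEP FDR threshold
    q_rna = 0.05,        # mRNA-side threshold for proteome-specific DEPs
    min_cohorts = 3,     # recurrence threshold for recurrent specific DEPs
    fdr_cut = 0.05,      # correlation screen permutation-FDR cutoff
    alphas = c(0.5, 1, 2),  # module resolution grid (reporting layer: 1)
    min_size = 10,       # minimum module size
    n_perm = 50,         # permutations (screen, split calibration, hubs)
    hub_q = 0.05,        # hub null tail
    q_strong = 0.05,     # preservation: strong FDR threshold
    p_weak = 0.05,       # preservation: weak raw-p threshold
    fold_min = 2,        # preservation: strong fold threshold
    span_min = NULL,     # PCPIC: min cohorts spanned (NULL = all cohorts)
    core_min = NULL,     # PCPIC core recurrence (NULL = majority)
    p_edge = 0.05,       # PCPIC cross-talk edge threshold
    h = 2,               # driver neighborhood depth
    q_driver = 0.05,     # driver FDR threshold
    min_neighbors = 5,   # minimum tested neighborhood size
    include_rna = TRUE,  # also build transcriptome networks
    report_alpha = 1,    # resolution of the reported module sets
    seed = 1             # master seed
  )
}

#' Build and validate a pipeline run configuration
#'
#' Starts from the documented defaults and overrides them with the supplied
#' values; unknown keys are rejected, and parameter domains are checked.
#'
#' @param ... configuration values to override (see
#'   `panpronet:::default_run_config()` for the full set and defaults).
#' @return validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  if (length(over) && is.null(names(over)))
    stop("configuration values must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  probs <- c("q_dep", "q_rna", "fdr_cut", "hub_q", "q_strong", "p_weak",
             "p_edge", "q_driver")
  for (k in probs)
    if (!(cfg[[k]] > 0 && cfg[[k]] <= 1)) stop(k, " must be in (0, 1]")
  stopifnot(cfg$min_size >= 3, cfg$n_perm >= 20, cfg$fold_min >= 1,
            cfg$h >= 1, cfg$min_neighbors >= 1, cfg$min_cohorts >= 2,
            all(cfg$alphas > 0), !is.unsorted(cfg$alphas),
            cfg$report_alpha %in% cfg$alphas)
  if (!is.null(cfg$span_min)) stopifnot(cfg$span_min >= 2)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [run_config()].
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$alphas)) vals$alphas <- as.numeric(vals$alphas)
  do.call(run_config, vals)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  path
}

#' Run the full pan-cancer network pipeline
#'
#' Executes all stages in order on a multi-cohort panel: per-cohort DEP
#' calling (cohorts without normal samples are skipped with a notice and
#' excluded from driver scoring), proteome-specific DEPs and their
#' cross-cohort recurrence, per-cohort multiscale networks (proteome and,
#' optionally, transcriptome), the module preservation matrix, PCPIC
#' extraction with cores and the signed cross-talk network, and key-driver
#' scoring with the pan-cancer ranking. All stage outputs are written as
#' TSV/GMT/JSON under `out_dir`, and `manifest.json` records parameters,
#' seeds and MD5 checksums of every output. All randomness derives from
#' `config$seed`, so a rerun with the same panel and config is
#' byte-identical.
#'
#' @param panel a `cohort_panel` (see [generate_cohort_panel()] /
#'   [read_panel()]) or a directory containing panel files.
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`deps`,
#'   `signatures`, `specific`, `recurrent`, `networks`, `hierarchies`,
#'   `module_sets`, `hubs`, `preservation`, `pcpic`, `drivers`, `ranking`,
#'   `manifest`).
#' @export
run_pipeline <- function(panel, config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(panel)) panel <- read_panel(panel)
  stopifnot(inherits(panel, "cohort_panel"))
  cohorts <- names(panel$proteome)
  if (!is.null(config$span_min) && config$span_min > length(cohorts))
    stop("span_min exceeds the number of cohorts")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  files <- character(0)
  meta <- panel$metadata

  ## stage 1: DEP calling ---------------------------------------------------
  deps <- list(); rna_deps <- list(); specific <- list()
  dep_cohorts <- character(0)
  for (cid in cohorts) {
    cmeta <- meta[meta$cohort == cid, ]
    tab <- call_deps(panel$proteome[[cid]], cmeta, config$q_dep)
    if (isTRUE(attr(tab, "no_dep"))) {
      message("cohort without normal samples, no DEP calling: ", cid)
      next
    }
    dep_cohorts <- c(dep_cohorts, cid)
    deps[[cid]] <- tab
    files[paste0("dep_", cid)] <-
      write_tsv(tab, file.path(out_dir, sprintf("dep_%s.tsv", cid)))
    if (cid %in% names(panel$transcriptome)) {
      rna_deps[[cid]] <- call_deps(panel$transcriptome[[cid]], cmeta,
                                   config$q_rna)
      specific[[cid]] <- proteome_specific(deps[[cid]], rna_deps[[cid]],
                                           config$q_dep, config$q_rna)
    }
  }
  if (length(deps) == 0) stop("stage dep failed: no cohort with normals")
  signatures <- dep_signatures(deps)
  files["signatures"] <- write_gmt(signatures,
                                   file.path(out_dir, "dep_signatures.gmt"))
  recurrent <- NULL
  if (length(specific) >= config$min_cohorts) {
    spec_sets <- lapply(specific, function(s) union(s$up, s$down))
    recurrent <- recurrent_specific_deps(spec_sets, panel$genes,
                                         config$min_cohorts)
    files["recurrent"] <- write_tsv(
      recurrent, file.path(out_dir, "recurrent_specific_deps.tsv"))
  }

  ## stage 2: networks ------------------------------------------------------
  ## co-expression is modelled within the tumor compartment so that
  ## tumor-vs-normal mean shifts cannot masquerade as co-expression
  tumor_cols <- function(x, cid) {
    cmeta <- meta[meta$cohort == cid, ]
    ts <- cmeta$sample_id[cmeta$condition == "tumor"]
    x[, intersect(colnames(x), ts), drop = FALSE]
  }
  networks <- list(); hierarchies <- list(); hubs <- list()
  rna_module_sets <- NULL; rna_universes <- NULL
  for (cid in cohorts) {
    edges <- correlation_screen(tumor_cols(panel$proteome[[cid]], cid),
                                config$n_perm, config$fdr_cut,
                                derive_seed(seed, paste0("screen:", cid)))
    net <- build_pmfg(edges)
    hier <- multiscale_cluster(net, config$alphas, config$min_size,
                               max(config$n_perm, 50),
                               derive_seed(seed, paste0("cluster:", cid)))
    networks[[cid]] <- net
    hierarchies[[cid]] <- hier
    hubs[[cid]] <- call_hubs(net, max(config$n_perm, 50), config$hub_q,
                             derive_seed(seed, paste0("hubs:", cid)))
    files[paste0("edges_", cid)] <- write_tsv(
      net$edges, file.path(out_dir, sprintf("network_%s_edges.tsv", cid)))
    files[paste0("modules_", cid)] <- write_tsv(
      hierarchy_table(hier),
      file.path(out_dir, sprintf("modules_%s.tsv", cid)))
    files[paste0("hubs_", cid)] <- write_tsv(
      hubs[[cid]], file.path(out_dir, sprintf("hubs_%s.tsv", cid)))
  }
  module_sets <- lapply(hierarchies, modules_at, alpha = config$report_alpha)
  ## preservation background = genes measured in the cohort, not just the
  ## genes that survived the correlation screen
  universes <- setNames(lapply(cohorts, function(cid)
    rownames(panel$proteome[[cid]])), cohorts)
  if (isTRUE(config$include_rna) && length(panel$transcriptome)) {
    rna_nets <- list(); rna_hiers <- list()
    for (cid in intersect(cohorts, names(panel$transcriptome))) {
      edges <- correlation_screen(
        tumor_cols(panel$transcriptome[[cid]], cid), config$n_perm,
        config$fdr_cut, derive_seed(seed, paste0("screen_rna:", cid)))
      rna_nets[[cid]] <- build_pmfg(edges)
      rna_hiers[[cid]] <- multiscale_cluster(
        rna_nets[[cid]], config$alphas, config$min_size,
        max(config$n_perm, 50),
        derive_seed(seed, paste0("cluster_rna:", cid)))
    }
    rna_module_sets <- lapply(rna_hiers, modules_at,
                              alpha = config$report_alpha)
    rna_universes <- setNames(lapply(names(rna_nets), function(cid)
      rownames(panel$transcriptome[[cid]])), names(rna_nets))
  }

  ## stage 3: preservation --------------------------------------------------
  preservation <- preservation_matrix(
    module_sets, universes, rna_module_sets, rna_universes,
    q_strong = config$q_strong, p_weak = config$p_weak,
    fold_min = config$fold_min)
  files["preservation"] <- write_tsv(
    preservation, file.path(out_dir, "preservation.tsv"))

  ## stage 4: PCPIC ---------------------------------------------------------
  ## summary cross-talk is, like the networks, a tumor-compartment quantity:
  ## tumor-vs-normal shifts must not masquerade as community correlation
  tumor_proteomes <- setNames(lapply(cohorts, function(cid)
    tumor_cols(panel$proteome[[cid]], cid)), cohorts)
  pcpic <- pcpic_analysis(preservation, module_sets, tumor_proteomes,
                          signatures, config$span_min, config$core_min,
                          config$p_edge)
  cores <- lapply(pcpic$pcpics, `[[`, "core")
  names(cores) <- vapply(pcpic$pcpics, `[[`, character(1), "community_id")
  if (length(cores)) {
    files["pcpic_cores"] <- write_gmt(
      cores, file.path(out_dir, "pcpic_cores.gmt"))
  }
  files["pcpic_network"] <- write_tsv(
    pcpic$network, file.path(out_dir, "pcpic_network.tsv"))
  files["pcpic"] <- file.path(out_dir, "pcpic.json")
  jsonlite::write_json(
    lapply(pcpic$pcpics, function(p) {
      list(community_id = p$community_id, members = p$members,
           cohorts_spanned = p$cohorts_spanned, core = p$core)
    }), files["pcpic"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## stage 5: drivers -------------------------------------------------------
  drivers <- list()
  for (cid in dep_cohorts) {
    drivers[[cid]] <- score_drivers(
      networks[[cid]], signatures[[paste0(cid, "_up")]],
      signatures[[paste0(cid, "_down")]], config$h, config$q_driver,
      config$min_neighbors, hubs[[cid]])
    files[paste0("drivers_", cid)] <- write_tsv(
      drivers[[cid]], file.path(out_dir, sprintf("drivers_%s.tsv", cid)))
  }
  ranking <- NULL
  if (length(drivers) >= 2) {
    ranking <- rank_pan_cancer(drivers, config$q_driver)
    files["ranking"] <- write_tsv(
      ranking, file.path(out_dir, "pan_cancer_driver_ranking.tsv"))
  }

  ## manifest ---------------------------------------------------------------
  manifest <- list(
    package = "panpronet",
    version = as.character(utils::packageVersion("panpronet")),
    parameters = unclass(config),
    cohorts = cohorts, dep_cohorts = dep_cohorts,
    ## keyed by logical output name so manifests from different directories
    ## are comparable byte for byte
    checksums = as.list(setNames(unname(tools::md5sum(unname(files))),
                                 names(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(deps = deps, signatures = signatures, specific = specific,
                 recurrent = recurrent, networks = networks,
                 hierarchies = hierarchies, module_sets = module_sets,
                 hubs = hubs, preservation = preservation, pcpic = pcpic,
                 drivers = drivers, ranking = ranking, manifest = manifest))
}

#' Long-format table of a module hierarchy
#'
#' @param hierarchy a `module_hierarchy`.
#' @return data.frame: `module_id`, `parent_id`, `alpha`, `gene_id`.
#' @export
hierarchy_table <- function(hierarchy) {
  rows <- lapply(hierarchy$modules, function(m) {
    if (length(m$members) == 0) return(NULL)
    data.frame(module_id = m$id,
               parent_id = if (is.na(m$parent)) "" else m$parent,
               alpha = m$alpha, gene_id = m$members,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module_id = character(0), parent_id = character(0),
                      alpha = numeric(0), gene_id = character(0))
  out
}
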