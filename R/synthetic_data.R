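#' Describe one synthetic cohort
#'
#' A cohort emulates one cancer-type proteogenomic dataset: a shared gene
#' universe measured on tumor and matched adjacent normal samples, on two
#' layers (proteome and transcriptome) with partial concordance.
#'
#' @param cohort_id cohort label (e.g. `"C1"`).
#' @param n_tumor,n_normal sample counts; both must be at least 3.
#' @param noise_sd gene-level Gaussian noise standard deviation on the log
#'   scale, added on top of the latent module signal. Must be positive.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(cohort_id, n_tumor, n_normal, noise_sd = 0.5) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L,
            n_tumor >= 3, n_normal >= 3, noise_sd > 0)
  structure(list(cohort_id = cohort_id, n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal), noise_sd = noise_sd),
            class = "cohort_spec")
}

#' Describe one planted co-expression module
#'
#' Members of a planted module share a single latent factor within every
#' cohort that carries the module, so their pairwise correlation is governed
#' by the factor loadings and the cohort noise level. A module may be coupled
#' to another module's factor to plant positive or negative cross-module
#' correlation.
#'
#' @param module_id module label.
#' @param member_genes character vector of at least 10 gene ids.
#' @param cohorts cohort ids carrying the module.
#' @param latent_effect_sd standard deviation of the latent factor.
#' @param is_pan logical; `TRUE` when the module is present in all cohorts.
#' @param couple_to optional module id whose factor this module's factor is
#'   correlated with.
#' @param couple_rho target correlation with the `couple_to` factor, in
#'   \[-1, 1\].
#' @return a `planted_module` list.
#' @export
planted_module <- function(module_id, member_genes, cohorts,
                           latent_effect_sd = 1, is_pan = FALSE,
                           couple_to = NULL, couple_rho = NULL) {
  stopifnot(length(member_genes) >= 10, latent_effect_sd > 0,
            length(cohorts) >= 1)
  if (!is.null(couple_to)) stopifnot(!is.null(couple_rho),
                                     abs(couple_rho) <= 1)
  structure(list(module_id = module_id,
                 member_genes = unique(as.character(member_genes)),
                 cohorts = as.character(cohorts),
                 latent_effect_sd = latent_effect_sd,
                 is_pan = isTRUE(is_pan),
                 couple_to = couple_to, couple_rho = couple_rho),
            class = "planted_module")
}

#' Lay out disjoint planted modules over a gene universe
#'
#' Convenience constructor: assigns consecutive disjoint blocks of the gene
#' universe `G0001, G0002, ...` to modules of the requested sizes.
#'
#' @param n_genes size of the gene universe.
#' @param sizes integer vector of module sizes.
#' @param cohorts list (one element per module) of cohort-id vectors.
#' @param all_cohorts character vector of every cohort id, used to set the
#'   `is_pan` flag.
#' @param ... passed per-module: `latent_effect_sd`, `couple_to`,
#'   `couple_rho` may be vectors/lists aligned with `sizes`.
#' @return list of [planted_module()] objects.
#' @export
plan_modules <- function(n_genes, sizes, cohorts, all_cohorts,
                         latent_effect_sd = rep(1, length(sizes)),
                         couple_to = vector("list", length(sizes)),
                         couple_rho = vector("list", length(sizes))) {
  stopifnot(sum(sizes) <= n_genes, length(cohorts) == length(sizes))
  genes <- sprintf("G%04d", seq_len(n_genes))
  offset <- 0L
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    members <- genes[(offset + 1L):(offset + sizes[i])]
    offset <- offset + sizes[i]
    out[[i]] <- planted_module(
      module_id = sprintf("PM%02d", i), member_genes = members,
      cohorts = cohorts[[i]],
      latent_effect_sd = latent_effect_sd[i],
      is_pan = setequal(cohorts[[i]], all_cohorts),
      couple_to = couple_to[[i]], couple_rho = couple_rho[[i]])
  }
  out
}

validate_module_plan <- function(module_plan, n_genes, genes) {
  if (length(module_plan) == 0) return(invisible(TRUE))
  members <- lapply(module_plan, `[[`, "member_genes")
  all_members <- unlist(members)
  if (anyDuplicated(all_members))
    stop("planted modules must have disjoint member sets")
  if (!all(all_members %in% genes))
    stop("module member genes outside the gene universe")
  if (max(lengths(members)) > n_genes)
    stop("n_genes smaller than the largest module")
  ids <- vapply(module_plan, `[[`, character(1), "module_id")
  if (anyDuplicated(ids)) stop("duplicated module ids")
  invisible(TRUE)
}

#' Generate a synthetic multi-cohort proteome/transcriptome panel
#'
#' Emulates the structure of a multi-cancer proteogenomic study: several
#' cohorts over one gene universe, each with tumor and normal samples and two
#' expression layers. Planted module members load on a shared latent factor
#' (loading x factor + Gaussian noise; loadings are Uniform(0.6, 1)) within
#' the cohorts carrying the module; the same factor drives both layers, with
#' layer-specific noise, which yields partial proteome/transcriptome
#' concordance. One member per module is seeded as a regulator: it gets
#' loading 1 and a quarter of the module noise, making it the strongest
#' correlate of its module and hence a network hub. All members of a module
#' (and `n_extra_dep` background genes per cohort) receive a tumor-vs-normal
#' mean shift of +/-`dep_effect`; a fraction `frac_proteome_specific` of each
#' cohort's shifted genes is shifted on the proteome layer only.
#'
#' Randomness is consumed from per-cohort streams plus one truth stream, all
#' derived from `seed` via [derive_seed()]; identical inputs give identical
#' output.
#'
#' @param specs list of [cohort_spec()] objects.
#' @param n_genes gene universe size (genes are labelled `G0001`, ...).
#' @param module_plan list of [planted_module()] objects with disjoint
#'   members.
#' @param dep_effect absolute tumor-vs-normal shift in log units (> 0).
#' @param frac_proteome_specific fraction of each cohort's shifted genes
#'   whose shift is applied to the proteome only.
#' @param seed master seed.
#' @param n_extra_dep number of background (non-module) genes per cohort that
#'   also receive a shift.
#' @return a `cohort_panel` list with elements `proteome` and
#'   `transcriptome` (named lists of genes x samples matrices), `metadata`
#'   (sample_id, cohort, condition) and `truth` (planted modules, per-cohort
#'   signed shifts, proteome-specific genes, regulators).
#' @export
generate_cohort_panel <- function(specs, n_genes, module_plan,
                                  dep_effect = 2, frac_proteome_specific = 0.3,
                                  seed = 1, n_extra_dep = 50) {
  stopifnot(length(specs) >= 1, dep_effect > 0,
            frac_proteome_specific >= 0, frac_proteome_specific <= 1)
  genes <- sprintf("G%04d", seq_len(n_genes))
  validate_module_plan(module_plan, n_genes, genes)
  cohort_ids <- vapply(specs, `[[`, character(1), "cohort_id")
  if (anyDuplicated(cohort_ids)) stop("duplicated cohort ids")
  module_ids <- vapply(module_plan, `[[`, character(1), "module_id")
  module_members <- lapply(module_plan, `[[`, "member_genes")
  names(module_members) <- module_ids

  ## ground-truth assignments from a dedicated stream
  set.seed(derive_seed(seed, "truth"))
  regulators_by_module <- vapply(module_plan, function(m) {
    sample(m$member_genes, 1L)
  }, character(1))
  names(regulators_by_module) <- module_ids
  module_sign <- setNames(sample(c(-1, 1), length(module_plan), TRUE),
                          module_ids)
  background <- setdiff(genes, unlist(module_members))
  dep_genes <- list(); prot_specific <- list(); regulators <- list()
  for (cid in cohort_ids) {
    carried <- module_ids[vapply(module_plan, function(m)
      cid %in% m$cohorts, logical(1))]
    shifts <- numeric(0)
    for (mid in carried) {
      shifts <- c(shifts, setNames(
        rep(module_sign[[mid]] * dep_effect, length(module_members[[mid]])),
        module_members[[mid]]))
    }
    extra <- sample(background, min(n_extra_dep, length(background)))
    shifts <- c(shifts, setNames(
      sample(c(-1, 1), length(extra), TRUE) * dep_effect, extra))
    ps <- sample(names(shifts),
                 round(frac_proteome_specific * length(shifts)))
    dep_genes[[cid]] <- shifts
    prot_specific[[cid]] <- sort(ps)
    regulators[[cid]] <- unname(regulators_by_module[carried])
  }

  proteome <- list(); transcriptome <- list(); meta <- list()
  for (sp in specs) {
    cid <- sp$cohort_id
    set.seed(derive_seed(seed, paste0("cohort:", cid)))
    n <- sp$n_tumor + sp$n_normal
    samples <- c(sprintf("%s_T%03d", cid, seq_len(sp$n_tumor)),
                 sprintf("%s_N%03d", cid, seq_len(sp$n_normal)))
    condition <- rep(c("tumor", "normal"), c(sp$n_tumor, sp$n_normal))
    carried <- which(vapply(module_plan, function(m) cid %in% m$cohorts,
                            logical(1)))
    ## latent factors (coupled modules share variance with their reference)
    factors <- matrix(0, nrow = n, ncol = length(carried))
    colnames(factors) <- module_ids[carried]
    for (j in seq_along(carried)) {
      m <- module_plan[[carried[j]]]
      f <- rnorm(n)
      if (!is.null(m$couple_to) && m$couple_to %in% colnames(factors)) {
        base <- factors[, m$couple_to] /
          module_plan[[match(m$couple_to, module_ids)]]$latent_effect_sd
        f <- m$couple_rho * base + sqrt(1 - m$couple_rho^2) * f
      }
      factors[, j] <- m$latent_effect_sd * f
    }
    prot <- matrix(rnorm(n_genes * n), nrow = n_genes,
                   dimnames = list(genes, samples))
    rna <- matrix(rnorm(n_genes * n), nrow = n_genes,
                  dimnames = list(genes, samples))
    for (j in seq_along(carried)) {
      m <- module_plan[[carried[j]]]
      load <- setNames(runif(length(m$member_genes), 0.6, 1.0),
                       m$member_genes)
      noise <- setNames(rep(sp$noise_sd, length(m$member_genes)),
                        m$member_genes)
      reg <- regulators_by_module[[m$module_id]]
      load[reg] <- 1.0
      noise[reg] <- 0.25 * sp$noise_sd
      for (g in m$member_genes) {
        prot[g, ] <- load[g] * factors[, j] + noise[g] * rnorm(n)
        rna[g, ] <- load[g] * factors[, j] + noise[g] * rnorm(n)
      }
    }
    ## planted tumor shifts
    shifts <- dep_genes[[cid]]
    tumor_cols <- which(condition == "tumor")
    for (g in names(shifts)) {
      prot[g, tumor_cols] <- prot[g, tumor_cols] + shifts[[g]]
      if (!(g %in% prot_specific[[cid]]))
        rna[g, tumor_cols] <- rna[g, tumor_cols] + shifts[[g]]
    }
    proteome[[cid]] <- prot
    transcriptome[[cid]] <- rna
    meta[[cid]] <- data.frame(sample_id = samples, cohort = cid,
                              condition = condition,
                              stringsAsFactors = FALSE)
  }

  structure(list(
    proteome = proteome, transcriptome = transcriptome,
    metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    truth = list(modules = module_plan, dep_genes = dep_genes,
                 proteome_specific_genes = prot_specific,
                 regulators = regulators),
    genes = genes, seed = seed), class = "cohort_panel")
}

#' Write a synthetic panel to disk
#'
#' One expression TSV per cohort per layer (first column `gene_id`, then one
#' column per sample), one `metadata.tsv` (`sample_id`, `cohort`,
#' `condition`) and the planted truth as `truth.json`. Gene order is
#' identical between the proteome and transcriptome files of a cohort.
#'
#' @param panel a `cohort_panel` from [generate_cohort_panel()].
#' @param directory output directory (created if missing).
#' @return named character vector of the written file paths, invisibly.
#' @export
write_panel <- function(panel, directory) {
  stopifnot(inherits(panel, "cohort_panel"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (layer in c("proteome", "transcriptome")) {
    for (cid in names(panel[[layer]])) {
      p <- file.path(directory, sprintf("%s_%s.tsv", cid, layer))
      write_expression_tsv(panel[[layer]][[cid]], p)
      paths[sprintf("%s_%s", cid, layer)] <- p
    }
  }
  mp <- file.path(directory, "metadata.tsv")
  data.table::fwrite(panel$metadata, mp, sep = "\t")
  paths["metadata"] <- mp
  tp <- file.path(directory, "truth.json")
  truth <- panel$truth
  truth$modules <- lapply(truth$modules, unclass)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths["truth"] <- tp
  invisible(paths)
}

#' Read a panel written by [write_panel()]
#'
#' @param directory directory containing the panel files.
#' @return a `cohort_panel` list (truth restored from `truth.json` when
#'   present).
#' @export
read_panel <- function(directory) {
  mp <- file.path(directory, "metadata.tsv")
  meta <- as.data.frame(data.table::fread(mp, sep = "\t"))
  cohorts <- unique(meta$cohort)
  proteome <- list(); transcriptome <- list()
  for (cid in cohorts) {
    for (layer in c("proteome", "transcriptome")) {
      p <- file.path(directory, sprintf("%s_%s.tsv", cid, layer))
      if (file.exists(p)) {
        m <- read_expression_tsv(p)
        if (layer == "proteome") proteome[[cid]] <- m
        else transcriptome[[cid]] <- m
      }
    }
  }
  truth <- NULL
  tp <- file.path(directory, "truth.json")
  if (file.exists(tp)) {
    truth <- jsonlite::read_json(tp, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
    truth$dep_genes <- lapply(truth$dep_genes, unlist)
  }
  structure(list(proteome = proteome, transcriptome = transcriptome,
                 metadata = meta, truth = truth,
                 genes = rownames(proteome[[1]])),
            class = "cohort_panel")
}

#' Write one expression matrix as TSV
#'
#' @param x genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  check_expression_matrix(x)
  dt <- data.table::data.table(gene_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an expression TSV (first column `gene_id`)
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (names(dt)[1] != "gene_id") stop("first column must be gene_id: ", path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$gene_id
  m
}
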