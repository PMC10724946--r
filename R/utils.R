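#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages consume seeds derived from one master seed and a
#' stage/cohort key, so a single integer reproduces an entire run while
#' stages remain independently re-runnable. The derivation hashes the key
#' characters into a 31-bit integer together with the master seed.
#'
#' @param seed master seed (single integer).
#' @param key character scalar naming the consumer (e.g. `"network:BRCA"`).
#' @return a single integer suitable for [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(key),
            length(key) == 1L)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 48271 + h + 1) %% 2147483629)
}

#' Adjusted Rand index between two labelings
#'
#' Convenience wrapper used to score recovery of planted module labels.
#' Labels are matched by name when both vectors are named.
#'
#' @param labels,truth label vectors (coerced to character).
#' @return the adjusted Rand index.
#' @export
module_recovery_ari <- function(labels, truth) {
  if (!is.null(names(labels)) && !is.null(names(truth))) {
    common <- intersect(names(labels), names(truth))
    labels <- labels[common]
    truth <- truth[common]
  }
  stopifnot(length(labels) == length(truth), length(labels) > 0)
  mclust::adjustedRandIndex(as.character(labels), as.character(truth))
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Gene identifiers are opaque, case-sensitive strings.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# internal: validate an expression matrix (genes x samples, log scale)
check_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop(what, " has duplicated gene ids")
  invisible(x)
}

# internal: metadata data.frame with sample_id, cohort, condition
check_metadata <- function(meta) {
  need <- c("sample_id", "cohort", "condition")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(meta$condition), c("tumor", "normal"))
  if (length(bad))
    stop("condition must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "))
  invisible(meta)
}
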