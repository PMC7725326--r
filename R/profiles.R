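#' Define a metabolic pathway by its member enzymes
#'
#' @param pathway_id Pathway identifier.
#' @param enzyme_ids Character vector of member enzyme IDs (unique,
#'   non-empty); its length is the denominator of the fuzzy profile.
#' @param name Human-readable name; defaults to `pathway_id`.
#' @param source_genome Optional genome the pathway definition comes from.
#' @return An object of class `pathway_definition`.
#' @export
pathway_definition <- function(pathway_id, enzyme_ids, name = pathway_id,
                               source_genome = NA_character_) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  enzyme_ids <- as.character(enzyme_ids)
  if (!length(enzyme_ids)) {
    stop("pathway '", pathway_id, "' has no enzymes", call. = FALSE)
  }
  if (anyDuplicated(enzyme_ids)) {
    stop("duplicate enzyme IDs in pathway '", pathway_id, "'",
         call. = FALSE)
  }
  structure(list(pathway_id = pathway_id, name = name,
                 enzyme_ids = enzyme_ids, source_genome = source_genome),
            class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat(sprintf("pathway '%s' (%s): %d enzymes\n", x$pathway_id, x$name,
              length(x$enzyme_ids)))
  invisible(x)
}

#' @export
length.pathway_definition <- function(x) length(x$enzyme_ids)

#' Read pathway definitions from a two-column TSV
#'
#' One row per (pathway_id, enzyme_id) pair, no header; enzyme order within
#' a pathway follows file order.
#'
#' @param path File path.
#' @return A named list of [pathway_definition()] objects.
#' @export
read_pathway_definitions <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected two tab-separated columns", call. = FALSE)
  ids <- unique(as.character(raw[[1L]]))
  out <- lapply(ids, function(p) {
    pathway_definition(p, as.character(raw[[2L]][raw[[1L]] == p]))
  })
  stats::setNames(out, ids)
}

#' Fuzzy pathway profile
#'
#' The fuzzy presence of a pathway in genome `j` is the arithmetic mean of
#' the homologue counts of its `n` member enzymes in that genome,
#' `f_j = (sum_i h_ij) / n` — an unbounded non-negative score where 0 means
#' complete absence and values near or above 1 indicate (partial) presence.
#' Every declared enzyme must be a matrix row: silently dropping a missing
#' enzyme would change the denominator and bias the profile invisibly.
#'
#' @param matrix A [homology_matrix()].
#' @param pathway A [pathway_definition()].
#' @return Named numeric vector of fuzzy presences, one per genome column.
#' @export
fuzzy_profile <- function(matrix, pathway) {
  stopifnot(inherits(matrix, "homology_matrix"),
            inherits(pathway, "pathway_definition"))
  missing <- setdiff(pathway$enzyme_ids, rownames(matrix))
  if (length(missing)) {
    stop("pathway '", pathway$pathway_id,
         "' enzymes missing from the homology matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  colMeans(unclass(matrix)[pathway$enzyme_ids, , drop = FALSE])
}

#' Fuzzy profiles for a set of pathways
#'
#' @param matrix A [homology_matrix()].
#' @param pathways List of [pathway_definition()] objects.
#' @return Numeric matrix, pathways (rows) by genomes (columns).
#' @export
fuzzy_profile_matrix <- function(matrix, pathways) {
  stopifnot(length(pathways) >= 1L)
  out <- t(vapply(pathways, function(p) fuzzy_profile(matrix, p),
                  numeric(ncol(matrix))))
  rownames(out) <- vapply(pathways, function(p) p$pathway_id, "")
  out
}

#' Discretize a fuzzy profile
#'
#' Applies the presence threshold `alpha`: `d_j = 1` when `f_j >= alpha`,
#' else 0. The boundary is inclusive — a fuzzy value exactly at the
#' threshold is a presence call.
#'
#' @param fuzzy Numeric vector (or pathway-by-genome matrix) of fuzzy
#'   presences.
#' @param alpha Positive presence threshold.
#' @return Integer 0/1 object shaped like `fuzzy`.
#' @export
discretize_profile <- function(fuzzy, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  out <- ifelse(fuzzy >= alpha, 1L, 0L)
  if (is.matrix(fuzzy)) dimnames(out) <- dimnames(fuzzy)
  else names(out) <- names(fuzzy)
  out
}

#' Data-driven default for the presence threshold
#'
#' When no `alpha` is supplied, the threshold is taken as the average fuzzy
#' presence over all genomes. `method = "grand"` (the default) averages
#' over every pathway-by-genome cell of the run; `method = "genome"`
#' averages the per-genome column means, which coincides with the grand
#' mean on a complete grid but differs in the presence of missing cells.
#'
#' @param all_fuzzy Numeric matrix (pathways x genomes) of fuzzy presences.
#' @param method `"grand"` or `"genome"`.
#' @return A single numeric threshold. Note that an all-zero grid yields 0,
#'   which [discretize_profile()] rejects, forcing an explicit user alpha.
#' @export
default_alpha <- function(all_fuzzy, method = c("grand", "genome")) {
  method <- match.arg(method)
  if (!length(all_fuzzy)) stop("empty fuzzy grid", call. = FALSE)
  all_fuzzy <- as.matrix(all_fuzzy)
  switch(method,
         grand = mean(all_fuzzy),
         genome = mean(colMeans(all_fuzzy)))
}

#' Write a pathway-by-genome profile grid as TSV
#'
#' @param grid Numeric matrix (pathways x genomes), fuzzy or discrete.
#' @param path File path.
#' @export
write_profile_grid <- function(grid, path) {
  header <- paste(c("pathway", colnames(grid)), collapse = "\t")
  rows <- vapply(seq_len(nrow(grid)), function(i) {
    paste(c(rownames(grid)[i],
            format(grid[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
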