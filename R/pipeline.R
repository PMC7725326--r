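#' Run the full reconstruction pipeline
#'
#' Wires the whole method end to end: homology-matrix construction from
#' similarity-search hits (or a precomputed matrix), optional pangenome
#' aggregation and virtual-leaf attachment, fuzzy pathway profiles,
#' discretization, and the per-pathway ancestral reconstruction. All
#' intermediates, per-pathway states/events, a summary and a
#' machine-readable manifest (parameters, the alpha actually used, package
#' version) are written into `out_dir`; identical inputs and parameters
#' reproduce byte-identical outputs.
#'
#' @param hits Path to BLAST outfmt-6 style hits (ignored when `matrix` is
#'   given).
#' @param gene_map Path to the gene-to-genome two-column TSV.
#' @param pathways Path to the pathway-definition TSV, or a list of
#'   [pathway_definition()] objects.
#' @param tree Path to the Newick tree, or a `phylo` object.
#' @param out_dir Output directory.
#' @param matrix Optional path to a precomputed homology-matrix TSV (or a
#'   `homology_matrix`), replacing the hits/gene_map stage.
#' @param blocks Optional genome-to-block TSV path or named vector; when
#'   given, virtual pangenome columns and leaves are added.
#' @param genomes Optional character vector fixing the genome (column)
#'   universe; defaults to the genomes seen in `gene_map`/`matrix`.
#' @param evalue_cutoff E-value cutoff for hit counting (default `1e-6`).
#' @param alpha Presence threshold, or `"auto"` (default) for the grand
#'   mean of the fuzzy grid.
#' @param alpha_method Passed to [default_alpha()].
#' @param gain,loss,mode Reconstruction parameters, see [pathtrace()].
#' @param aggregate Pangenome aggregation rule, see [aggregate_pangenome()].
#' @param biopax Optional path to a BioPAX L3 template; one annotated file
#'   per tree node is emitted for the pathway matching the template (the
#'   first pathway otherwise).
#' @param seed Optional integer recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return Invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(hits = NULL, gene_map = NULL, pathways, tree,
                         out_dir, matrix = NULL, blocks = NULL,
                         genomes = NULL, evalue_cutoff = 1e-6,
                         alpha = "auto", alpha_method = "grand",
                         gain = 5L, loss = 2L, mode = "leaf",
                         aggregate = "max", biopax = NULL, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.character(pathways)) {
    pathways <- stage("pathways", read_pathway_definitions(pathways))
  }
  if (is.character(tree)) tree <- stage("tree", read_newick(tree))
  # a bare string is a file path; a named vector is already the map
  if (is.character(blocks) && is.null(names(blocks))) {
    blocks <- stage("blocks", read_id_map(blocks))
  }

  if (is.null(matrix)) {
    if (is.null(hits) || is.null(gene_map)) {
      stop("either 'matrix' or both 'hits' and 'gene_map' are required",
           call. = FALSE)
    }
    hit_rows <- stage("hits", read_blast_hits(hits))
    g2g <- if (is.character(gene_map) && is.null(names(gene_map))) {
      stage("gene_map", read_id_map(gene_map))
    } else gene_map
    if (is.null(genomes)) genomes <- unique(unname(g2g))
    enzymes <- unique(unlist(lapply(pathways, function(p) p$enzyme_ids)))
    mat <- stage("matrix", count_homologues(
      hit_rows, g2g, enzymes, genomes, evalue_cutoff = evalue_cutoff,
      blocks = blocks))
  } else if (is.character(matrix)) {
    mat <- stage("matrix", read_homology_matrix(matrix, blocks = blocks))
  } else {
    mat <- matrix
  }

  png_names <- NULL
  if (!is.null(blocks)) {
    block_ids <- unique(unname(blocks))
    png_names <- stats::setNames(paste0(block_ids, "-png"), block_ids)
    mat <- stage("aggregate",
                 aggregate_pangenome(mat, blocks, mode = aggregate,
                                     png_names = png_names))
    tree <- stage("tree", attach_pangenome_leaves(tree, blocks, png_names))
  }

  fuzzy <- stage("profiles", fuzzy_profile_matrix(mat, pathways))
  alpha_used <- if (identical(alpha, "auto")) {
    default_alpha(fuzzy, method = alpha_method)
  } else as.numeric(alpha)
  discrete <- stage("discretize", discretize_profile(fuzzy, alpha_used))

  leafset <- tree$tip.label
  profile_cols <- intersect(colnames(discrete), leafset)
  missing_leaves <- setdiff(leafset, colnames(discrete))
  if (length(missing_leaves)) {
    stop("pipeline stage 'reconstruct' failed: tree leaves without a ",
         "profile column: ", paste(missing_leaves, collapse = ", "),
         call. = FALSE)
  }
  fits <- stage("reconstruct",
                pathtrace_all(tree, discrete[, leafset, drop = FALSE],
                              gain = gain, loss = loss, mode = mode))
  hist_summary <- summarize_history(fits)

  write_homology_matrix(mat, file.path(out_dir, "matrix.tsv"))
  write_profile_grid(fuzzy, file.path(out_dir, "fuzzy.tsv"))
  write_profile_grid(discrete, file.path(out_dir, "discrete.tsv"))
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  nodes <- do.call(rbind, lapply(names(fits), function(p) {
    cbind(pathway = p, tree_to_nodes(tree, fits[[p]]))
  }))
  utils::write.table(nodes, file.path(out_dir, "states.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  events <- do.call(rbind, lapply(names(fits), function(p) {
    ev <- fits[[p]]$events
    if (nrow(ev)) cbind(pathway = p, ev) else NULL
  }))
  if (is.null(events)) {
    events <- data.frame(pathway = character(0), parent = character(0),
                         child = character(0), event = character(0))
  }
  utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(hist_summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  if (!is.null(biopax)) {
    tpl <- stage("biopax", extract_proteins(read_biopax(biopax)))
    target <- if (tpl$pathway$pathway_id %in% names(fits)) {
      tpl$pathway$pathway_id
    } else names(fits)[1L]
    stage("biopax", annotate_per_node(biopax, fits[[target]],
                                      file.path(out_dir, "biopax")))
  }

  manifest <- list(
    parameters = list(evalue_cutoff = evalue_cutoff, alpha = alpha,
                      alpha_used = alpha_used, alpha_method = alpha_method,
                      gain = gain, loss = loss, mode = mode,
                      aggregate = aggregate, seed = seed),
    n_pathways = length(pathways),
    n_genomes = ncol(mat),
    n_enzymes = nrow(mat),
    leaves = tree$tip.label,
    package_version = as.character(utils::packageVersion("pathtrace"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(matrix = mat, tree = tree, fuzzy = fuzzy,
                 discrete = discrete, alpha = alpha_used, fits = fits,
                 summary = hist_summary, manifest = manifest))
}
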