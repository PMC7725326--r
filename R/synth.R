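#' Specify a synthetic pangenome ensemble
#'
#' The generator emulates the data regime the method targets: strains
#' organized in pangenome blocks (block clades on a caterpillar spine),
#' small integer homologue counts, per-clade planted pathway presence or
#' absence, and two noise channels — spurious hits where a pathway is
#' absent (`epsilon`) and missed hits where it is present (`dropout`).
#'
#' Homologue counts where a pathway is present are drawn as
#' `1 + Poisson(lambda_present - 1)` (mean exactly `lambda_present`,
#' support >= 1): a genome that truly encodes an enzyme carries at least
#' one gene copy, so the noise-free limit yields discrete profiles equal to
#' the planted states. Cells where the pathway is absent are 1 with
#' probability `epsilon`, else 0.
#'
#' @param n_blocks Number of pangenome blocks.
#' @param strains_per_block Integer vector of length `n_blocks`.
#' @param n_pathways Number of pathways.
#' @param enzymes_per_pathway Integer vector of length `n_pathways`.
#' @param planted_states Optional character matrix
#'   (`n_pathways x n_blocks`) of `"present"`/`"absent"`; default all
#'   present.
#' @param lambda_present Mean homologue count where present (>= 1).
#' @param epsilon Spurious-hit probability where absent, in `[0, 1)`.
#' @param dropout Per-cell missed-hit probability where present, in
#'   `[0, 1)`.
#' @param seed Integer seed; the ensemble is fully reproducible from it.
#' @param balanced Use balanced bifurcating block clades instead of
#'   polytomies.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_blocks, strains_per_block, n_pathways,
                          enzymes_per_pathway, planted_states = NULL,
                          lambda_present = 2, epsilon = 0, dropout = 0,
                          seed = 1L, balanced = FALSE) {
  n_blocks <- as.integer(n_blocks)
  strains_per_block <- as.integer(strains_per_block)
  n_pathways <- as.integer(n_pathways)
  enzymes_per_pathway <- as.integer(enzymes_per_pathway)
  if (length(strains_per_block) != n_blocks) {
    stop("strains_per_block must have length n_blocks", call. = FALSE)
  }
  if (length(enzymes_per_pathway) != n_pathways) {
    stop("enzymes_per_pathway must have length n_pathways", call. = FALSE)
  }
  if (any(strains_per_block < 1L) || any(enzymes_per_pathway < 1L)) {
    stop("block and pathway sizes must be >= 1", call. = FALSE)
  }
  if (lambda_present < 1) {
    stop("lambda_present must be >= 1", call. = FALSE)
  }
  if (epsilon < 0 || epsilon >= 1 || dropout < 0 || dropout >= 1) {
    stop("epsilon and dropout must lie in [0, 1)", call. = FALSE)
  }
  blocks <- paste0("B", seq_len(n_blocks))
  pathways <- paste0("P", seq_len(n_pathways))
  if (is.null(planted_states)) {
    planted_states <- matrix("present", n_pathways, n_blocks,
                             dimnames = list(pathways, blocks))
  } else {
    planted_states <- as.matrix(planted_states)
    if (!all(dim(planted_states) == c(n_pathways, n_blocks)) ||
        !all(planted_states %in% c("present", "absent"))) {
      stop("planted_states must be an n_pathways x n_blocks matrix of ",
           "'present'/'absent'", call. = FALSE)
    }
    dimnames(planted_states) <- list(pathways, blocks)
  }
  structure(list(n_blocks = n_blocks, strains_per_block = strains_per_block,
                 n_pathways = n_pathways,
                 enzymes_per_pathway = enzymes_per_pathway,
                 planted_states = planted_states,
                 lambda_present = lambda_present, epsilon = epsilon,
                 dropout = dropout, seed = as.integer(seed),
                 balanced = balanced,
                 block_names = blocks, pathway_names = pathways),
            class = "ensemble_spec")
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

balanced_clade <- function(labels) {
  if (length(labels) == 1L) return(labels)
  mid <- ceiling(length(labels) / 2)
  paste0("(", balanced_clade(labels[seq_len(mid)]), ",",
         balanced_clade(labels[-seq_len(mid)]), ")")
}

# caterpillar spine of block clades: (((B1,B2)S1,B3)S2,...)root
ensemble_newick <- function(spec) {
  clades <- vapply(seq_len(spec$n_blocks), function(b) {
    strains <- paste0(spec$block_names[b], "_s",
                      seq_len(spec$strains_per_block[b]))
    if (length(strains) == 1L) return(strains)
    inner <- if (spec$balanced) {
      bc <- balanced_clade(strains)
      substr(bc, 2L, nchar(bc) - 1L)
    } else paste(strains, collapse = ",")
    paste0("(", inner, ")", spec$block_names[b])
  }, "")
  if (spec$n_blocks == 1L) return(paste0(clades, ";"))
  tree <- clades[1L]
  for (b in 2L:spec$n_blocks) {
    lab <- if (b == spec$n_blocks) "root" else paste0("S", b - 1L)
    tree <- paste0("(", tree, ",", clades[b], ")", lab)
  }
  paste0(tree, ";")
}

sample_present <- function(n, lambda, dropout) {
  x <- 1L + stats::rpois(n, lambda - 1)
  if (dropout > 0) x[stats::runif(n) < dropout] <- 0L
  x
}

sample_absent <- function(n, epsilon) {
  if (epsilon <= 0) integer(n) else
    as.integer(stats::runif(n) < epsilon)
}

#' Generate a synthetic ensemble
#'
#' Produces the tree, block map, homology matrix, pathway definitions and
#' the planted per-node truth for a [ensemble_spec()]. Internal truth
#' states follow a single-origin history: a pathway is present at every
#' ancestor of a present leaf and absent only in uniformly-absent clades,
#' so a block planted absent among present blocks is one loss (use
#' [plant_event()] to compose explicit gain histories).
#'
#' @param spec An [ensemble_spec()].
#' @return An object of class `synthetic_ensemble` with fields `tree`,
#'   `blocks`, `matrix`, `pathways`, `truth` and `spec`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  tree <- parse_newick(ensemble_newick(spec))
  strain_block <- unlist(lapply(seq_len(spec$n_blocks), function(b) {
    stats::setNames(rep(spec$block_names[b], spec$strains_per_block[b]),
                    paste0(spec$block_names[b], "_s",
                           seq_len(spec$strains_per_block[b])))
  }))
  enz_ids <- unlist(lapply(seq_len(spec$n_pathways), function(p) {
    paste0(spec$pathway_names[p], "_e",
           seq_len(spec$enzymes_per_pathway[p]))
  }))
  pathways <- lapply(seq_len(spec$n_pathways), function(p) {
    pathway_definition(spec$pathway_names[p],
                       paste0(spec$pathway_names[p], "_e",
                              seq_len(spec$enzymes_per_pathway[p])))
  })
  names(pathways) <- spec$pathway_names

  m <- matrix(0, nrow = length(enz_ids), ncol = length(strain_block),
              dimnames = list(enz_ids, names(strain_block)))
  with_seed(spec$seed, {
    for (p in seq_len(spec$n_pathways)) {
      rows <- paste0(spec$pathway_names[p], "_e",
                     seq_len(spec$enzymes_per_pathway[p]))
      for (b in seq_len(spec$n_blocks)) {
        cols <- names(strain_block)[strain_block == spec$block_names[b]]
        n_cells <- length(rows) * length(cols)
        vals <- if (spec$planted_states[p, b] == "present") {
          sample_present(n_cells, spec$lambda_present, spec$dropout)
        } else {
          sample_absent(n_cells, spec$epsilon)
        }
        m[rows, cols] <- vals
      }
    }
  })

  truth <- lapply(seq_len(spec$n_pathways), function(p) {
    leaf_states <- stats::setNames(
      as.integer(spec$planted_states[p, strain_block] == "present"),
      names(strain_block))
    truth_from_leaves(tree, leaf_states)
  })
  names(truth) <- spec$pathway_names

  structure(list(tree = tree, blocks = strain_block,
                 matrix = homology_matrix(m, blocks = strain_block),
                 pathways = pathways, truth = truth, spec = spec),
            class = "synthetic_ensemble")
}

# single-origin truth: every ancestor of a present leaf is present
truth_from_leaves <- function(tree, leaf_states) {
  n_tip <- length(tree$tip.label)
  tc <- tree_children(tree)
  n_nodes <- n_tip + tree$Nnode
  np <- integer(n_nodes)
  np[seq_len(n_tip)] <- leaf_states[tree$tip.label]
  for (k in seq_len(nrow(tc$edge))) {
    e <- tc$edge[k, ]
    np[e[1L]] <- np[e[1L]] + np[e[2L]]
  }
  st <- as.integer(np > 0L)
  lab <- node_labels(tree)
  ed <- tree$edge
  diff <- st[ed[, 1L]] != st[ed[, 2L]]
  list(states = stats::setNames(c("ABSENT", "PRESENT")[st + 1L], lab),
       events = data.frame(
         parent = lab[ed[diff, 1L]],
         child = lab[ed[diff, 2L]],
         event = ifelse(st[ed[diff, 2L]] == 1L, "GAIN", "LOSS"),
         stringsAsFactors = FALSE),
       leaf_states = stats::setNames(np[seq_len(n_tip)] > 0L,
                                     tree$tip.label) * 1L)
}

# node number for a clade label (internal label, block name or tip name)
find_clade <- function(tree, clade) {
  lab <- node_labels(tree)
  node <- match(clade, lab)
  if (is.na(node)) {
    stop("unknown clade '", clade, "'", call. = FALSE)
  }
  node
}

clade_leaves <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  tc <- tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n_tip) out <- c(out, v) else
      stack <- c(stack, tc$children[[v]])
  }
  tree$tip.label[sort(out)]
}

#' Plant a single gain or loss event
#'
#' Flips the planted state of all leaves under a clade for one pathway,
#' regenerates the affected matrix cells (deterministically from the
#' ensemble seed), and records the expected single event on the clade's
#' parent edge in the truth. Planting an event whose end state already
#' holds is a no-op.
#'
#' @param ensemble A [generate_ensemble()] result.
#' @param pathway Pathway ID.
#' @param clade Clade label: a block name, internal node label or leaf
#'   name.
#' @param event `"gain"` (clade becomes present) or `"loss"`.
#' @return The modified `synthetic_ensemble`.
#' @export
plant_event <- function(ensemble, pathway, clade,
                        event = c("loss", "gain")) {
  event <- match.arg(event)
  stopifnot(inherits(ensemble, "synthetic_ensemble"))
  if (!pathway %in% names(ensemble$pathways)) {
    stop("unknown pathway '", pathway, "'", call. = FALSE)
  }
  spec <- ensemble$spec
  node <- find_clade(ensemble$tree, clade)
  leaves <- clade_leaves(ensemble$tree, node)
  target <- if (event == "gain") 1L else 0L

  truth <- ensemble$truth[[pathway]]
  if (all(truth$leaf_states[leaves] == target)) {
    return(ensemble) # idempotent: states already flipped
  }
  truth$leaf_states[leaves] <- target

  # regenerate the affected cells under the new state
  rows <- ensemble$pathways[[pathway]]$enzyme_ids
  n_cells <- length(rows) * length(leaves)
  cell_seed <- (spec$seed * 1009L +
                  sum(utf8ToInt(paste(pathway, clade, event)))) %% 2147483587L
  vals <- with_seed(cell_seed, {
    if (target == 1L) {
      sample_present(n_cells, spec$lambda_present, spec$dropout)
    } else {
      sample_absent(n_cells, spec$epsilon)
    }
  })
  m <- unclass(ensemble$matrix)
  blocks <- attr(ensemble$matrix, "blocks")
  m[rows, leaves] <- vals
  ensemble$matrix <- homology_matrix(m, blocks = blocks)

  # the planted clade becomes uniform at the target state; every node
  # outside it keeps its previous truth state, so exactly one new event
  # appears on the clade's parent edge
  tree <- ensemble$tree
  lab <- node_labels(tree)
  st <- truth$states
  desc <- clade_descendant_labels(tree, node)
  st[desc] <- c("ABSENT", "PRESENT")[target + 1L]
  ed <- tree$edge
  diff <- st[lab[ed[, 1L]]] != st[lab[ed[, 2L]]]
  truth$states <- st
  truth$events <- data.frame(
    parent = lab[ed[diff, 1L]],
    child = lab[ed[diff, 2L]],
    event = ifelse(st[lab[ed[diff, 2L]]] == "PRESENT", "GAIN", "LOSS"),
    stringsAsFactors = FALSE)
  ensemble$truth[[pathway]] <- truth
  ensemble
}

clade_descendant_labels <- function(tree, node) {
  lab <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  tc <- tree_children(tree)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, lab[v])
    if (v > n_tip) stack <- c(stack, tc$children[[v]])
  }
  out
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf(
    "synthetic ensemble: %d blocks, %d strains, %d pathways, %d enzymes\n",
    x$spec$n_blocks, sum(x$spec$strains_per_block), x$spec$n_pathways,
    sum(x$spec$enzymes_per_pathway)))
  cat(sprintf("  lambda_present = %g, epsilon = %g, dropout = %g, seed = %d\n",
              x$spec$lambda_present, x$spec$epsilon, x$spec$dropout,
              x$spec$seed))
  invisible(x)
}

#' Write a synthetic ensemble to a directory
#'
#' Emits the homology matrix (TSV), block map (TSV), tree (Newick),
#' pathway definitions (TSV) and planted truth (JSON).
#'
#' @param ensemble A `synthetic_ensemble`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    blocks = file.path(dir, "blocks.tsv"),
    tree = file.path(dir, "tree.nwk"),
    pathways = file.path(dir, "pathways.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_homology_matrix(ensemble$matrix, paths[["matrix"]])
  writeLines(paste(names(ensemble$blocks), unname(ensemble$blocks),
                   sep = "\t"), paths[["blocks"]])
  write_newick(ensemble$tree, paths[["tree"]])
  rows <- unlist(lapply(ensemble$pathways, function(p) {
    paste(p$pathway_id, p$enzyme_ids, sep = "\t")
  }))
  writeLines(rows, paths[["pathways"]])
  jsonlite::write_json(ensemble$truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Write simulated similarity-search hits
#'
#' Optional adapter for integration tests of the homology module: each
#' non-zero matrix cell `(enzyme i, genome j)` with count `c` becomes `c`
#' rows of BLAST outfmt-6 style output against distinct synthetic subject
#' genes of genome `j`, plus the matching gene-to-genome map.
#'
#' @param ensemble A `synthetic_ensemble`.
#' @param hits_path Output path for the tabular hits.
#' @param gene_map_path Output path for the gene-to-genome TSV.
#' @param evalue E-value written on each row (passes the default cutoff).
#' @return Invisibly, `c(hits_path, gene_map_path)`.
#' @export
write_synthetic_hits <- function(ensemble, hits_path, gene_map_path,
                                 evalue = 1e-20) {
  m <- unclass(ensemble$matrix)
  hits <- character(0)
  map <- character(0)
  for (j in colnames(m)) {
    genes <- character(0)
    for (i in rownames(m)) {
      cnt <- as.integer(m[i, j])
      if (cnt > 0L) {
        subj <- paste0(j, ".", i, ".g", seq_len(cnt))
        genes <- c(genes, subj)
        hits <- c(hits, paste(i, subj, 90, 100, 5, 1, 1, 100, 1, 100,
                              format(evalue, scientific = TRUE), 200,
                              sep = "\t"))
      }
    }
    if (length(genes)) map <- c(map, paste(genes, j, sep = "\t"))
  }
  writeLines(hits, hits_path)
  writeLines(map, gene_map_path)
  invisible(c(hits_path, gene_map_path))
}
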