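#' Parse a rooted Newick tree
#'
#' Reads a rooted, possibly multifurcating Newick string into an
#' [ape::phylo] object. The method operating on these trees is purely
#' topological, so branch lengths and support values are parsed and
#' discarded; only the topology, tip labels and internal-node labels are
#' kept. Tip numbering follows left-to-right order of appearance in the
#' string.
#'
#' @param text A Newick string terminated by `";"`.
#' @return A rooted `phylo` object without edge lengths.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' tr$tip.label
#' @seealso [read_newick()], [write_newick()], [attach_pangenome_leaves()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    stop("empty Newick string", call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("malformed Newick string: missing terminating ';' at position ",
         nchar(text), call. = FALSE)
  }
  # locate unbalanced parentheses before handing off to the grammar parser,
  # so the error can name the offending position
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick string: unmatched ')' at position ", i,
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("malformed Newick string: ", depth,
         " unclosed '(' by position ", nchar(text), call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick string: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("malformed Newick string: not parseable as a tree", call. = FALSE)
  }
  tree$edge.length <- NULL
  validate_pathtree(tree)
  tree
}

#' @rdname parse_newick
#' @param path Path to a `.nwk` file holding one Newick tree.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Structural invariants of a usable species tree: rooted/connected with
# |E| = |V| - 1 (guaranteed by the phylo edge matrix), unique non-empty
# leaf names, internal nodes with >= 1 child.
validate_pathtree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty leaf name", call. = FALSE)
  dup <- unique(tips[duplicated(tips)])
  if (length(dup)) {
    stop("duplicate leaf names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  n_nodes <- length(tips) + tree$Nnode
  if (nrow(tree$edge) != n_nodes - 1L) {
    stop("tree is not connected: expected ", n_nodes - 1L, " edges, found ",
         nrow(tree$edge), call. = FALSE)
  }
  kids <- tabulate(tree$edge[, 1L], nbins = n_nodes)
  if (any(kids[seq_len(tree$Nnode) + length(tips)] < 1L)) {
    stop("internal node without children", call. = FALSE)
  }
  invisible(tree)
}

# children list and postorder internal-node sequence for a phylo tree;
# postorder is derived by an explicit DFS so children always precede
# parents regardless of the edge-matrix row order
tree_children <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  ch <- vector("list", n_nodes)
  for (k in seq_len(nrow(ed))) {
    ch[[ed[k, 1L]]] <- c(ch[[ed[k, 1L]]], ed[k, 2L])
  }
  root <- setdiff(ed[, 1L], ed[, 2L])[1L]
  stack <- root
  rev_post <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    rev_post <- c(rev_post, v)
    kids <- ch[[v]]
    stack <- c(stack, kids[kids > n_tip])
  }
  list(children = ch,
       postorder_internal = rev(rev_post),
       edge = ed,
       root = root)
}

# display labels for all node numbers: tips keep their names, internal
# nodes use their Newick label when present, otherwise "node<k>"
node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  lab <- character(n_tip + tree$Nnode)
  lab[seq_len(n_tip)] <- tree$tip.label
  inner <- tree$node.label
  if (is.null(inner)) inner <- rep("", tree$Nnode)
  inner[is.na(inner)] <- ""
  idx <- !nzchar(inner)
  inner[idx] <- paste0("node", which(idx) + n_tip)
  lab[n_tip + seq_len(tree$Nnode)] <- inner
  lab
}

#' Attach pangenome "virtual genome" leaves
#'
#' A pangenome can be represented on the tree as an extra leaf — a virtual
#' genome standing for the union of all strains of the taxon — attached at
#' the root of the clade spanned by its member strains. For a block with a
#' single member strain the virtual leaf is attached to that strain's
#' parent node (the degenerate clade is the leaf itself, which cannot take
#' children).
#'
#' @param tree A `phylo` object.
#' @param blocks Named character vector mapping leaf (genome) names to
#'   block labels. Blocks need not cover all leaves.
#' @param png_names Named character vector mapping block labels to virtual
#'   leaf names; defaults to `"<block>-png"`.
#' @return The extended `phylo` tree; original leaves are untouched and one
#'   new leaf is added per block.
#' @examples
#' tr <- parse_newick("((E1,E2),(B1,B2));")
#' blocks <- c(E1 = "ECOL", E2 = "ECOL", B1 = "BUCH", B2 = "BUCH")
#' attach_pangenome_leaves(tr, blocks)$tip.label
#' @export
attach_pangenome_leaves <- function(tree, blocks, png_names = NULL) {
  validate_pathtree(tree)
  stopifnot(is.character(blocks), !is.null(names(blocks)))
  block_ids <- unique(unname(blocks))
  if (is.null(png_names)) {
    png_names <- stats::setNames(paste0(block_ids, "-png"), block_ids)
  }
  missing_blocks <- setdiff(block_ids, names(png_names))
  if (length(missing_blocks)) {
    stop("no virtual-leaf name for block(s): ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  }
  for (b in block_ids) {
    members <- names(blocks)[blocks == b]
    absent <- setdiff(members, tree$tip.label)
    if (length(absent)) {
      stop("block '", b, "' members are not leaves of the tree: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    if (png_names[[b]] %in% tree$tip.label) {
      stop("virtual leaf name '", png_names[[b]],
           "' collides with an existing leaf", call. = FALSE)
    }
    if (length(members) >= 2L) {
      node <- ape::getMRCA(tree, members)
    } else {
      tip <- match(members, tree$tip.label)
      node <- tree$edge[tree$edge[, 2L] == tip, 1L]
    }
    tree <- add_child_tip(tree, node, png_names[[b]])
  }
  validate_pathtree(tree)
  tree
}

# add a new tip as an additional child of internal node `node`
# (phylo numbering: tips 1..N, internals N+1..N+Nnode; adding a tip shifts
# every internal node number up by one)
add_child_tip <- function(tree, node, label) {
  n_tip <- length(tree$tip.label)
  ed <- tree$edge
  ed[ed > n_tip] <- ed[ed > n_tip] + 1L
  ed <- rbind(ed, c(node + 1L, n_tip + 1L))
  tree$edge <- ed
  tree$tip.label <- c(tree$tip.label, label)
  tree$edge.length <- NULL
  attr(tree, "order") <- NULL
  tree
}

#' Tabulate a tree (and optional reconstruction) as child/parent rows
#'
#' Serializes the tree into a data frame of `(child, parent, state, event)`
#' rows, one per node (the root has an empty parent). When a fitted
#' [pathtrace()] object is supplied its node states and edge events fill
#' the last two columns; otherwise they are `"UNASSIGNED"`/`"NONE"`.
#'
#' @param tree A `phylo` object.
#' @param fit Optional `pathtrace` object fitted on `tree`.
#' @return A data frame with columns child, parent, state, event.
#' @export
tree_to_nodes <- function(tree, fit = NULL) {
  validate_pathtree(tree)
  lab <- node_labels(tree)
  n_nodes <- length(lab)
  parent <- character(n_nodes)
  ed <- tree$edge
  parent[ed[, 2L]] <- lab[ed[, 1L]]
  state <- rep("UNASSIGNED", n_nodes)
  event <- rep("NONE", n_nodes)
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "pathtrace"))
    state <- unname(fit$states[lab])
    ev <- fit$events
    if (nrow(ev)) event[match(ev$child, lab)] <- ev$event
  }
  data.frame(child = lab, parent = parent, state = state, event = event,
             stringsAsFactors = FALSE)
}

#' Clades at which a planted event is unambiguously recoverable
#'
#' Bottom-up local-majority reconstruction polarizes a single gain or loss
#' on the edge above a clade only when the leaves outside the clade form a
#' strict majority of every ancestral subtree; otherwise the event is
#' absorbed higher up or split. This helper returns the internal nodes
#' (clade roots) satisfying that identifiability condition, used when
#' planting events for recovery experiments.
#'
#' @param tree A `phylo` object.
#' @return Integer vector of internal node numbers (phylo numbering).
#' @export
recoverable_clades <- function(tree) {
  validate_pathtree(tree)
  n_tip <- length(tree$tip.label)
  tc <- tree_children(tree)
  n_nodes <- n_tip + tree$Nnode
  size <- integer(n_nodes)
  size[seq_len(n_tip)] <- 1L
  for (k in seq_len(nrow(tc$edge))) {
    e <- tc$edge[k, ]
    size[e[1L]] <- size[e[1L]] + size[e[2L]]
  }
  parent <- integer(n_nodes)
  parent[tc$edge[, 2L]] <- tc$edge[, 1L]
  ok <- logical(n_nodes)
  for (v in setdiff(n_tip + seq_len(tree$Nnode), tc$root)) {
    u <- v
    good <- TRUE
    repeat {
      u <- parent[u]
      if (size[u] - size[v] <= size[v]) { good <- FALSE; break }
      if (u == tc$root) break
    }
    ok[v] <- good
  }
  which(ok)
}
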