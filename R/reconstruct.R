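#' Parsimony reconstruction of pathway presence on a phylogeny
#'
#' Assigns PRESENT/ABSENT to every node of a rooted (possibly
#' multifurcating) tree from a discrete leaf profile, in a single bottom-up
#' pass, and labels gain/loss events on the edges where the assigned state
#' changes. At each internal node `u` with children `c_1..c_k` the rules
#' are applied in order:
#'
#' * R1 — if all children carry the same assigned state `s`, `u` gets `s`;
#' * R2 — else if `P(u) - A(u) > gain` and present leaves occur in at least
#'   two child subtrees, `u` is PRESENT;
#' * R3 — else if `A(u) - P(u) > loss`, `u` is ABSENT;
#' * R4 — else `u` is PRESENT exactly when `P(u) > A(u)` (ties are ABSENT —
#'   the conservative completion, since absence is the harder claim).
#'
#' `P(u)`/`A(u)` count present/absent leaves in the subtree of `u`
#' (`mode = "leaf"`, the default) or maximal uniformly-present /
#' uniformly-absent clades below `u` (`mode = "event"`, a Dollo-style
#' reading of "potential gains and losses").
#'
#' Note that with the majority fallback R4 the assignment each rule would
#' make coincides with the subtree majority wherever the rule fires, so the
#' reconstruction is invariant to the `gain`/`loss` settings; the
#' thresholds are retained as explicit rule parameters and the full rule
#' cascade is evaluated as stated. See the package vignette for the
#' analysis and its consequences.
#'
#' @param tree A rooted `phylo` object (see [parse_newick()]).
#' @param states Named 0/1 (or logical) vector assigning a state to every
#'   leaf of `tree`, including any virtual pangenome leaves.
#' @param gain Non-negative integer GAIN threshold (default 5).
#' @param loss Non-negative integer LOSS threshold (default 2).
#' @param mode `"leaf"` (count subtree leaves) or `"event"` (count maximal
#'   uniform clades).
#' @param pathway_id Optional label carried into the summary.
#' @return An object of class `pathtrace`: a list with `states` (named
#'   character vector over all nodes), `events` (data frame of parent,
#'   child, event), `root_state`, the inputs and the configuration.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' fit <- pathtrace(tr, c(A = 1, B = 1, C = 1, D = 0))
#' summary(fit)
#' @export
pathtrace <- function(tree, states, gain = 5L, loss = 2L,
                      mode = c("leaf", "event"), pathway_id = NULL) {
  mode <- match.arg(mode)
  validate_pathtree(tree)
  if (!is.numeric(gain) || length(gain) != 1L || is.na(gain) || gain < 0) {
    stop("gain threshold must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(loss) || length(loss) != 1L || is.na(loss) || loss < 0) {
    stop("loss threshold must be a non-negative number", call. = FALSE)
  }
  tips <- tree$tip.label
  if (is.logical(states)) states <- as.integer(states)
  missing <- setdiff(tips, names(states))
  if (length(missing)) {
    stop("no state for leaf/leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- as.integer(states[tips])
  if (anyNA(s) || !all(s %in% c(0L, 1L))) {
    stop("leaf states must be 0/1", call. = FALSE)
  }

  st <- pathtrace_states(tree, s, gain, loss, mode)

  lab <- node_labels(tree)
  ed <- tree$edge
  diff <- st[ed[, 1L]] != st[ed[, 2L]]
  events <- data.frame(
    parent = lab[ed[diff, 1L]],
    child = lab[ed[diff, 2L]],
    event = ifelse(st[ed[diff, 2L]] == 1L, "GAIN", "LOSS"),
    stringsAsFactors = FALSE
  )
  root <- length(tips) + 1L
  structure(list(
    states = stats::setNames(c("ABSENT", "PRESENT")[st + 1L], lab),
    events = events,
    root_state = c("ABSENT", "PRESENT")[st[root] + 1L],
    tree = tree,
    leaf_states = stats::setNames(s, tips),
    gain = gain, loss = loss, mode = mode,
    pathway_id = pathway_id
  ), class = "pathtrace")
}

# single bottom-up pass over the postorder edge list; returns integer 0/1
# state per node (tips 1..N, internals N+1..N+Nnode)
pathtrace_states <- function(tree, s, gain, loss, mode) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  tc <- tree_children(tree)
  ed <- tc$edge

  # subtree tallies of present/absent leaves, one postorder sweep
  np <- integer(n_nodes); na_ <- integer(n_nodes)
  np[seq_len(n_tip)] <- s
  na_[seq_len(n_tip)] <- 1L - s
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; c_ <- ed[k, 2L]
    np[p] <- np[p] + np[c_]
    na_[p] <- na_[p] + na_[c_]
  }

  if (mode == "event") {
    # counts of maximal uniformly-present / uniformly-absent clades:
    # a uniform subtree contributes itself (1), a mixed one the sum over
    # its children
    cp <- integer(n_nodes); ca <- integer(n_nodes)
    cp[seq_len(n_tip)] <- s
    ca[seq_len(n_tip)] <- 1L - s
    for (u in tc$postorder_internal) {
      ch <- tc$children[[u]]
      cp[u] <- if (na_[u] == 0L) 1L else sum(cp[ch])
      ca[u] <- if (np[u] == 0L) 1L else sum(ca[ch])
    }
    P <- cp; A <- ca
  } else {
    P <- np; A <- na_
  }

  st <- integer(n_nodes)
  st[seq_len(n_tip)] <- s
  for (u in tc$postorder_internal) {
    ch <- tc$children[[u]]
    ch_states <- st[ch]
    if (all(ch_states == ch_states[1L])) {            # R1: uniform children
      st[u] <- ch_states[1L]
    } else {
      s2 <- sum(np[ch] > 0L)                          # child subtrees with presence
      if (P[u] - A[u] > gain && s2 >= 2L) {           # R2: gain threshold
        st[u] <- 1L
      } else if (A[u] - P[u] > loss) {                # R3: loss threshold
        st[u] <- 0L
      } else {                                        # R4: majority, tie -> absent
        st[u] <- as.integer(P[u] > A[u])
      }
    }
  }
  st
}

#' @export
print.pathtrace <- function(x, ...) {
  cat("Parsimony pathway reconstruction",
      if (!is.null(x$pathway_id)) paste0(" for '", x$pathway_id, "'"),
      "\n", sep = "")
  cat(sprintf("  tree: %d leaves, %d internal nodes (mode = %s, gain = %d, loss = %d)\n",
              length(x$tree$tip.label), x$tree$Nnode, x$mode,
              as.integer(x$gain), as.integer(x$loss)))
  cat(sprintf("  root state: %s\n", x$root_state))
  n_gain <- sum(x$events$event == "GAIN")
  n_loss <- sum(x$events$event == "LOSS")
  cat(sprintf("  events: %d gain(s), %d loss(es)\n", n_gain, n_loss))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events))) {
      cat(sprintf("    %s on edge %s -> %s\n", x$events$event[i],
                  x$events$parent[i], x$events$child[i]))
    }
  }
  invisible(x)
}

#' Summarize a reconstruction
#'
#' One row per fitted pathway: root state, gain/loss event counts and the
#' clade labels under each event.
#'
#' @param object A `pathtrace` object.
#' @param ... Unused.
#' @return A one-row data frame of class `summary.pathtrace` with columns
#'   pathway, root_state, gains, losses, gain_clades, loss_clades.
#' @export
summary.pathtrace <- function(object, ...) {
  ev <- object$events
  out <- data.frame(
    pathway = if (is.null(object$pathway_id)) NA_character_ else
      object$pathway_id,
    root_state = object$root_state,
    gains = sum(ev$event == "GAIN"),
    losses = sum(ev$event == "LOSS"),
    gain_clades = paste(ev$child[ev$event == "GAIN"], collapse = ","),
    loss_clades = paste(ev$child[ev$event == "LOSS"], collapse = ","),
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.pathtrace", "data.frame")
  out
}

#' @export
as.data.frame.pathtrace <- function(x, ...) {
  tree_to_nodes(x$tree, fit = x)
}

#' Plot a reconstructed pathway history
#'
#' Draws the tree with edges coloured by event (red = gain, blue = loss,
#' black = no change) and node symbols filled when the pathway is inferred
#' present.
#'
#' @param x A `pathtrace` object.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.pathtrace <- function(x, ...) {
  tree <- x$tree
  lab <- node_labels(tree)
  st <- x$states[lab]
  ed <- tree$edge
  col <- rep("black", nrow(ed))
  child_state <- st[ed[, 2L]]
  parent_state <- st[ed[, 1L]]
  col[parent_state == "ABSENT" & child_state == "PRESENT"] <- "red"
  col[parent_state == "PRESENT" & child_state == "ABSENT"] <- "blue"
  ape::plot.phylo(tree, edge.color = col, ...)
  ape::nodelabels(pch = 21,
                  bg = ifelse(st[-seq_along(tree$tip.label)] == "PRESENT",
                              "black", "white"))
  ape::tiplabels(pch = 21,
                 bg = ifelse(st[seq_along(tree$tip.label)] == "PRESENT",
                             "black", "white"))
  invisible(x)
}

#' Reconstruct all pathway profiles of a discrete grid
#'
#' @param tree A rooted `phylo` object whose tips match the grid columns.
#' @param discrete Pathway-by-genome 0/1 matrix (see
#'   [discretize_profile()]).
#' @param ... Passed to [pathtrace()].
#' @return Named list of `pathtrace` fits, one per grid row.
#' @export
pathtrace_all <- function(tree, discrete, ...) {
  stopifnot(is.matrix(discrete))
  fits <- lapply(rownames(discrete), function(p) {
    pathtrace(tree, discrete[p, ], pathway_id = p, ...)
  })
  stats::setNames(fits, rownames(discrete))
}

#' @rdname summary.pathtrace
#' @param fits A list of `pathtrace` objects (see [pathtrace_all()]).
#' @return `summarize_history()` returns one summary row per fit.
#' @export
summarize_history <- function(fits) {
  if (inherits(fits, "pathtrace")) fits <- list(fits)
  do.call(rbind, lapply(fits, summary))
}
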