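# Independent reference implementation of the bottom-up assignment rules,
# written directly from their statement as a plain recursion over the edge
# matrix. Shares no code with the package's optimized traversal; used as
# the oracle in equivalence tests.

oracle_children <- function(tree, v) tree$edge[tree$edge[, 1] == v, 2]

oracle_leaves_under <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(v)
  unlist(lapply(oracle_children(tree, v), oracle_leaves_under, tree = tree))
}

# number of maximal uniformly-`state` clades in the subtree of v
oracle_clades <- function(tree, states01, v, state) {
  lv <- oracle_leaves_under(tree, v)
  vals <- states01[tree$tip.label[lv]]
  if (all(vals == state)) return(1)
  if (all(vals != state)) return(0)
  sum(vapply(oracle_children(tree, v),
             function(c) oracle_clades(tree, states01, c, state), numeric(1)))
}

oracle_assign <- function(tree, states01, v, gain, loss, mode) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(unname(states01[tree$tip.label[v]]))
  ch <- oracle_children(tree, v)
  ch_states <- vapply(ch, function(c)
    oracle_assign(tree, states01, c, gain, loss, mode), numeric(1))
  if (length(unique(ch_states)) == 1) return(ch_states[1])        # R1
  if (mode == "leaf") {
    lv <- states01[tree$tip.label[oracle_leaves_under(tree, v)]]
    P <- sum(lv == 1); A <- sum(lv == 0)
  } else {
    P <- oracle_clades(tree, states01, v, 1)
    A <- oracle_clades(tree, states01, v, 0)
  }
  s2 <- sum(vapply(ch, function(c) {
    any(states01[tree$tip.label[oracle_leaves_under(tree, c)]] == 1)
  }, logical(1)))
  if (P - A > gain && s2 >= 2) return(1)                          # R2
  if (A - P > loss) return(0)                                     # R3
  if (P > A) 1 else 0                                             # R4
}

oracle_reconstruct <- function(tree, states01, gain = 5, loss = 2,
                               mode = "leaf") {
  n_tip <- length(tree$tip.label)
  vapply(seq_len(n_tip + tree$Nnode), function(v)
    oracle_assign(tree, states01, v, gain, loss, mode), numeric(1))
}
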