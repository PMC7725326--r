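test_that("parse_newick handles bifurcations, multifurcations and labels", {
  tr <- parse_newick("(A,B);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$Nnode, 1L)

  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(tr$Nnode, 3L)
  root <- length(tr$tip.label) + 1L
  expect_equal(sum(tr$edge[, 1L] == root), 2L)

  tr <- parse_newick("(A,(B,C),D);")
  expect_equal(length(tr$tip.label), 4L)
  root <- length(tr$tip.label) + 1L
  expect_equal(sum(tr$edge[, 1L] == root), 3L)

  # left-to-right leaf order and internal labels survive
  tr <- parse_newick("((Z,Y)inner,X)top;")
  expect_equal(tr$tip.label, c("Z", "Y", "X"))
  expect_true(all(c("inner", "top") %in% tr$node.label))

  # branch lengths are parsed and discarded
  tr <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
  expect_null(tr$edge.length)
})

test_that("malformed Newick input is rejected with the offending position", {
  expect_error(parse_newick("(A,B)"), "missing terminating ';'")
  expect_error(parse_newick("((A,B);"), "unclosed")
  expect_error(parse_newick("(A,B));"), "position 6")
  expect_error(parse_newick("(A,A);"), "duplicate leaf names: A")
  expect_error(parse_newick(""), "empty")
})

test_that("Newick round-trip preserves topology of random trees", {
  set.seed(42)
  for (i in 1:20) {
    tr <- random_topology(sample(3:15, 1L))
    back <- parse_newick(write_newick(tr))
    expect_true(isTRUE(all.equal(tr, back, use.edge.length = FALSE)))
  }
})

test_that("pangenome leaves attach at the clade root", {
  tr <- parse_newick("((E1,E2),(B1,B2));")
  blocks <- c(E1 = "ECOL", E2 = "ECOL", B1 = "BUCH", B2 = "BUCH")
  out <- attach_pangenome_leaves(tr, blocks)
  expect_equal(length(out$tip.label), 6L)
  expect_setequal(setdiff(out$tip.label, tr$tip.label),
                  c("ECOL-png", "BUCH-png"))
  # each virtual leaf is a child of its block's MRCA
  for (b in c("ECOL", "BUCH")) {
    members <- names(blocks)[blocks == b]
    mrca <- ape::getMRCA(out, members)
    png_tip <- match(paste0(b, "-png"), out$tip.label)
    expect_equal(out$edge[out$edge[, 2L] == png_tip, 1L], mrca)
  }
})

test_that("a single-member block attaches its virtual leaf at the parent", {
  tr <- parse_newick("((E1,X),(B1,B2));")
  out <- attach_pangenome_leaves(tr, c(E1 = "ECOL"))
  e1 <- match("E1", out$tip.label)
  png <- match("ECOL-png", out$tip.label)
  expect_equal(out$edge[out$edge[, 2L] == png, 1L],
               out$edge[out$edge[, 2L] == e1, 1L])
})

test_that("ten strains in five blocks extend to a 15-leaf target set", {
  tr <- parse_newick(
    "((((ECOL_K12,ECOL_DH1),(BAPH_SCH,BAPH_5AX)),((BSUB,BANT),(SPYO,SPNE))),(PABY,PHOR));")
  blocks <- c(ECOL_K12 = "ECOL", ECOL_DH1 = "ECOL",
              BAPH_SCH = "BUCH", BAPH_5AX = "BUCH",
              BSUB = "BACI", BANT = "BACI",
              SPYO = "STRE", SPNE = "STRE",
              PABY = "PYRO", PHOR = "PYRO")
  out <- attach_pangenome_leaves(tr, blocks)
  expect_equal(length(out$tip.label), 15L)
})

test_that("attachment preserves prior ancestry and rejects bad input", {
  set.seed(7)
  tr <- random_topology(8L)
  blocks <- c(t1 = "BL", t2 = "BL")
  out <- attach_pangenome_leaves(tr, blocks)
  expect_equal(length(out$tip.label), 9L)
  expect_true(all(tr$tip.label %in% out$tip.label))
  # clades of the original tree survive: every original internal node's
  # leaf set (minus virtual leaves) is still a clade leaf set
  orig_sets <- lapply(ape::prop.part(tr), function(i) sort(tr$tip.label[i]))
  new_sets <- lapply(ape::prop.part(out), function(i) sort(out$tip.label[i]))
  new_sets <- lapply(new_sets, setdiff, y = "BL-png")
  for (s in orig_sets) {
    expect_true(any(vapply(new_sets, identical, logical(1), y = s)))
  }

  expect_error(attach_pangenome_leaves(tr, c(zz = "BL")),
               "not leaves of the tree: zz")
  expect_error(attach_pangenome_leaves(tr, c(t1 = "BL"),
                                       png_names = c(BL = "t2")),
               "collides")
})

test_that("tree_to_nodes tabulates every node with its parent", {
  tr <- parse_newick("((A,B)ab,C)r;")
  df <- tree_to_nodes(tr)
  expect_equal(nrow(df), 5L)
  expect_equal(df$parent[df$child == "r"], "")
  expect_equal(df$parent[df$child == "A"], "ab")
  expect_true(all(df$state == "UNASSIGNED"))

  fit <- pathtrace(tr, c(A = 1, B = 1, C = 1))
  df2 <- tree_to_nodes(tr, fit)
  expect_true(all(df2$state == "PRESENT"))
  expect_true(all(df2$event == "NONE"))
})

test_that("recoverable clades exclude minority-violating caterpillar blocks", {
  spec <- ensemble_spec(5, rep(4L, 5), 1, 3L, seed = 1L)
  ens <- generate_ensemble(spec)
  ok <- recoverable_clades(ens$tree)
  lab <- ens$tree$node.label
  n_tip <- length(ens$tree$tip.label)
  ok_labels <- lab[ok - n_tip]
  # the two deepest equal-size blocks cannot dominate their first ancestor
  expect_false("B1" %in% ok_labels)
  expect_false("B2" %in% ok_labels)
  expect_true(all(c("B3", "B4", "B5") %in% ok_labels))
})
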