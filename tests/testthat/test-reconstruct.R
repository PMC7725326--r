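test_that("uniform leaf profiles propagate unchanged with zero events", {
  tr <- parse_newick("((a,b),(c,(d,e)));")
  s1 <- stats::setNames(rep(1L, 5), tr$tip.label)
  fit <- pathtrace(tr, s1)
  expect_true(all(fit$states == "PRESENT"))
  expect_equal(nrow(fit$events), 0L)
  expect_equal(fit$root_state, "PRESENT")

  fit0 <- pathtrace(tr, s1 * 0L)
  expect_true(all(fit0$states == "ABSENT"))
  expect_equal(nrow(fit0$events), 0L)
})

test_that("a dominant present clade with an absent sibling loses once", {
  # 10 present leaves in clade X, 2 absent in sibling Y: R2 is blocked by
  # the two-subtree condition (presence only in X), R3 fails, majority
  # keeps the root present, so Y's edge carries the single loss
  nwk <- paste0("((", paste(paste0("x", 1:10), collapse = ","),
                ")X,(y1,y2)Y)root;")
  tr <- parse_newick(nwk)
  s <- stats::setNames(c(rep(1L, 10), 0L, 0L),
                       c(paste0("x", 1:10), "y1", "y2"))
  fit <- pathtrace(tr, s)
  expect_equal(fit$root_state, "PRESENT")
  expect_equal(fit$events$event, "LOSS")
  expect_equal(fit$events$child, "Y")
  sm <- summary(fit)
  expect_equal(sm$gains, 0L)
  expect_equal(sm$losses, 1L)
})

test_that("a lone absent leaf in a present majority is a single loss", {
  nwk <- "((a1,a2,a3,a4,a5)A,(b1,b2,b3,b4,b5)B);"
  tr <- parse_newick(nwk)
  s <- stats::setNames(c(rep(1L, 9), 0L), c(paste0("a", 1:5),
                                            paste0("b", 1:5)))
  names(s)[10] <- "b5"
  fit <- pathtrace(tr, s)
  expect_equal(fit$root_state, "PRESENT")
  expect_equal(fit$events$event, "LOSS")
  expect_equal(fit$events$child, "b5")
})

test_that("presence confined to one leaf cannot reach the root", {
  tr <- parse_newick("((a,b),(c,d),(e,f));")
  s <- stats::setNames(c(1L, rep(0L, 5)), tr$tip.label)
  fit <- pathtrace(tr, s)
  expect_equal(fit$root_state, "ABSENT")
  expect_equal(summary(fit)$gains, 1L)
  expect_equal(summary(fit)$losses, 0L)
})

test_that("reconstruction is deterministic and child-order invariant", {
  s <- c(a = 1L, b = 0L, c = 1L, d = 0L, e = 1L)
  t1 <- parse_newick("((a,b)u,(c,(d,e)v)w)r;")
  t2 <- parse_newick("(((e,d)v,c)w,(b,a)u)r;") # children permuted
  f1 <- pathtrace(t1, s)
  f2 <- pathtrace(t2, s)
  expect_identical(f1$states, pathtrace(t1, s)$states)
  common <- intersect(names(f1$states), names(f2$states))
  expect_equal(f1$states[common], f2$states[common])
})

test_that("optimized traversal equals the naive recursive reference", {
  set.seed(101)
  for (i in 1:150) {
    tr <- random_topology(sample(3:12, 1L))
    s <- random_leaf_states(tr, p = runif(1, 0.2, 0.8))
    gain <- sample(0:8, 1L)
    loss <- sample(0:8, 1L)
    mode <- sample(c("leaf", "event"), 1L)
    fit <- pathtrace(tr, s, gain = gain, loss = loss, mode = mode)
    ref <- oracle_reconstruct(tr, s, gain, loss, mode)
    got <- as.integer(fit$states == "PRESENT")
    expect_equal(got, as.integer(ref),
                 info = sprintf("tree %s gain %d loss %d mode %s",
                                write_newick(tr), gain, loss, mode))
  }
})

test_that("events are exactly the state changes along every path", {
  set.seed(55)
  for (i in 1:30) {
    tr <- random_topology(sample(4:12, 1L))
    s <- random_leaf_states(tr)
    fit <- pathtrace(tr, s)
    df <- as.data.frame(fit)
    st <- stats::setNames(df$state, df$child)
    parent <- stats::setNames(df$parent, df$child)
    ev <- fit$events
    for (tip in tr$tip.label) {
      changes <- 0L
      v <- tip
      while (nzchar(parent[[v]])) {
        if (st[[v]] != st[[parent[[v]]]]) changes <- changes + 1L
        v <- parent[[v]]
      }
      on_path <- 0L
      v <- tip
      while (nzchar(parent[[v]])) {
        on_path <- on_path + sum(ev$child == v & ev$parent == parent[[v]])
        v <- parent[[v]]
      }
      expect_equal(changes, on_path)
    }
    # gain edges go absent -> present, loss edges the reverse
    if (nrow(ev)) {
      expect_true(all(st[ev$child[ev$event == "GAIN"]] == "PRESENT"))
      expect_true(all(st[ev$parent[ev$event == "GAIN"]] == "ABSENT"))
      expect_true(all(st[ev$child[ev$event == "LOSS"]] == "ABSENT"))
      expect_true(all(st[ev$parent[ev$event == "LOSS"]] == "PRESENT"))
    }
  }
})

test_that("leaf-count and event-count modes disagree where clades tie", {
  # one present clade of 10 vs one absent clade of 2: leaf counting keeps
  # the root present, clade counting ties (1 vs 1) and the tie is absent
  nwk <- paste0("((", paste(paste0("x", 1:10), collapse = ","),
                ")X,(y1,y2)Y)root;")
  tr <- parse_newick(nwk)
  s <- stats::setNames(c(rep(1L, 10), 0L, 0L),
                       c(paste0("x", 1:10), "y1", "y2"))
  expect_equal(pathtrace(tr, s, mode = "leaf")$root_state, "PRESENT")
  expect_equal(pathtrace(tr, s, mode = "event")$root_state, "ABSENT")
})

test_that("invalid reconstruction inputs are rejected", {
  tr <- parse_newick("((a,b),(c,d));")
  expect_error(pathtrace(tr, c(a = 1, b = 0, c = 1)), "no state for")
  expect_error(pathtrace(tr, c(a = 1, b = 0, c = 1, d = 2)), "0/1")
  expect_error(pathtrace(tr, c(a = 1, b = 0, c = 1, d = 0), gain = -1),
               "non-negative")
  expect_error(pathtrace(tr, c(a = 1, b = 0, c = 1, d = 0), mode = "zz"))
})

test_that("summarize_history collects one row per pathway", {
  tr <- parse_newick("((a,b)A,(c,d)B)root;")
  grid <- rbind(P1 = c(a = 1, b = 1, c = 1, d = 1),
                P2 = c(a = 1, b = 1, c = 0, d = 0))
  fits <- pathtrace_all(tr, grid)
  sm <- summarize_history(fits)
  expect_equal(sm$pathway, c("P1", "P2"))
  expect_equal(sm$root_state[1L], "PRESENT")
  expect_equal(sm$gains[1L] + sm$losses[1L], 0L)
  # P2: two leaves each way, tie at the root is absent; B stays absent so
  # the A clade carries the single gain
  expect_equal(sm$root_state[2L], "ABSENT")
  expect_equal(sm$gain_clades[2L], "A")
})
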