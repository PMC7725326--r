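test_that("noise-free ensembles discretize to the planted states exactly", {
  planted <- rbind(c("present", "absent", "present"),
                   c("absent", "present", "present"))
  spec <- ensemble_spec(3, c(3L, 4L, 5L), 2, c(4L, 6L),
                        planted_states = planted, seed = 42L)
  ens <- generate_ensemble(spec)
  fz <- fuzzy_profile_matrix(ens$matrix, ens$pathways)
  d <- discretize_profile(fz, 0.5)
  for (p in 1:2) {
    for (g in colnames(d)) {
      b <- ens$blocks[[g]]
      expect_equal(unname(d[p, g]),
                   as.integer(planted[p, match(b, spec$block_names)] ==
                                "present"))
    }
  }
})

test_that("the same spec and seed reproduce the ensemble exactly", {
  spec <- ensemble_spec(3, rep(4L, 3), 2, c(3L, 5L), epsilon = 0.1,
                        dropout = 0.1, seed = 7L)
  e1 <- generate_ensemble(spec)
  e2 <- generate_ensemble(spec)
  expect_identical(unclass(e1$matrix), unclass(e2$matrix))
  expect_identical(write_newick(e1$tree), write_newick(e2$tree))
  e3 <- generate_ensemble(ensemble_spec(3, rep(4L, 3), 2, c(3L, 5L),
                                        epsilon = 0.1, dropout = 0.1,
                                        seed = 8L))
  expect_false(identical(unclass(e1$matrix), unclass(e3$matrix)))
})

test_that("a ten-block layout with published strain counts has 249 columns", {
  spec <- ensemble_spec(10, c(4L, 20L, 48L, 78L, 27L, 4L, 6L, 46L, 8L, 8L),
                        1, 2L, seed = 1L)
  ens <- generate_ensemble(spec)
  expect_equal(ncol(ens$matrix), 249L)
  expect_equal(length(ens$tree$tip.label), 249L)
})

test_that("planting a loss records exactly one loss on the clade edge", {
  spec <- ensemble_spec(4, rep(4L, 4), 1, 5L, seed = 3L)
  ens <- generate_ensemble(spec)
  ens <- plant_event(ens, "P1", "B3", "loss")
  tr <- ens$truth$P1
  expect_equal(nrow(tr$events), 1L)
  expect_equal(tr$events$event, "LOSS")
  expect_equal(tr$events$child, "B3")
  # matrix cells under the clade were zeroed (noise-free)
  strains <- names(ens$blocks)[ens$blocks == "B3"]
  expect_true(all(unclass(ens$matrix)[, strains] == 0))
  # idempotence
  again <- plant_event(ens, "P1", "B3", "loss")
  expect_identical(again$truth, ens$truth)
  expect_error(plant_event(ens, "P1", "nope", "loss"), "unknown clade")
  expect_error(plant_event(ens, "P9", "B3", "loss"), "unknown pathway")
})

test_that("planting a gain on an absent pathway yields one gain edge", {
  planted <- matrix("absent", 1, 4)
  spec <- ensemble_spec(4, rep(4L, 4), 1, 5L, planted_states = planted,
                        seed = 4L)
  ens <- generate_ensemble(spec)
  ens <- plant_event(ens, "P1", "B4", "gain")
  tr <- ens$truth$P1
  expect_equal(tr$events$event, "GAIN")
  expect_equal(tr$events$child, "B4")
  expect_equal(unname(tr$states[["root"]]), "ABSENT")
  strains <- names(ens$blocks)[ens$blocks == "B4"]
  expect_true(all(unclass(ens$matrix)[, strains] >= 1))
})

test_that("present-cell means track lambda and dropout", {
  spec <- ensemble_spec(1, 100L, 1, 100L, lambda_present = 2.5,
                        dropout = 0.2, seed = 12L)
  ens <- generate_ensemble(spec)
  cells <- as.numeric(unclass(ens$matrix))
  expect_equal(length(cells), 10000L)
  mu <- 2.5 * 0.8
  # variance of the shifted-Poisson-with-dropout cell value
  ev2 <- 0.8 * (1.5 + (1 + 1.5)^2) # E[X^2 | kept], X = 1 + Pois(1.5)
  se <- sqrt((ev2 - mu^2) / length(cells))
  expect_lt(abs(mean(cells) - mu), 3 * se)
})

test_that("invalid ensemble specs are rejected", {
  expect_error(ensemble_spec(3, c(2L, 2L), 1, 1L), "length n_blocks")
  expect_error(ensemble_spec(2, c(2L, 2L), 2, 3L), "length n_pathways")
  expect_error(ensemble_spec(1, 2L, 1, 1L, epsilon = 1.2), "\\[0, 1\\)")
  expect_error(ensemble_spec(1, 2L, 1, 1L, lambda_present = 0.5), ">= 1")
  expect_error(ensemble_spec(1, 2L, 1, 1L,
                             planted_states = matrix("maybe", 1, 1)),
               "present")
})

test_that("simulated hits round-trip through homologue counting", {
  spec <- ensemble_spec(2, c(3L, 3L), 2, c(2L, 3L),
                        planted_states = rbind(c("present", "absent"),
                                               c("absent", "present")),
                        epsilon = 0.1, seed = 21L)
  ens <- generate_ensemble(spec)
  hits_fp <- tempfile(); map_fp <- tempfile()
  write_synthetic_hits(ens, hits_fp, map_fp)
  g2g <- read_id_map(map_fp)
  m <- count_homologues(read_blast_hits(hits_fp), g2g,
                        rownames(ens$matrix), colnames(ens$matrix),
                        blocks = ens$blocks)
  expect_equal(unclass(m)[rownames(ens$matrix), colnames(ens$matrix)],
               unclass(ens$matrix)[, ], ignore_attr = TRUE)
})

test_that("ensembles serialize to plain-text files", {
  spec <- ensemble_spec(2, c(2L, 3L), 1, 2L, seed = 9L)
  ens <- generate_ensemble(spec)
  dir <- tempfile()
  paths <- write_ensemble(ens, dir)
  expect_true(all(file.exists(paths)))
  back <- read_homology_matrix(paths[["matrix"]])
  expect_equal(unclass(back)[, colnames(ens$matrix)],
               unclass(ens$matrix)[, ], ignore_attr = TRUE)
  tr <- read_newick(paths[["tree"]])
  expect_setequal(tr$tip.label, ens$tree$tip.label)
})

test_that("balanced block clades are bifurcating", {
  spec <- ensemble_spec(2, c(4L, 5L), 1, 2L, seed = 2L, balanced = TRUE)
  ens <- generate_ensemble(spec)
  deg <- table(ens$tree$edge[, 1L])
  expect_true(all(deg == 2L))
})
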