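# Tree parsing/validation, SIMMAP histories, shared-path segments and the
# event timeline.

test_that("parse_newick reads ultrametric binary trees and rejects violations", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tree_height(tr), 2)
  expect_equal(unname(node_depths(tr)[1:3]), c(2, 2, 2))

  expect_error(parse_newick("((A:1,B:2):1,C:2);"), "B")
  expect_error(parse_newick("((A:1,B:1,C:1):1,D:2);"), "polytom")
  expect_error(parse_newick("((A:1,B:1):-1,C:0);"), "negative")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("branching structure of a balanced four-tip tree is as enumerated", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  d <- node_depths(tr)
  ntip <- 4L
  internal_depths <- sort(d[(ntip + 1L):(ntip + tr$Nnode)])
  expect_equal(internal_depths, c(0, 1, 1))
  tl <- build_event_timeline(tr)
  n_alive <- vapply(tl$intervals, function(iv) length(iv$lineages), integer(1))
  expect_equal(n_alive, c(2L, 4L))
  expect_equal(tl$times, c(0, 1, 2))
})

test_that("round trip through the serializer preserves topology and segments", {
  fx <- random_fixture(5, n_tips = 8)
  txt <- write_simmap(fx$regimes)
  re <- parse_simmap(txt, alphabet = two_state, ref_tree = fx$tree)
  rh <- regime_history(re$tree, re$maps, alphabet = two_state)
  expect_equal(sort(re$tree$tip.label), sort(fx$tree$tip.label))
  o <- compevol:::match_edges(re$tree, fx$tree)
  for (e in seq_along(rh$maps)) {
    expect_equal(rh$maps[[e]], fx$regimes$maps[[o[e]]], tolerance = 1e-9)
  }
})

test_that("parse_simmap reads the curly-brace dialect root-ward first", {
  h <- parse_simmap("((A:{0,0.4:1,0.6},B:{0,1}):{0,1},C:{0,2});")
  eA <- which(h$tree$edge[, 2] == match("A", h$tree$tip.label))
  expect_equal(h$maps[[eA]], c("0" = 0.4, "1" = 0.6))
  eB <- which(h$tree$edge[, 2] == match("B", h$tree$tip.label))
  expect_equal(h$maps[[eB]], c("0" = 1))
  expect_equal(h$tree$edge.length[eA], 1)
  expect_error(parse_simmap("((A:{0,0.4:1,0.6},B:{0,1}):{0,1},C:{0,2});",
                            alphabet = c("0")), "unknown state")
})

test_that("segment durations must tile the reference branch lengths", {
  ref <- parse_newick("((A:1,B:1):1,C:2);")
  bad <- "((A:{0,0.4:1,0.5},B:{0,1}):{0,1},C:{0,2});"  # sums to 0.9 on a 1.0 branch
  expect_error(parse_simmap(bad, ref_tree = ref), "0.9")
  good <- "((A:{0,0.4:1,0.6},B:{0,1}):{0,1},C:{0,2});"
  expect_silent(parse_simmap(good, ref_tree = ref))
})

test_that("regime_history validates tiling and alphabet", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  maps <- lapply(seq_len(nrow(tr$edge)), function(e)
    stats::setNames(tr$edge.length[e], "A"))
  expect_s3_class(regime_history(tr, maps, alphabet = c("A", "B")), "regime_history")
  bad <- maps; bad[[1]] <- stats::setNames(0.5 * tr$edge.length[1], "A")
  expect_error(regime_history(tr, bad, alphabet = c("A", "B")), "sum")
  bad2 <- maps; names(bad2[[2]]) <- "Z"
  expect_error(regime_history(tr, bad2, alphabet = c("A", "B")), "unknown")
})

test_that("shared path segments sum to MRCA depth (or T on the diagonal)", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  segs <- shared_path_segments(tr, NULL, "A", "B")
  expect_equal(sum(segs$duration), 1)
  expect_equal(nrow(shared_path_segments(tr, NULL, "A", "C")), 0L)
  expect_equal(sum(shared_path_segments(tr, NULL, "A", "A")$duration), 2)
  expect_error(shared_path_segments(tr, NULL, "A", "Z"), "unknown tip")

  fx <- random_fixture(9, n_tips = 7)
  d <- node_depths(fx$tree)
  for (pair in list(c(1, 2), c(1, 7), c(3, 3))) {
    i <- pair[1]; j <- pair[2]
    segs <- shared_path_segments(fx$tree, fx$regimes, i, j)
    target <- if (i == j) i else ape::getMRCA(fx$tree, pair)
    expect_equal(sum(segs$duration), d[target], tolerance = 1e-10)
  }
})

test_that("timeline interval count and sympatry matrices obey the invariants", {
  for (seed in c(2, 3, 4)) {
    fx <- random_fixture(seed, n_tips = 8, with_biogeo = TRUE)
    tl <- build_event_timeline(fx$tree, fx$regimes, fx$biogeo)
    n_branch <- fx$tree$Nnode - 1L  # the root split opens the timeline
    n_switch <- sum(vapply(fx$regimes$maps, length, integer(1)) - 1L)
    n_occ <- sum(vapply(fx$biogeo$maps, length, integer(1)) - 1L)
    expect_equal(length(tl$intervals), n_branch + n_switch + n_occ + 1L)
    for (iv in tl$intervals) {
      expect_true(all(iv$A %in% c(0, 1)))
      expect_equal(iv$A, t(iv$A))
      expect_equal(unname(diag(iv$A)), rep(1, length(iv$lineages)))
    }
    n_alive <- vapply(tl$intervals, function(iv) length(iv$lineages), integer(1))
    expect_true(all(diff(n_alive) >= 0))
    expect_true(all(diff(tl$times) > 0))
  }
})

test_that("without biogeography the sympatry matrix is all ones", {
  fx <- random_fixture(6, n_tips = 5)
  tl <- build_event_timeline(fx$tree, fx$regimes)
  for (iv in tl$intervals) {
    expect_equal(iv$A, matrix(1, length(iv$lineages), length(iv$lineages)))
  }
})

test_that("disjoint occupancy yields a block-diagonal sympatry matrix", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # left clade in area 1, right clade in area 2, root in both
  pat <- c(A = "10", B = "10", C = "01", D = "01")
  maps <- lapply(seq_len(nrow(tr$edge)), function(e) {
    v <- tr$edge[e, 2]
    lab <- if (v <= 4) pat[tr$tip.label[v]] else if (v == 6) "10" else "01"
    stats::setNames(tr$edge.length[e], lab)
  })
  bio <- suppressWarnings(biogeo_history(tr, maps, areas = c("west", "east")))
  tl <- build_event_timeline(tr, NULL, bio)
  last <- tl$intervals[[length(tl$intervals)]]
  lab <- tr$tip.label[last$lineages]
  A <- last$A; dimnames(A) <- list(lab, lab)
  expect_equal(A["A", "B"], 1)
  expect_equal(A["C", "D"], 1)
  expect_equal(A["A", "C"], 0)
  expect_equal(A["B", "D"], 0)
})

test_that("histories on a mismatched topology are rejected", {
  fx <- random_fixture(2, n_tips = 6)
  other <- simulate_bd_tree(6, 0.3, 0.1, seed = 999)
  expect_error(build_event_timeline(other, fx$regimes), "topology")
})

test_that("regime collapse is a projection and merges adjacent segments", {
  tr <- simulate_bd_tree(12, 0.3, 0.05, seed = 31)
  Q <- mk_generator(rep(0.1, 6), c("tropical", "temperate", "both"))
  h3 <- simulate_regime_history(tr, Q, seed = 7)
  h2 <- collapse_regimes(h3)
  expect_setequal(unique(unlist(lapply(h2$maps, names))) %in% two_state,
                  TRUE)
  h22 <- collapse_regimes(h2)
  expect_equal(h22$maps, h2$maps)
  # durations preserved branch by branch
  expect_equal(vapply(h2$maps, sum, numeric(1)),
               vapply(h3$maps, sum, numeric(1)))
  # no adjacent same-label segments survive
  for (segs in h2$maps) {
    if (length(segs) > 1) {
      expect_true(all(names(segs)[-1] != names(segs)[-length(segs)]))
    }
  }
  expect_equal(collapse_state(c("both", "tropical", "temperate")),
               c("temperate", "tropical", "temperate"))
  expect_error(collapse_state("polar"), "unknown")
})

test_that("trait tables validate and align with trees", {
  td <- trait_data(c("A", "B", "C"), c(1, 2, 3), n = c(4, 5, 6), se2 = 0.1)
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  al <- compevol:::align_traits(td, tr)
  expect_equal(al$species, tr$tip.label)
  expect_error(trait_data(c("A", "A"), c(1, 2)), "duplicate")
  expect_error(trait_data("A", 1, se2 = -1), "standard errors")
  td2 <- trait_data(c("A", "B"), c(1, 2))
  expect_error(compevol:::align_traits(td2, tr), "C")
  f <- tempfile(fileext = ".csv")
  write_trait_data(td, f)
  back <- read_trait_data(f)
  expect_equal(back$mean, td$mean)
  unlink(f)
})
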