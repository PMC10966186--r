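test_that("read_topology parses labels and rejects malformed input", {
  phy <- read_topology(text = "((A,B),C);")
  expect_equal(ape::Ntip(phy), 3L)
  expect_equal(phy$Nnode, 2L)
  phy2 <- read_topology(text = "(('†X',B)N1,C)R;")
  expect_true(all(c("N1", "R") %in% phy2$node.label))
  expect_true("†X" %in% phy2$tip.label)
  expect_error(read_topology(text = "((A,B),C;"), "malformed Newick")
  expect_error(read_topology(text = "((A,B),(C);"), "malformed Newick")
})

test_that("strat ranges validate and sample_tip_ages follows the uniform law", {
  expect_error(strat_ranges("X", 10, 20), "fad >= lad")
  expect_error(strat_ranges(c("X", "X"), c(1, 2), c(0, 0)), "duplicate")
  rng <- strat_ranges(c("A", "B", "C"), c(259, 290, 0), c(259, 280, 0))
  a1 <- sample_tip_ages(rng, seed = 5)
  expect_identical(a1[["A"]], 259)        # degenerate interval, exact
  expect_identical(a1[["C"]], 0)          # extant, exact zero
  expect_identical(sample_tip_ages(rng, seed = 5), a1)  # reproducible
  expect_error(sample_tip_ages(rng, tips = c("A", "Z")), "Z")

  big <- strat_ranges("B", 290, 280)
  set.seed(33)
  draws <- replicate(1e4, sample_tip_ages(big)[["B"]])
  expect_true(all(draws >= 280 & draws <= 290))
  expect_equal(mean(draws), 285, tolerance = 0.1 / 285)
})

test_that("basic node ages take the oldest descendant", {
  phy <- read_topology(text = "((A,B)n1,C)r;")
  age <- basic_node_ages(phy, c(A = 300, B = 280, C = 250))
  expect_equal(unname(age[4:5]), c(300, 300))  # root, cherry
  age0 <- basic_node_ages(phy, c(A = 0, B = 0, C = 0))
  expect_true(all(age0 == 0))
  expect_error(basic_node_ages(phy, c(A = 1, B = 1)), "C")
})

test_that("'equal' spaces undatable nodes evenly and keeps dated nodes", {
  # zero run n1 -> n2 at 270 below the root; root itself shares a zero branch
  # with its oldest tip D(300) so it takes the buffer, then n1, n2 are spread
  # in equal steps between the buffered root and the 270 bound
  phy <- read_topology(text = "(((A,B)n2,C)n1,D)r;")
  te <- timescale_equal(phy, c(A = 270, B = 100, C = 150, D = 300),
                        root_buffer = 10)
  a <- node_ages(te)
  lab <- node_label_vector(te)
  expect_equal(a[lab == "r"], 310)
  gaps <- diff(c(a[lab == "r"], a[lab == "n1"], a[lab == "n2"], 270))
  expect_equal(gaps, rep(-40 / 3, 3), tolerance = 1e-12)  # even spacing
  expect_true(all(te$edge.length > 0))
  # tips never move
  expect_equal(unname(a[match(c("A", "B", "C", "D"), lab)]), c(270, 100, 150, 300))

  # sibling zero-length cherries under one (buffered) node: respaced
  # independently, each to the midpoint
  phy2 <- read_topology(text = "((A,B)c1,(C,D)c2)r;")
  te2 <- timescale_equal(phy2, c(A = 200, B = 200, C = 200, D = 200),
                         root_buffer = 10)
  a2 <- node_ages(te2); lab2 <- node_label_vector(te2)
  expect_equal(a2[lab2 == "r"], 210)
  expect_equal(a2[lab2 == "c1"], 205)
  expect_equal(a2[lab2 == "c2"], 205)

  expect_error(timescale_equal(phy2, c(A = 200, B = 200, C = 200, D = 200),
                               root_buffer = 0), "cannot date root")

  # every internal node touches its oldest descendant tip through a zero
  # branch, so each run is respaced under its (already final) head
  phy3 <- read_topology(text = "(((A,B)n2,C)n1,D)r;")
  te3 <- timescale_equal(phy3, c(A = 250, B = 240, C = 290, D = 310))
  a3 <- node_ages(te3); lab3 <- node_label_vector(te3)
  expect_equal(a3[lab3 == "r"], 320)                 # buffered above tip D
  expect_equal(a3[lab3 == "n1"], (320 + 290) / 2)    # midpoint above tip C
  expect_equal(a3[lab3 == "n2"], (305 + 250) / 2)    # midpoint above tip A
})

test_that("'mbl' ratchets ancestors by the minimum and touches no tip", {
  phy <- read_topology(text = "((A,B)c,D)r;")
  tm <- timescale_mbl(phy, c(A = 300, B = 300, D = 100))
  a <- node_ages(tm); lab <- node_label_vector(tm)
  expect_equal(a[lab == "c"], 301)
  expect_equal(a[lab == "r"], 302)
  # stacked zero branches ratchet one minimum per level
  phy2 <- read_topology(text = "(((A,B)n2,C)n1,D)r;")
  tm2 <- timescale_mbl(phy2, c(A = 300, B = 300, C = 300, D = 300))
  a2 <- node_ages(tm2); lab2 <- node_label_vector(tm2)
  expect_equal(unname(a2[match(c("n2", "n1", "r"), lab2)]), c(301, 302, 303))
  # an already-satisfying configuration is a fixed point
  tm3 <- timescale_mbl(phy2, c(A = 250, B = 200, C = 280, D = 310))
  expect_equal(unname(node_ages(tm3)[match(c("n2", "n1", "r"), lab2)]),
               c(251, 281, 311))
  expect_error(timescale_mbl(phy, c(A = 1, B = 1, D = 1), min_len = 0), "positive")
})

test_that("both algorithms keep the dating invariants on random instances", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    phy <- ape::rtree(n)
    phy$edge.length <- NULL
    lad <- stats::runif(n, 0, 250)
    fad <- lad + stats::runif(n, 0, 30)
    extant <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
    fad[extant] <- 0; lad[extant] <- 0
    rng <- strat_ranges(phy$tip.label, fad, lad)
    ages <- sample_tip_ages(rng, seed = i)
    te <- timescale_equal(phy, ages)
    tm <- timescale_mbl(phy, ages)
    expect_true(all(te$edge.length > 0))
    expect_true(all(tm$edge.length >= 1 - 1e-9))
    for (tr in list(te, tm)) {
      a <- node_ages(tr)
      expect_equal(unname(a[seq_len(n)]), unname(ages[phy$tip.label]))
      expect_true(all(a[tr$edge[, 1]] > a[tr$edge[, 2]]))
    }
    # determinism given tip ages
    expect_identical(node_ages(timescale_equal(phy, ages)), node_ages(te))
    expect_identical(node_ages(timescale_mbl(phy, ages)), node_ages(tm))
  }
})

test_that("timescale_ensemble writes readable Newick with durations", {
  phy <- read_topology(text = "((A,B)n1,C)r;")
  rng <- strat_ranges(c("A", "B", "C"), c(300, 290, 0), c(290, 280, 0))
  trees <- timescale_ensemble(phy, rng, method = "mbl", reps = 3, seed = 9)
  expect_length(trees, 3L)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_timescaled(trees[[1]], f)
  back <- read_topology(f)
  expect_equal(sort(back$tip.label), sort(phy$tip.label))
  expect_equal(sum(back$edge.length), sum(trees[[1]]$edge.length), tolerance = 1e-8)
})
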