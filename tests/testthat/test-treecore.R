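# Tree model, Newick I/O, fixtures and the brute-force MRCA oracle

test_that("node times are reconstructed by summing branch lengths", {
  tr <- read_newick("((A|A:5,B|A:5):5,C|A:10);")
  expect_equal(tr$present, 10)
  ab <- mrca_oracle(tr, c("A", "B"))
  expect_equal(node_time(tr, ab), 5)
  # all three tips are extant and span both origin lineages
  expect_identical(mrca_oracle(tr, c("A", "B", "C")), "origin")
})

test_that("fixture trees round-trip through Newick with times intact", {
  cat_tab <- fixture_catalogue()
  for (nm in cat_tab$name) {
    tr <- make_fixture(nm)
    tr2 <- read_newick(write_newick(tr), present_time = tr$present)
    expect_equal(node_time_profile(tr2), node_time_profile(tr),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(n_extant(tr2), n_extant(tr))
    # a second pass is the canonical form of the first
    expect_identical(write_newick(read_newick(write_newick(tr2))),
                     write_newick(tr2))
  }
})

test_that("shipped Newick catalogue matches the in-code fixture builder", {
  cat_tab <- fixture_catalogue()
  for (i in seq_len(nrow(cat_tab))) {
    f <- system.file("extdata", cat_tab$file[i], package = "crownsim")
    expect_true(nzchar(f))
    tr <- read_newick(file = f, present_time = cat_tab$present[i])
    ref <- make_fixture(cat_tab$name[i])
    expect_equal(node_time_profile(tr), node_time_profile(ref),
                 tolerance = 1e-9)
    expect_equal(n_extant(tr), cat_tab$n_extant[i])
    if (is.na(cat_tab$crown_time[i])) {
      expect_error(crown_time(tr), class = "crownsim_undefined_crown")
    } else {
      expect_equal(crown_time(tr), cat_tab$crown_time[i])
      expect_equal(crown_time(ref), cat_tab$crown_time[i])
    }
  }
})

test_that("simulated trees round-trip through Newick within 1e-9", {
  trees <- c(random_trees(60, 0.5, 0.5, 8, seed = 101),
             random_trees(20, 0.6, 0.2, 6, seed = 202),
             random_trees(20, 0.2, 0.6, 10, seed = 303))
  for (tr in trees) {
    tr2 <- read_newick(write_newick(tr), present_time = tr$present)
    expect_equal(node_time_profile(tr2), node_time_profile(tr),
                 tolerance = 1e-9)
    expect_equal(n_extant(tr2), n_extant(tr))
  }
})

test_that("extant-only export prunes extinct lineages, keeping path lengths", {
  expect_identical(write_newick(make_fixture("one_side_extinct"),
                                extant_only = TRUE),
                   "(A|A:6,B|A:6):4;")
  expect_identical(write_newick(make_fixture("five_tip_mixed"),
                                extant_only = TRUE),
                   "((A|A:5,B|A:5):3,C|A:8):2;")
  # a single survivor still serializes with its full path length
  expect_identical(write_newick(make_fixture("single_survivor"),
                                extant_only = TRUE), "A|A:8;")
  # nothing extant: refuse to prune
  dead <- bd_tree(birth = c(0, 0), death = c(2, 3), parent = c(NA, NA),
                  extant = c(FALSE, FALSE), present = 5)
  expect_error(write_newick(dead, extant_only = TRUE),
               class = "crownsim_no_extant")
})

test_that("parse errors name the offending character", {
  expect_error(read_newick("((A|A:5,B|A:5):5,C|A:10));"),
               "character", class = "crownsim_parse")
  expect_error(read_newick("((A|A:5,B|A:-5):5,C|A:10);"),
               "negative branch length at character 12",
               class = "crownsim_invalid_tree")
  expect_error(read_newick("((A|A:5,B:5):5,C|A:10);"),
               "status suffix", class = "crownsim_parse")
  expect_error(read_newick("((A|A:5,B|A:5):5,C|A:10):2;"),
               "root edge", class = "crownsim_parse")
})

test_that("the MRCA oracle handles tips, origin pairs and permutations", {
  tr <- make_fixture("five_tip_mixed")
  # single lineage is its own MRCA
  a <- match("A", tr$labels)
  expect_identical(mrca_oracle(tr, a), a)
  # the two origin lineages join only at the initial split
  expect_identical(mrca_oracle(tr, which(is.na(tr$parent))), "origin")
  # the three extant tips coalesce at the documented crown split (t = 2)
  m <- mrca_oracle(tr, c("A", "B", "C"))
  expect_equal(node_time(tr, m), 2)
  # permutation invariance
  for (perm in list(c("C", "A", "B"), c("B", "C", "A"))) {
    expect_identical(mrca_oracle(tr, perm), m)
  }
  expect_error(mrca_oracle(tr, "nope"), class = "crownsim_bad_query")
  expect_error(mrca_oracle(tr, integer(0)), class = "crownsim_bad_query")
})

test_that("MRCA of a nested tip set is ancestral-or-equal to the subset's", {
  trees <- random_trees(25, 0.5, 0.5, 15, seed = 404, min_extant = 3L)
  ancestor_path <- function(tree, id) {
    p <- id
    while (!is.na(tree$parent[p[length(p)]]))
      p <- c(p, tree$parent[p[length(p)]])
    c(p, 0L)  # 0 stands for the origin
  }
  set.seed(1)
  for (tr in trees) {
    tips <- extant_ids(tr)
    sub <- sample(tips, max(2L, length(tips) %/% 2L))
    mB <- mrca_oracle(tr, tips)          # full tip set
    mA <- mrca_oracle(tr, sub)           # nested subset
    if (identical(mA, "origin")) {
      expect_identical(mB, "origin")
    } else if (!identical(mB, "origin")) {
      expect_true(mB %in% ancestor_path(tr, mA))
    }
    expect_lte(node_time(tr, mB), node_time(tr, mA))
  }
})

test_that("unknown fixture names are rejected with the valid list", {
  expect_error(make_fixture("no_such_tree"), "five_tip_mixed",
               class = "crownsim_bad_fixture")
})
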