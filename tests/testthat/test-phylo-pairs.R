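# Tree reading, cluster detection, representatives, and independent pairs.

test_that("Newick reading handles polytomies and rejects malformed input", {
  expect_equal(ape::Ntip(read_species_tree("(A,B);")), 2L)
  expect_equal(ape::Ntip(read_species_tree("((A,B,C),D);")), 4L)
  expect_error(read_species_tree("(A,(B,A));"), "duplicate")
  expect_error(read_species_tree("((A,B);"), "parse failure")
  expect_warning(read_species_tree("((A,B),C);", species = c("A", "B")),
                 "absent from the species list.*C")
})

test_that("packaged tree and table cross-reference exactly", {
  tab <- neosex_karyotypes()
  expect_silent(tree <- read_species_tree(neosex_fixture_path("tree"),
                                          species = tab$species_key))
  expect_equal(sort(tree$tip.label), sort(tab$species_key))
})

test_that("maximal same-system clades are recovered on the packaged tree", {
  fx <- fixture_bundle()
  units <- fx$units
  n_members <- vapply(units, function(u) length(u$members), 0L)
  systems <- vapply(units, `[[`, "", "system")

  expect_equal(unname(n_members[["Gazella_XY1Y2"]]), 6L)
  expect_equal(unname(n_members[["Taterillus_XY1Y2"]]), 6L)
  # congeneric Mus split into two singleton units of opposite systems
  expect_equal(unname(n_members[["Mus_X1X2Y"]]), 1L)
  expect_equal(unname(n_members[["Mus_XY1Y2"]]), 1L)
  expect_equal(sum(systems == "XY1Y2"), 9L)
  expect_equal(sum(systems == "X1X2Y"), 10L)
  # units partition the analysis tips
  members <- unname(unlist(lapply(units, `[[`, "members")))
  expect_equal(sort(members), sort(fx$tab$species_key))

  # every unit is monophyletic and system-homogeneous (independent check)
  smap <- stats::setNames(fx$tab$system, fx$tab$species_key)
  for (u in units) {
    expect_equal(unique(unname(smap[u$members])), u$system)
    if (length(u$members) > 1) {
      mrca <- ape::getMRCA(fx$tree, u$members)
      clade <- ape::extract.clade(fx$tree, mrca)
      expect_setequal(clade$tip.label, u$members)
    }
  }
})

test_that("degenerate system maps are handled", {
  tree <- read_species_tree("(gx_a,gy_b);")
  units <- find_system_clusters(tree, c(gx_a = "X1X2Y", gy_b = "XY1Y2"))
  expect_equal(length(units), 2L)
  expect_equal(vapply(units, function(u) length(u$members), 0L),
               c(gx_X1X2Y = 1L, gy_XY1Y2 = 1L))
  expect_error(find_system_clusters(tree, c(gx_a = "X1X2Y")),
               "lacking a system label")
})

test_that("cluster representatives follow mean and random modes", {
  fx <- fixture_bundle()
  gaz <- fx$units[["Gazella_XY1Y2"]]
  expect_equal(round(cluster_value(gaz, fx$tab, mode = "mean"), 3), 0.138)
  # singleton: both modes return the member's own value
  tra <- fx$units[["Tragelaphus_X1X2Y"]]
  expect_equal(cluster_value(tra, fx$tab, mode = "mean"), 0.19)
  expect_equal(cluster_value(tra, fx$tab, mode = "random"), 0.19)
  # random draws stay inside the member multiset and are seed-reproducible
  vals <- fx$tab$female_frac_acro[fx$tab$genus == "Gazella"]
  set.seed(3)
  draws <- replicate(50, cluster_value(gaz, fx$tab, mode = "random"))
  expect_true(all(draws %in% vals))
  set.seed(3)
  expect_identical(draws,
                   replicate(50, cluster_value(gaz, fx$tab, mode = "random")))
  # mean mode ignores member order
  gaz_rev <- gaz
  gaz_rev$members <- rev(gaz$members)
  expect_identical(cluster_value(gaz_rev, fx$tab), cluster_value(gaz, fx$tab))
})

test_that("explicit pair configurations are validated", {
  fx <- fixture_bundle()
  expect_equal(nrow(fx$pairs), 9L)
  expect_equal(attr(fx$pairs, "pairing"), "explicit")
  # config order preserved
  cfg <- read_pair_config(neosex_fixture_path("pairs"))
  expect_equal(fx$pairs$x1x2y, cfg$x1x2y)

  expect_error(build_pairs(fx$tree, fx$units,
                           data.frame(x1x2y = "Gazella_XY1Y2",
                                      xy1y2 = "Gazella_XY1Y2")),
               "oppose")
  expect_error(build_pairs(fx$tree, fx$units,
                           data.frame(x1x2y = "Nonexistent_X1X2Y",
                                      xy1y2 = "Gazella_XY1Y2")),
               "unknown unit")
  dup <- rbind(cfg, cfg[1, ])
  expect_error(build_pairs(fx$tree, fx$units, dup), "more than one pair")
})

test_that("automatic pairing matches the enumerable four-tip case", {
  tree <- read_species_tree("((x1_a,y1_a),(x2_a,y2_a));")
  smap <- c(x1_a = "X1X2Y", y1_a = "XY1Y2", x2_a = "X1X2Y", y2_a = "XY1Y2")
  units <- find_system_clusters(tree, smap)
  pairs <- build_pairs(tree, units)
  expect_equal(nrow(pairs), 2L)
  # nearest-distance rule pairs within each cherry
  got <- sort(paste(pairs$x1x2y, pairs$xy1y2))
  expect_equal(got, c("x1_X1X2Y y1_XY1Y2", "x2_X1X2Y y2_XY1Y2"))
  expect_true(validate_pair_independence(tree, pairs)$ok)
})

test_that("single-system unit sets yield no pairs, with a warning", {
  tree <- read_species_tree("(a_a,b_b);")
  units <- find_system_clusters(tree, c(a_a = "X1X2Y", b_b = "X1X2Y"))
  expect_warning(pairs <- build_pairs(tree, units), "one system")
  expect_equal(nrow(pairs), 0L)
  expect_true(validate_pair_independence(tree, pairs)$ok)
})

test_that("packaged nine pairs are phylogenetically independent", {
  fx <- fixture_bundle()
  rep_ok <- validate_pair_independence(fx$tree, fx$pairs)
  expect_true(rep_ok$ok)
  expect_length(rep_ok$shared_edges, 0L)

  # independent oracle: igraph shortest paths over the tree's edge graph
  library(igraph)
  g <- graph_from_edgelist(apply(fx$tree$edge, 2, as.character),
                           directed = FALSE)
  ids <- vapply(fx$units, `[[`, "", "id")
  used <- character(0)
  for (i in seq_len(nrow(fx$pairs))) {
    ux <- fx$units[[match(fx$pairs$x1x2y[i], ids)]]
    uy <- fx$units[[match(fx$pairs$xy1y2[i], ids)]]
    from <- as.character(karyopairs:::kp_unit_node(fx$tree, ux$members))
    to <- as.character(karyopairs:::kp_unit_node(fx$tree, uy$members))
    vp <- shortest_paths(g, from, to)$vpath[[1]]
    nodes <- as_ids(vp)
    edges <- paste(pmin(as.integer(head(nodes, -1)), as.integer(nodes[-1])),
                   pmax(as.integer(head(nodes, -1)), as.integer(nodes[-1])),
                   sep = "-")
    expect_length(intersect(edges, used), 0L)
    used <- c(used, edges)
  }
})

test_that("shared-edge violations are detected on a constructed example", {
  # comb tree: pairing across the backbone twice must share edges
  tree <- read_species_tree("(x1_a,(y1_a,(x2_a,y2_a)));")
  smap <- c(x1_a = "X1X2Y", y1_a = "XY1Y2", x2_a = "X1X2Y", y2_a = "XY1Y2")
  units <- find_system_clusters(tree, smap)
  crossing <- data.frame(x1x2y = c("x1_X1X2Y", "x2_X1X2Y"),
                         xy1y2 = c("y2_XY1Y2", "y1_XY1Y2"))
  pairs <- build_pairs(tree, units, crossing)
  rep_bad <- validate_pair_independence(tree, pairs)
  expect_false(rep_bad$ok)
  expect_gt(length(rep_bad$shared_edges), 0L)
})

test_that("automatic pairing on simulated data is always independent", {
  set.seed(21)
  for (i in 1:15) {
    p <- sim_params(n_tips = 60, sex_fusion_rate = 0.6)
    ds <- karyopairs:::kp_sim_until_informative(p)
    rec <- ds$records
    units <- find_system_clusters(ds$analysis_tree,
                                  stats::setNames(rec$system, rec$species_key))
    pairs <- build_pairs(ds$analysis_tree, units)
    used <- c(pairs$x1x2y, pairs$xy1y2)
    expect_true(!anyDuplicated(used))
    expect_true(validate_pair_independence(ds$analysis_tree, pairs)$ok)
    n_sys <- table(vapply(units, `[[`, "", "system"))
    expect_lte(nrow(pairs), min(n_sys))
  }
})
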