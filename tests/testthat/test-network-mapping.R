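test_that("density thresholding keeps the exact largest-edge set", {
  withr::with_seed(1, {
    m <- matrix(runif(36, 0.1, 0.9), 6)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    g <- threshold_at_density(m, 0.2)
    expect_equal(nrow(g$edges), ceiling(0.2 * 15))
    ut <- m[upper.tri(m)]
    expect_setequal(g$edges$w, sort(ut, decreasing = TRUE)[1:3])

    full <- threshold_at_density(m, 1)
    expect_equal(nrow(full$edges), 15)
  })
})

test_that("ties at the cut go to lexicographically smallest pairs", {
  m <- matrix(0.5, 4, 4)
  diag(m) <- 1
  g <- threshold_at_density(m, 0.5) # 3 of 6 identical edges
  expect_equal(nrow(g$edges), 3)
  expect_equal(g$edges$i, c(1, 1, 1))
  expect_equal(g$edges$j, c(2, 3, 4))
})

test_that("thresholded edge sets are nested across densities", {
  withr::with_seed(2, {
    m <- cor(matrix(rnorm(20 * 60), 60, 20))
    keys <- lapply(default_density_grid(), function(d) {
      e <- threshold_at_density(m, d)$edges
      paste(e$i, e$j)
    })
    for (k in seq_len(length(keys) - 1)) {
      expect_true(all(keys[[k]] %in% keys[[k + 1]]))
    }
  })
  expect_error(threshold_at_density(diag(3) * 0 + diag(3), 0.5),
               "zero edges")
})

test_that("map-equation optimizer recovers planted structures", {
  sol <- infomap_partition(two_clique_graph(), seed = 3)
  expect_equal(sol$n_communities, 2)
  expect_length(unique(sol$membership[1:5]), 1)
  expect_length(unique(sol$membership[6:10]), 1)

  pairs <- expand.grid(i = 1:5, j = 1:5)
  pairs <- pairs[pairs$i < pairs$j, ]
  clique <- structure(list(n_nodes = 5L,
                           edges = data.frame(i = pairs$i, j = pairs$j,
                                              w = 1), density = NA),
                      class = "fc_graph")
  expect_equal(infomap_partition(clique, seed = 1)$n_communities, 1)

  ring <- infomap_partition(triangle_ring_graph(), seed = 1)
  expect_equal(ring$n_communities, 4)
  expect_equal(ring$membership, rep(1:4, each = 3))
  expect_error(infomap_partition(structure(
    list(n_nodes = 3L, edges = data.frame(i = integer(), j = integer(),
                                          w = numeric()), density = NA),
    class = "fc_graph")), "empty graph")
})

test_that("partitions agree with an independent Infomap implementation", {
  skip_if_not_installed("igraph")
  g <- two_clique_graph()
  sol <- infomap_partition(g, seed = 2)
  ig <- igraph::graph_from_data_frame(g$edges[, c("i", "j")],
                                      directed = FALSE,
                                      vertices = data.frame(1:10))
  igraph::E(ig)$weight <- g$edges$w
  cm <- withr::with_seed(1, igraph::cluster_infomap(ig))
  expect_equal(nmi(as.character(sol$membership),
                   as.character(igraph::membership(cm))), 1)
})

test_that("greedy codelength agrees with exhaustive search on 8 nodes", {
  # two 4-cliques joined by one weak edge; Bell(8) = 4140 partitions
  pairs <- expand.grid(i = 1:4, j = 1:4)
  pairs <- pairs[pairs$i < pairs$j, ]
  g <- structure(list(n_nodes = 8L,
                      edges = data.frame(i = c(pairs$i, pairs$i + 4L, 4L),
                                         j = c(pairs$j, pairs$j + 4L, 5L),
                                         w = c(rep(1, 12), 0.15)),
                      density = NA), class = "fc_graph")
  sol <- infomap_partition(g, seed = 2)
  oracle <- exhaustive_best_partition(g)
  expect_equal(sol$codelength, oracle$codelength, tolerance = 1e-10)
})

test_that("codelength never increases across accepted greedy moves", {
  for (s in 1:5) {
    sol <- infomap_partition(two_clique_graph(), seed = s,
                             record_trace = TRUE)
    expect_true(all(diff(sol$trace) <= 1e-12))
  }
  # reported codelength matches the independent R evaluation
  sol <- infomap_partition(triangle_ring_graph(), seed = 4)
  expect_equal(sol$codelength,
               map_equation_codelength(triangle_ring_graph(),
                                       sol$membership),
               tolerance = 1e-12)
})

test_that("jaccard endpoints and overlap arithmetic", {
  expect_equal(jaccard(1:10, 1:10), 1)
  expect_equal(jaccard(1:5, 6:10), 0)
  expect_equal(jaccard(1:100, 51:150), 1 / 3)
  expect_error(jaccard(integer(), integer()), "empty")
})

test_that("template matching assigns names by thresholded argmax", {
  tmpl <- make_template(fix_mesh2, 4, seed = 1)
  # communities identical to the template networks inherit their names
  membership <- match(tmpl$labels, tmpl$names)
  out <- template_match(membership, tmpl)
  expect_identical(out, tmpl$labels)

  # a small community stays unassigned
  memb2 <- membership
  memb2[1:3] <- 99L
  out2 <- template_match(memb2, tmpl, match_config(min_community_size = 5))
  expect_true(all(out2[1:3] == unassigned_label()))

  # below-threshold overlap stays unassigned: a 12-node community straddling
  # two 50-node networks has Jaccard 6/56 ~ 0.107 with each
  flat <- structure(list(labels = rep(c("A", "B"), each = 50),
                         names = c("A", "B"), K = 2L),
                    class = "network_template")
  memb_flat <- rep(1L, 100)
  memb_flat[45:56] <- 2L
  out3 <- template_match(memb_flat, flat,
                         match_config(jaccard_threshold = 0.15))
  expect_true(all(out3[45:56] == unassigned_label()))

  # argmax between two overlapped networks takes the larger Jaccard
  two <- ifelse(tmpl$labels %in% tmpl$names[1:2], 1L, 2L)
  sizes <- table(factor(tmpl$labels, tmpl$names))
  out4 <- template_match(two, tmpl)
  big <- tmpl$names[which.max(sizes[1:2])]
  expect_true(all(out4[two == 1L] == big))
})

test_that("consensus takes the sparsest assigned label and is idempotent", {
  un <- unassigned_label()
  d1 <- c("DMN", un, un)
  d2 <- c("VIS", "FPN", un)
  d3 <- c("VIS", "FPN", un)
  out <- consensus_labels(list(d1, d2, d3))
  expect_identical(out, c("DMN", "FPN", un))
  expect_identical(consensus_labels(list(out, out)), out)
  # order independence given the density-sorted stack: consensus of the
  # consensus with any denser map is unchanged
  expect_identical(consensus_labels(list(out, d3)), out)
})

test_that("full mapping recovers the planted template", {
  tmpl <- make_template(fix_mesh2, 5, seed = 2)
  spec <- cohort_spec(n_subjects = 8L, n_frames = 600L,
                      motion_burst_rate = 0, n_subcortical = 0L, seed = 3)
  co <- simulate_cohort(tmpl, spec)
  g <- group_average_fc(lapply(co$subjects, function(s)
    subject_fc(s$timeseries)))
  lab <- map_networks(g, tmpl, seed = 5)
  expect_gte(nmi(lab, tmpl$labels), 0.90)

  audit <- attr(lab, "audit")
  expect_equal(nrow(audit), length(default_density_grid()))
  expect_true(all(audit$n_communities >= 1))
})

test_that("near-noiseless mapping reproduces the truth on all nodes", {
  # noise small enough that the limit holds, but nonzero so edge weights
  # are tie-free; the grid reaches past the within-network pair fraction
  # so whole networks survive thresholding
  tmpl <- make_template(fix_mesh2, 5, seed = 2)
  spec <- cohort_spec(n_subjects = 2L, n_frames = 300L, noise_sd = 0.05,
                      within_network_corr = 0.5,
                      between_network_corr = 0.05,
                      motion_burst_rate = 0, n_subcortical = 0L, seed = 3)
  co <- simulate_cohort(tmpl, spec)
  g <- group_average_fc(lapply(co$subjects, function(s)
    subject_fc(s$timeseries)))
  grid <- c(0.02, 0.05, 0.12)
  lab <- map_networks(g, tmpl, grid = grid, seed = 5)
  expect_gte(mean(lab == tmpl$labels), 0.99)

  # relabeling invariance: permuted node order gives identical labels
  # after inverse permutation (tie-free weights, clean optimum)
  perm <- withr::with_seed(9, sample(nrow(g)))
  gp <- fc_matrix(unclass(g)[perm, perm])
  tmpl_p <- structure(list(labels = tmpl$labels[perm], names = tmpl$names,
                           K = tmpl$K), class = "network_template")
  lab_p <- map_networks(gp, tmpl_p, grid = grid, seed = 5)
  expect_identical(as.character(lab_p)[order(perm)], as.character(lab))
})

test_that("planted-template recovery holds across seeds", {
  tmpl <- make_template(fix_mesh2, 5, seed = 2)
  hits <- vapply(1:6, function(s) {
    spec <- cohort_spec(n_subjects = 6L, n_frames = 600L,
                        motion_burst_rate = 0, n_subcortical = 0L,
                        seed = 200 + s)
    co <- simulate_cohort(tmpl, spec)
    g <- group_average_fc(lapply(co$subjects, function(x)
      subject_fc(x$timeseries)))
    nmi(map_networks(g, tmpl, seed = s), tmpl$labels)
  }, numeric(1))
  expect_gte(mean(hits >= 0.90), 0.95)
})
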