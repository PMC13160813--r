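test_that("NMI matches the plug-in entropy oracle and endpoints", {
  a <- rep(c("x", "y"), c(40, 40))
  b <- c(rep(c("u", "v"), c(30, 10)), rep(c("u", "v"), c(10, 30)))
  # hand-computed: joint [[30,10],[10,30]]/80, symmetric marginals 1/2
  p <- matrix(c(30, 10, 10, 30) / 80, 2)
  mi <- sum(p * log2(p / outer(rowSums(p), colSums(p))))
  expect_equal(nmi(a, b), mi / 1, tolerance = 1e-12) # H = 1 bit each

  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, rep("z", 80)), 0) # zero-entropy convention

  # symmetry and label-renaming invariance
  expect_equal(nmi(a, b), nmi(b, a))
  b2 <- c(u = "Q", v = "R")[b]
  expect_equal(nmi(a, unname(b2)), nmi(a, b))

  # unassigned nodes are excluded pairwise
  a2 <- a; a2[1:10] <- unassigned_label()
  expect_equal(nmi(a2, b), nmi(a[-(1:10)], b[-(1:10)]))
  expect_error(nmi(rep(unassigned_label(), 5), rep("x", 5)), "no nodes")
})

test_that("Dice endpoints and arithmetic", {
  expect_equal(dice(1:10, 1:10), 1)
  expect_equal(dice(1:5, 6:10), 0)
  expect_equal(dice(1:100, 51:150), 0.5)
  expect_equal(dice(1:4, 3:6), dice(3:6, 1:4))
  expect_error(dice(integer(), integer()), "empty")

  a <- c("A", "A", "B", unassigned_label())
  b <- c("A", "B", "B", "B")
  d <- dice_by_network(a, b)
  expect_equal(unname(d["A"]), 2 * 1 / (2 + 1))
  expect_equal(unname(d["B"]), 2 * 1 / (1 + 3))
})

test_that("spin rotations are orthogonal, seeded, and uniform", {
  R <- spin_rotations(50, seed = 2)
  for (i in c(1, 25, 50)) {
    expect_lt(max(abs(t(R[, , i]) %*% R[, , i] - diag(3))), 1e-9)
    expect_equal(det(R[, , i]), 1, tolerance = 1e-9)
  }
  expect_identical(spin_rotations(50, seed = 2), R)

  big <- spin_rotations(10000, seed = 9)
  v <- c(1, 0, 0)
  rotated <- vapply(seq_len(10000), function(i) big[, , i] %*% v,
                    numeric(3))
  expect_lt(sqrt(sum(rowMeans(rotated)^2)), 3 / sqrt(10000) * sqrt(3))
})

test_that("label rotation is a near-isometry of the map", {
  tmpl <- make_template(fix_mesh3, 12, seed = 1)
  expect_identical(rotate_labelmap(tmpl$labels, fix_mesh3, diag(3)),
                   tmpl$labels)
  R <- spin_rotations(10, seed = 4)
  share <- table(factor(tmpl$labels, tmpl$names)) / fix_mesh3$n_vertices
  for (i in 1:10) {
    rot <- rotate_labelmap(tmpl$labels, fix_mesh3, R[, , i])
    back <- rotate_labelmap(rot, fix_mesh3, t(R[, , i]))
    # nearest-neighbor quantization flips only boundary vertices
    expect_gte(mean(back == tmpl$labels), 0.95)
    share_rot <- table(factor(rot, tmpl$names)) / fix_mesh3$n_vertices
    expect_lt(max(abs(share_rot - share)), 0.02)
  }
  # a 2-label map round-trips almost perfectly
  t2 <- make_template(fix_mesh3, 2, seed = 1)
  agree <- vapply(1:10, function(i) {
    mean(rotate_labelmap(rotate_labelmap(t2$labels, fix_mesh3, R[, , i]),
                         fix_mesh3, t(R[, , i])) == t2$labels)
  }, numeric(1))
  expect_gte(mean(agree), 0.99)
})

test_that("spin p-values use the documented conventions", {
  tmpl <- make_template(fix_mesh2, 5, seed = 3)
  res <- spin_pvalue(nmi, tmpl$labels, tmpl$labels, fix_mesh2,
                     n_rot = 99, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$n_perm, 99)
  # identical maps: no rotation can beat NMI 1 except exact preservation
  expect_equal(res$p_value,
               (sum(res$null_sample >= 1) + 1) / 100)
  expect_lte(res$p_value, 0.05)

  raw <- spin_pvalue(nmi, tmpl$labels, tmpl$labels, fix_mesh2,
                     n_rot = 99, seed = 1, convention = "proportion")
  expect_equal(raw$p_value, mean(raw$null_sample >= 1))
})

test_that("spin p-values are calibrated under a rotational null", {
  a0 <- make_template(fix_mesh2, 5, seed = 11)$labels
  b <- make_template(fix_mesh2, 5, seed = 99)$labels
  Rs <- spin_rotations(200, seed = 777)
  ps <- vapply(1:200, function(s) {
    a_s <- rotate_labelmap(a0, fix_mesh2, Rs[, , s])
    spin_pvalue(nmi, a_s, b, fix_mesh2, n_rot = 99,
                seed = 1000 + s)$p_value
  }, numeric(1))
  expect_lt(ks_distance_uniform(ps), 0.1)
  # validity: P(p <= alpha) <= alpha + 1/(n_perm+1) within Monte-Carlo slack
  for (alpha in c(0.05, 0.1)) {
    slack <- 2.5 * sqrt(alpha * (1 - alpha) / 200)
    expect_lte(mean(ps <= alpha), alpha + 1 / 100 + slack)
  }
})

test_that("mantel observed statistic and p behave as documented", {
  withr::with_seed(5, {
    a <- cor(matrix(rnorm(15 * 40), 40, 15))
    res <- mantel(a, a, method = "linear", n_perm = 99, seed = 1)
    expect_equal(res$observed, 1)
    expect_equal(res$p_value, 1 / 100)

    # relabeled copy: the identity-level value sits inside the null range
    idx <- sample(15)
    ap <- a[idx, idx]
    res2 <- mantel(ap, a, method = "linear", n_perm = 199, seed = 2)
    expect_gte(max(res2$null_sample), res2$observed - 1e-12)

    # rank variant equals Spearman on the upper triangles
    b <- cor(matrix(rnorm(15 * 40), 40, 15))
    res3 <- mantel(a, b, method = "rank", n_perm = 9, seed = 3)
    expect_equal(res3$observed,
                 cor(a[upper.tri(a)], b[upper.tri(b)], method = "spearman"))

    # independent implementation agrees on the observed statistic
    if (requireNamespace("vegan", quietly = TRUE)) {
      vg <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                          permutations = 0)
      expect_equal(mantel(a, b, "linear", n_perm = 1, seed = 1)$observed,
                   unname(vg$statistic), tolerance = 1e-12)
    }
  })
})

test_that("mantel p-values are calibrated under independence", {
  ps <- vapply(1:200, function(s) {
    withr::with_seed(1000 + s, {
      m1 <- cor(matrix(rnorm(12 * 30), 30, 12))
      m2 <- cor(matrix(rnorm(12 * 30), 30, 12))
    })
    mantel(m1, m2, "linear", n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_lt(ks_distance_uniform(ps), 0.1)
})
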