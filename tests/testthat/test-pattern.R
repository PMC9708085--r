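test_that("match score reproduces its closed-form reference points", {
  m <- array(TRUE, c(2, 2, 1))
  attr(m, "voxel_dims") <- c(1, 1, 1)
  px <- flat_partition(m, axis = 1)
  py <- flat_partition(m, axis = 2)
  expect_identical(match_score(px, px)$value, 1)
  expect_identical(match_score(px, py)$value, 0.5)
  # swapped daughter labels still give a perfect match
  sl <- px$labels
  sl[px$labels == 1L] <- 2L
  sl[px$labels == 2L] <- 1L
  swapped <- division_partition(sl, c(1, 1, 1))
  expect_identical(match_score(px, swapped)$value, 1)
  expect_identical(match_score(px, swapped)$pairing, "swapped")
  mismatch <- division_partition(array(c(1L, 2L, 0L, 0L), c(2, 2, 1)),
                                 c(1, 1, 1))
  expect_error(match_score(px, mismatch), "same mother")
})

test_that("match score stays within [0.5, 1] over all partition pairs", {
  # exhaustive over all binary partitions of an 8-voxel mother
  n <- 8
  labs <- as.matrix(expand.grid(rep(list(1:2), n)))
  scores <- outer(seq_len(nrow(labs)), seq_len(nrow(labs)),
                  Vectorize(function(i, j) {
    a <- labs[i, ]
    b <- labs[j, ]
    agree <- sum(a == b)
    max(agree, n - agree) / n
  }))
  expect_gte(min(scores), 0.5)
  expect_lte(max(scores), 1)
  # the package computation agrees with the direct formula on a sample
  set.seed(12)
  for (k in 1:20) {
    i <- sample(nrow(labs), 1)
    j <- sample(nrow(labs), 1)
    pi_ <- division_partition(array(labs[i, ], c(2, 2, 2)), c(1, 1, 1))
    pj <- division_partition(array(labs[j, ], c(2, 2, 2)), c(1, 1, 1))
    expect_identical(match_score(pi_, pj)$value, scores[i, j])
    expect_identical(match_score(pi_, pj)$value, match_score(pj, pi_)$value)
  }
})

test_that("solution tables carry bounded scores and are deterministic", {
  res <- cuboid_batch()
  obs <- flat_partition(unit_cuboid(16), axis = 3)
  tab <- build_solution_table(res, obs)
  expect_identical(nrow(tab), length(res))
  expect_true(all(tab$score >= 0.5 & tab$score <= 1))
  expect_true(all(tab$area >= 0))
  expect_identical(tab, build_solution_table(res, obs))
  expect_error(build_solution_table(list()), "empty")
})

test_that("family clustering has the expected limiting behavior", {
  res <- cuboid_batch()[1:30]
  # all runs identical: one family
  same <- rep(res[1], 10)
  expect_identical(unique(cluster_families(same)), 1L)
  # theta = 0: every distinct partition its own family
  fam0 <- cluster_families(res, theta = 0)
  key <- vapply(res, function(r) paste(r$partition$labels, collapse = ""),
                character(1))
  expect_identical(length(unique(fam0)), length(unique(key)))
  # the three axis-parallel plane modes appear as distinct families
  resall <- cuboid_batch()
  fam <- cluster_families(resall)
  axis_of <- vapply(resall, function(r) {
    n <- interface_normal(r)
    which.max(abs(n))
  }, integer(1))
  clean <- vapply(resall, function(r) {
    n <- interface_normal(r)
    max(abs(n)) > 0.9
  }, logical(1))
  fam_axes <- unique(vapply(unique(fam[clean]), function(f) {
    ax <- axis_of[clean & fam == f]
    as.integer(names(which.max(table(ax))))
  }, integer(1)))
  expect_gte(length(unique(fam)), 3L)
  expect_setequal(fam_axes, 1:3)
})

test_that("mid-plane divisions comply with the center/area rule", {
  res <- cuboid_batch()
  mask <- unit_cuboid(16)
  obs <- flat_partition(mask, axis = 3)
  tab <- build_solution_table(res, obs)
  rep1 <- rule_compliance(tab, res)
  expect_true(rep1$compliant)
  expect_identical(rep1$dominance_rank, 0L)
  # the best-matching run sits in the low-distance low-area corner
  best <- which.max(tab$score)
  expect_lte(tab$distance[best], stats::quantile(tab$distance, 0.2))
  expect_lte(tab$area[best], stats::quantile(tab$area, 0.2))
})

test_that("forced off-center large-area cuts are non-compliant", {
  res <- cuboid_batch()
  mask <- unit_cuboid(16)
  idx <- which(mask, arr.ind = TRUE)
  lab <- array(0L, dim(mask))
  lab[mask] <- 2L
  lab[idx[rowSums(idx) <= stats::quantile(rowSums(idx), 0.18), ,
          drop = FALSE]] <- 1L
  obs <- division_partition(lab, c(1, 1, 1))
  tab <- build_solution_table(res, obs)
  rep2 <- rule_compliance(tab, res)
  expect_false(isTRUE(rep2$compliant))
  # an empty center neighborhood is flagged inconclusive
  rep3 <- rule_compliance(tab, res, delta = 1e-6)
  expect_true(rep3$inconclusive)
})

test_that("chord measurements recover generated asymmetries", {
  ax <- list(ab_axis = c(0, 0, 1), left = c(-1, 0, 0))
  g <- voxel_grid(c(30, 26, 30), c(1, 1, 1))
  sym <- make_shape_mask(shape_spec("triangular_prism",
                                    extent = c(20, 18, 12)), g)
  expect_lt(abs(length_asymmetries(sym, ax)$left_right - 1), 0.06)
  skew <- make_shape_mask(shape_spec("triangular_prism",
                                     extent = c(20, 18, 12),
                                     asymmetry = c(left_right = 0.8,
                                                   longitudinal = NA)), g)
  expect_lt(abs(length_asymmetries(skew, ax)$left_right - 0.8), 0.05)
  long <- make_shape_mask(shape_spec("triangular_prism",
                                     extent = c(20, 18, 12),
                                     asymmetry = c(left_right = 1,
                                                   longitudinal = 2)), g)
  expect_lt(abs(length_asymmetries(long, ax)$longitudinal - 2), 0.06)
  thin <- array(FALSE, c(4, 4, 4))
  thin[2, 2, 2] <- TRUE
  expect_error(length_asymmetries(thin, ax, center = c(0.1, 0.1, 0.1)),
               "geometry error")
})

test_that("orientation classification is grounded by generator cuts", {
  emb <- stereo16()
  probs <- list(apical_inner = c(radial = 1),
                apical_outer = c(anticlinal_transverse = 1),
                basal_inner = c(periclinal = 1),
                basal_outer = c(anticlinal_longitudinal = 1))
  e5 <- make_variable_generation(emb, probs, seed = 3)
  div5 <- e5$tree$divisions[e5$tree$divisions$generation == 5L, ]
  doms <- e5$tree$nodes$domain[match(div5$daughter1, e5$tree$nodes$cell_id)]
  for (i in seq_len(nrow(div5))) {
    o <- classify_orientation(e5$image, div5$daughter1[i],
                              div5$daughter2[i], e5$axes)
    expected <- switch(div5$orientation[i],
                       anticlinal_longitudinal = "anticlinal",
                       anticlinal_transverse = "anticlinal",
                       periclinal = "periclinal",
                       radial = "anticlinal")
    expect_identical(o$primary, expected)
  }
})

test_that("orientation sequences count and pool into attractor classes", {
  emb <- stereo16()
  # deterministic alternation in the basal-outer domain:
  # longitudinal at G5, then transverse in both daughters at G6
  p5 <- list(apical_inner = c(radial = 1),
             apical_outer = c(anticlinal_longitudinal = 1),
             basal_inner = c(periclinal = 1),
             basal_outer = c(anticlinal_longitudinal = 1))
  p6 <- list(apical_inner = c(radial = 1),
             apical_outer = c(anticlinal_transverse = 1),
             basal_inner = c(periclinal = 1),
             basal_outer = c(anticlinal_transverse = 1))
  e6 <- make_variable_generation(make_variable_generation(emb, p5, seed = 1),
                                 p6, seed = 2)
  seqs <- pattern_sequences(e6$tree, 5L)
  bo <- seqs[seqs$domain == "basal_outer", ]
  expect_identical(nrow(bo), 1L)
  expect_identical(sum(bo$count), 4L)   # all four basal-outer grandmothers
  expect_match(bo$attractor, "checkerboard")
  # the reversed order reaches the same attractor class
  e6b <- make_variable_generation(make_variable_generation(emb, p6, seed = 1),
                                  p5, seed = 2)
  seqs_b <- pattern_sequences(e6b$tree, 5L)
  bob <- seqs_b[seqs_b$domain == "basal_outer", ]
  expect_identical(unique(bob$attractor), unique(bo$attractor))
  expect_false(identical(unique(bob$sequence), unique(bo$sequence)))
  # a single-generation tree has no sequences
  expect_error(pattern_sequences(emb$tree, 5L), "depth error")
  # frequencies sum to the number of divided grandmothers per domain
  tot <- stats::aggregate(count ~ domain, seqs, sum)
  expect_true(all(tot$count == 4L))
})
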