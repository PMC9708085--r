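# small hand-built tree: root 2 -> (3,4) at G1 -> leaves (5,6,7,8) at G2
toy_tree <- function() {
  lineage_tree(data.frame(
    cell_id = c(2L, 3L, 4L, 5L, 6L, 7L, 8L),
    parent_id = c(NA, 2L, 2L, 3L, 3L, 4L, 4L),
    generation = c(0L, 1L, 1L, 2L, 2L, 2L, 2L)))
}

test_that("lineage trees validate their binary structure", {
  expect_s3_class(toy_tree(), "lineage_tree")
  expect_error(lineage_tree(data.frame(cell_id = c(1L, 2L),
                                       parent_id = c(NA, 1L),
                                       generation = c(0L, 1L))),
               "non-binary")
  expect_error(lineage_tree(data.frame(cell_id = c(1L, 2L, 3L),
                                       parent_id = c(NA, 1L, 1L),
                                       generation = c(0L, 2L, 2L))),
               "generation")
})

test_that("recursive merging reconstructs earlier generations", {
  emb <- stereo16()
  g3 <- reconstruct_generation(emb$image, emb$tree, 3L)
  expect_length(setdiff(cell_labels(g3), emb$suspensor_label), 8L)
  # identity at the leaf generation
  g4 <- reconstruct_generation(emb$image, emb$tree, 4L)
  expect_identical(unclass(g4), unclass(emb$image))
  # volume conservation under merging at every generation
  vol_leaf <- sum(unclass(emb$image) >= 2L & unclass(emb$image) != 1L)
  for (g in 0:3) {
    img_g <- reconstruct_generation(emb$image, emb$tree, g)
    cells <- setdiff(cell_labels(img_g), emb$suspensor_label)
    expect_identical(length(cells), as.integer(2^g))
    expect_identical(sum(unclass(img_g) %in% cells), vol_leaf)
  }
  expect_error(reconstruct_generation(emb$image, emb$tree, 5L),
               "lineage-depth")
})

test_that("interface origins follow the lowest common ancestor", {
  tr <- toy_tree()
  expect_identical(interface_generation(tr, 5L, 6L), 2L)  # sisters
  expect_identical(interface_generation(tr, 5L, 7L), 1L)  # across G1 wall
  expect_identical(interface_generation(tr, 5L, 0L), "outer_surface")
  expect_identical(interface_generation(tr, 5L, 1L), "suspensor_wall")
  expect_error(interface_generation(tr, 5L, 5L), "identical")
  # stereotyped embryo: apical vs basal 8C cells meet at the G3 wall
  emb <- stereo16()
  g3 <- reconstruct_generation(emb$image, emb$tree, 3L)
  cells <- setdiff(cell_labels(g3), emb$suspensor_label)
  doms <- assign_domains(g3, emb$tree, emb$axes, 3L)
  ap <- as.integer(names(doms)[doms == "apical"])
  ba <- as.integer(names(doms)[doms == "basal"])
  expect_identical(interface_generation(emb$tree, ap[1], ba[1]), 3L)
  # sisters at the deepest generation
  d <- emb$tree$divisions[emb$tree$divisions$generation == 4L, ][1, ]
  expect_identical(interface_generation(emb$tree, d$daughter1, d$daughter2),
                   4L)
})

test_that("face counting matches the printed canonical values", {
  emb <- stereo16()
  # basal 8C cells have five faces, apical four
  g3 <- reconstruct_generation(emb$image, emb$tree, 3L)
  doms <- assign_domains(g3, emb$tree, emb$axes, 3L)
  for (id in as.integer(names(doms))) {
    f <- count_division_faces(g3, emb$tree, id)
    expect_identical(f, if (doms[as.character(id)] == "basal") 5L else 4L)
  }
  # basal-outer 16C cells have six faces (cuboids)
  doms4 <- assign_domains(emb$image, emb$tree, emb$axes, 4L)
  bo <- as.integer(names(doms4)[doms4 == "basal_outer"])
  for (id in bo)
    expect_identical(count_division_faces(emb$image, emb$tree, id), 6L)
})

test_that("face counts are invariant to relabeling and translation", {
  emb <- stereo16()
  img <- emb$image
  lv <- sort(tree_leaves(emb$tree))
  f0 <- leaf_face_counts(emb)
  # relabel cells by an arbitrary permutation (offset keeps labels unique)
  perm <- stats::setNames(sample(seq_along(lv)) + 100L, lv)
  a <- unclass(img)
  b <- a
  for (id in lv) b[a == id] <- perm[[as.character(id)]]
  nodes <- emb$tree$nodes
  nodes$cell_id <- ifelse(nodes$cell_id %in% lv,
                          perm[as.character(nodes$cell_id)], nodes$cell_id)
  nodes$parent_id <- ifelse(nodes$parent_id %in% lv,
                            perm[as.character(nodes$parent_id)],
                            nodes$parent_id)
  tr2 <- lineage_tree(nodes)
  img2 <- label_image(b, voxel_dims(img))
  f1 <- vapply(unname(perm[as.character(lv)]), function(id)
    count_division_faces(img2, tr2, id), integer(1))
  expect_identical(f1, f0)
  # translate the whole grid by padding one slab of background
  d <- dim(a)
  big <- array(0L, d + c(2L, 0L, 0L))
  big[3:(d[1] + 2L), , ] <- a
  img3 <- label_image(big, voxel_dims(img))
  f2 <- vapply(lv, function(id)
    count_division_faces(img3, emb$tree, id), integer(1))
  expect_identical(f2, f0)
})

test_that("shape classification maps face counts totally", {
  expect_identical(as.character(classify_shape(c(4, 5, 6, 7, 2, 12))),
                   c("T", "P", "C", "O", "O", "O"))
  expect_error(classify_shape(1), ">= 2")
})

test_that("entropy follows the Shannon formula with 0 log 0 = 0", {
  expect_identical(shape_entropy(c(1)), 0)
  expect_identical(shape_entropy(c(0, 1, 0)), 0)
  expect_equal(shape_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(shape_entropy(rep(1 / 5, 5)), log(5), tolerance = 1e-12)
  expect_equal(shape_entropy(c(0.5, 0.5), base = 2), 1, tolerance = 1e-12)
  expect_error(shape_entropy(c(0.5, 0.4)), "sum to 1")
  # bounds on arbitrary random distributions
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    p <- stats::runif(k)
    p <- p / sum(p)
    h <- shape_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
  }
})

test_that("shape distributions match the stereotyped layout", {
  emb <- stereo16()
  d4 <- shape_distribution(emb$image, emb$tree, 4L)
  expect_identical(attr(d4, "N"), 16L)
  expect_equal(d4$proportion[match(c(4, 5, 6), d4$faces)],
               c(4, 8, 4) / 16)
  d2 <- shape_distribution(emb$image, emb$tree, 2L)
  expect_identical(d2$faces, 4L)
  expect_identical(d2$proportion, 1)
  d0 <- shape_distribution(emb$image, emb$tree, 0L)
  expect_identical(d0$faces, 2L)
  expect_identical(d0$proportion, 1)
  # per-generation entropy is zero up to G2, positive at G3/G4
  expect_identical(shape_entropy(d0), 0)
  expect_identical(shape_entropy(d2), 0)
  expect_gt(shape_entropy(shape_distribution(emb$image, emb$tree, 3L)), 0)
  # domain filter: basal-outer cells are all six-faced
  dbo <- shape_distribution(emb$image, emb$tree, 4L, domain = "basal_outer")
  expect_identical(attr(dbo, "N"), 4L)
  expect_identical(dbo$faces, 6L)
})

test_that("the noise-free face-count sequence is 2;3;4;{4,5};{4,5,5,6}", {
  emb <- stereo16()
  seqs <- lapply(0:4, function(g) {
    d <- shape_distribution(emb$image, emb$tree, g)
    rep(d$faces, d$count)
  })
  expect_identical(seqs[[1]], 2L)
  expect_identical(seqs[[2]], c(3L, 3L))
  expect_identical(seqs[[3]], rep(4L, 4))
  expect_identical(sort(unique(seqs[[4]])), c(4L, 5L))
  expect_identical(sort(seqs[[5]]), canonical_g4_faces())
})

test_that("domain assignment distinguishes inner cells from generation 4 on", {
  emb <- stereo16()
  doms <- assign_domains(emb$image, emb$tree, emb$axes, 4L)
  inner <- names(doms)[grepl("inner", doms)]
  for (id in as.integer(inner))
    expect_false(0L %in% embryodiv:::neighbor_labels(emb$image, id))
  g3 <- reconstruct_generation(emb$image, emb$tree, 3L)
  doms3 <- assign_domains(g3, emb$tree, emb$axes, 3L)
  expect_setequal(unique(doms3), c("apical", "basal"))
  expect_error(assign_domains(emb$image, emb$tree, list(ab_axis = c(0, 0, 1)),
                              4L),
               "configuration error")
})
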