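# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# noise-free stereotyped 16C embryo on the default grid
stereo16 <- function() {
  fixture("stereo16", function() make_stereotyped_embryo(4))
}

# canonical face counts of the noise-free 16C layout, sorted
canonical_g4_faces <- function() sort(rep(c(4L, 5L, 6L), c(4, 8, 4)))

leaf_face_counts <- function(emb) {
  lv <- sort(tree_leaves(emb$tree))
  vapply(lv, function(id)
    count_division_faces(emb$image, emb$tree, id,
                         suspensor_label = emb$suspensor_label), integer(1))
}

# unit-voxel cuboid mask of edge n inside a slightly larger grid
unit_cuboid <- function(n, pad = 4) {
  make_shape_mask(shape_spec("cuboid", extent = c(n, n, n)),
                  voxel_grid(c(n + pad, n + pad, n + pad), c(1, 1, 1)))
}

# flat axis-aligned observed division of a mask: lower half along `axis`
flat_partition <- function(mask, axis = 3, frac = 0.5) {
  idx <- which(mask, arr.ind = TRUE)
  pr <- idx[, axis]
  lab <- array(0L, dim(mask))
  lab[mask] <- 2L
  lab[idx[pr <= stats::quantile(pr, frac), , drop = FALSE]] <- 1L
  division_partition(lab, attr(mask, "voxel_dims"))
}

# dominant face-normal axis of the final interface of a simulation result
interface_normal <- function(result) {
  img <- label_image(result$partition$labels, result$partition$voxel_dims)
  fc <- embryodiv:::interface_faces(img, 1L, 2L)
  eigen(stats::cov(fc$centers), symmetric = TRUE)$vectors[, 3]
}

# batch of seeded cuboid simulations shared between tests
cuboid_batch <- function() {
  fixture("cuboid_batch", function() {
    mask <- unit_cuboid(16)
    cfg <- simulator_config(n_cycles = 300, cooling_cycles = 150)
    lapply(1:80, function(i) simulate_division(mask, cfg, seed = i))
  })
}
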