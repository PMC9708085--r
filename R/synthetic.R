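#' Idealized cell shape specification
#'
#' Describes one of the canonical cell shapes used throughout the analysis:
#' the truncated sphere of the first embryonic cell, half spheres,
#' tetrahedra, triangular prisms (triangle in the x-y plane, extruded along
#' z) and cuboids. Geometric asymmetry is expressed as the left/right length
#' ratio L/R along x and, optionally, the longitudinal-to-radial ratio
#' H/max(L, R) along z.
#'
#' @param shape_class one of "truncated_sphere", "half_sphere",
#'   "tetrahedron", "triangular_prism", "cuboid".
#' @param extent characteristic full lengths in voxels along (x, y, z); for
#'   the sphere classes `extent[1]` is the diameter.
#' @param asymmetry numeric: `left_right` L/R ratio (> 0) and `longitudinal`
#'   H/max(L, R) ratio (NA to keep `extent[3]`).
#' @param truncation for `truncated_sphere`: the normalized height (fraction
#'   of the radius below the center) at which the sphere is cut.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(shape_class = c("cuboid", "triangular_prism",
                                       "tetrahedron", "half_sphere",
                                       "truncated_sphere"),
                       extent,
                       asymmetry = c(left_right = 1, longitudinal = NA),
                       truncation = 0.6) {
  shape_class <- match.arg(shape_class)
  extent <- rep_len(as.numeric(extent), 3L)
  lr <- asymmetry[["left_right"]]
  long <- if ("longitudinal" %in% names(asymmetry))
    asymmetry[["longitudinal"]] else NA_real_
  if (!is.finite(lr) || lr <= 0) stop("left_right ratio must be > 0")
  if (!is.na(long) && long <= 0) stop("longitudinal ratio must be > 0")
  if (any(extent < 2))
    stop("dimension error: extent must be at least 2 voxels per axis")
  structure(list(shape_class = shape_class, extent = extent,
                 left_right = lr, longitudinal = long,
                 truncation = truncation),
            class = "shape_spec")
}

#' Rasterize an idealized shape
#'
#' Builds a binary foreground mask of the requested shape, centered in the
#' grid. Shapes are defined in physical coordinates so the asymmetry ratios
#' are physical length ratios; the returned mask is 6-connected.
#'
#' @param spec a [shape_spec()].
#' @param grid a [voxel_grid()].
#' @return logical 3D array with attributes `voxel_dims` and `center`
#'   (physical shape center).
#' @export
make_shape_mask <- function(spec, grid) {
  vd <- grid$voxel_dims
  d <- grid$shape
  phys <- d * vd
  ex <- spec$extent[1] * vd[1]
  ey <- spec$extent[2] * vd[2]
  # left/right half lengths along x: aL/aR = L/R, aL + aR = ex
  aL <- ex * spec$left_right / (1 + spec$left_right)
  aR <- ex / (1 + spec$left_right)
  hy <- ey / 2
  # half-width factor of the cross-section at the shape center: radial
  # chords measured through the center are a_L * w0 and a_R * w0
  w0 <- if (spec$shape_class == "triangular_prism") 0.5 else 1
  hz <- if (!is.na(spec$longitudinal))
    spec$longitudinal * max(aL, aR) * w0 / 2
  else spec$extent[3] * vd[3] / 2
  if (2 * hz < vd[3])
    stop("dimension error: extent must be at least 2 voxels per axis")
  if (ex > phys[1] || ey > phys[2] || 2 * hz > phys[3])
    stop("dimension error: shape extent exceeds the grid")
  ctr <- phys / 2
  xs <- (seq_len(d[1]) - 0.5) * vd[1] - ctr[1]
  ys <- (seq_len(d[2]) - 0.5) * vd[2] - ctr[2]
  zs <- (seq_len(d[3]) - 0.5) * vd[3] - ctr[3]
  ux <- ifelse(xs < 0, xs / aL, xs / aR)
  uy <- ys / hy
  uz <- zs / hz
  UX <- array(rep(ux, times = d[2] * d[3]), dim = d)
  UY <- array(rep(rep(uy, each = d[1]), times = d[3]), dim = d)
  UZ <- array(rep(uz, each = d[1] * d[2]), dim = d)
  mask <- switch(spec$shape_class,
    cuboid = abs(UX) <= 1 & abs(UY) <= 1 & abs(UZ) <= 1,
    triangular_prism = abs(UZ) <= 1 & UY >= -1 & abs(UX) <= (1 - UY) / 2,
    tetrahedron = {
      vx <- (UX + 1) / 2; vy <- (UY + 1) / 2; vz <- (UZ + 1) / 2
      vx >= 0 & vy >= 0 & vz >= 0 & (vx + vy + vz) <= 1
    },
    half_sphere = UX^2 + UY^2 + UZ^2 <= 1 & UZ >= 0,
    truncated_sphere = UX^2 + UY^2 + UZ^2 <= 1 & UZ >= -spec$truncation)
  if (!any(mask)) stop("dimension error: degenerate shape (empty mask)")
  attr(mask, "voxel_dims") <- vd
  # reference point for chord measurements; the corner tetrahedron does not
  # contain the grid center, so its centroid is recorded instead
  attr(mask, "center") <-
    if (spec$shape_class == "tetrahedron") cell_center(mask, voxel_dims = vd)
    else ctr
  mask
}

# Splits region voxels (physical coordinate matrix) by a flat plane with
# the given unit normal: side 1 = projections up to the `fraction` quantile.
# The plane anchor is displaced by a uniform draw of +/- noise times the
# projection range.
split_by_plane <- function(coords, normal, fraction, noise = 0) {
  proj <- drop(coords %*% (normal / sqrt(sum(normal^2))))
  anchor <- stats::quantile(proj, fraction, names = FALSE, type = 4)
  if (noise > 0)
    anchor <- anchor + stats::runif(1, -noise, noise) * diff(range(proj))
  side <- proj <= anchor
  if (!any(side) || all(side))
    side <- proj <= stats::quantile(proj, fraction, names = FALSE, type = 4)
  side
}

new_synthetic_embryo <- function(image, tree, axes,
                                 suspensor_label = 1L) {
  structure(list(image = image, tree = tree, axes = axes,
                 suspensor_label = suspensor_label),
            class = "synthetic_embryo")
}

#' @export
print.synthetic_embryo <- function(x, ...) {
  g <- max(x$tree$nodes$generation)
  cat(sprintf("synthetic_embryo at generation %d (%d cells)\n",
              g, length(tree_leaves(x$tree))))
  invisible(x)
}

#' Voxelized embryo with the stereotyped early division sequence
#'
#' Generates a synthetic embryo proper (a truncated sphere sitting on a
#' one-voxel-thick suspensor slab) and divides it through the invariant
#' sequence of the first four generations: two longitudinal anticlinal
#' quarterings (G1, G2), a transverse apical/basal division (G3), and the
#' G4 round whose periclinal walls create the inner cells. At generation 4
#' the four embryo domains carry the canonical shape topologies:
#' apical-inner tetrahedra (4 faces), apical-outer and basal-inner
#' triangular prisms (5), basal-outer cuboids (6). Division cuts are exact
#' planes, so ground-truth orientation labels exist for every wall.
#'
#' @param generations number of division rounds, 0 to 4.
#' @param grid a [voxel_grid()]; the default yields an embryo of roughly
#'   4 um radius at confocal-like calibration.
#' @param positioning_noise fraction of the cell extent by which each plane
#'   anchor is displaced (uniformly at random); 0 gives the noise-free
#'   canonical construction.
#' @param inner_fraction volume fraction given to the inner daughter at the
#'   G4 periclinal divisions.
#' @param seed optional RNG seed recorded in the output.
#' @return a `synthetic_embryo`: list with `image` (a [label_image()], label
#'   1 = suspensor, cells from 2), `tree` (a [lineage_tree()]), `axes`
#'   (apical-basal unit vector `ab_axis`, embryo `center`, transverse-wall
#'   height `g3_z`) and `suspensor_label`.
#' @export
make_stereotyped_embryo <- function(generations = 4,
                                    grid = voxel_grid(c(56, 56, 28)),
                                    positioning_noise = 0,
                                    inner_fraction = 0.2,
                                    seed = NULL) {
  if (generations > 4)
    stop("generations > 4: use make_variable_generation() for G5 onward")
  if (!is.null(seed)) set.seed(seed)
  vd <- grid$voxel_dims
  d <- grid$shape
  phys <- d * vd
  r <- 0.4 * min(phys[1], phys[2])
  z0 <- 3 * vd[3]                       # truncation plane height
  cz <- z0 + 0.6 * r                    # sphere center
  cx <- phys[1] / 2
  cy <- phys[2] / 2
  xs <- (seq_len(d[1]) - 0.5) * vd[1]
  ys <- (seq_len(d[2]) - 0.5) * vd[2]
  zs <- (seq_len(d[3]) - 0.5) * vd[3]
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)
  emb <- (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2 <= r^2 & Z >= z0
  if (!any(emb)) stop("dimension error: embryo does not fit the grid")
  # one-voxel-thick suspensor slab under the flat truncation disc
  susp <- array(FALSE, d)
  k0 <- min(which(apply(emb, 3, any)))
  if (k0 > 1L) susp[, , k0 - 1L] <- emb[, , k0]
  lab <- array(0L, d)
  lab[susp] <- 1L
  lab[emb] <- 2L

  nodes <- data.frame(cell_id = 2L, parent_id = NA_integer_,
                      generation = 0L, domain = NA_character_)
  divisions <- data.frame(mother = integer(0), daughter1 = integer(0),
                          daughter2 = integer(0), generation = integer(0),
                          orientation = character(0))
  next_id <- 3L
  g3_z <- NA_real_

  coords_of <- function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    list(idx = idx, xyz = voxel_centers(idx, vd))
  }
  divide <- function(id, g, normal, fraction, orientation,
                     inner_first = FALSE) {
    reg <- coords_of(id)
    ctr <- colMeans(reg$xyz)
    side <- split_by_plane(sweep(reg$xyz, 2L, ctr), normal, fraction,
                           positioning_noise)
    ids <- c(next_id, next_id + 1L)
    next_id <<- next_id + 2L
    lab[reg$idx[side, , drop = FALSE]] <<- ids[1]
    lab[reg$idx[!side, , drop = FALSE]] <<- ids[2]
    nodes <<- rbind(nodes,
                    data.frame(cell_id = ids, parent_id = id,
                               generation = g, domain = NA_character_))
    divisions <<- rbind(divisions,
                        data.frame(mother = id, daughter1 = ids[1],
                                   daughter2 = ids[2], generation = g,
                                   orientation = orientation))
    ids
  }

  if (generations >= 1)
    divide(2L, 1L, c(1, 0, 0), 0.5, "anticlinal_longitudinal")
  if (generations >= 2) {
    for (id in tree_leaves_df(nodes))
      divide(id, 2L, c(0, 1, 0), 0.5, "anticlinal_longitudinal")
  }
  if (generations >= 3) {
    zms <- vapply(tree_leaves_df(nodes), function(id) {
      reg <- coords_of(id)
      ctr <- colMeans(reg$xyz)
      divide(id, 3L, c(0, 0, 1), 0.5, "anticlinal_transverse")
      stats::median(reg$xyz[, 3])
    }, numeric(1))
    g3_z <- mean(zms)
  }
  if (generations >= 4) {
    for (id in tree_leaves_df(nodes)) {
      reg <- coords_of(id)
      ctr <- colMeans(reg$xyz)
      apical <- ctr[3] > g3_z
      # periclinal wall: parallel to the outer surface, i.e. normal along
      # the direction from the sphere center to the cell's surface centroid
      surf <- reg$xyz[reg$xyz[, 3] > cz |
                        sqrt((reg$xyz[, 1] - cx)^2 +
                               (reg$xyz[, 2] - cy)^2 +
                               (reg$xyz[, 3] - cz)^2) > 0.9 * r, ,
                      drop = FALSE]
      if (nrow(surf) == 0L) surf <- reg$xyz
      normal <- colMeans(surf) - c(cx, cy, cz)
      if (!apical) normal[3] <- 0
      ids <- divide(id, 4L, normal, inner_fraction, "periclinal")
      pole <- if (apical) "apical" else "basal"
      nodes$domain[nodes$cell_id == ids[1]] <-
        paste(pole, "inner", sep = "_")
      nodes$domain[nodes$cell_id == ids[2]] <-
        paste(pole, "outer", sep = "_")
    }
  }

  tree <- lineage_tree(nodes, divisions)
  axes <- list(ab_axis = c(0, 0, 1), center = c(cx, cy, cz),
               radial_origin = c(cx, cy), g3_z = g3_z)
  new_synthetic_embryo(label_image(lab, vd), tree, axes)
}

# leaves of a nodes data.frame (before the lineage_tree object exists)
tree_leaves_df <- function(nodes) {
  sort(setdiff(nodes$cell_id, nodes$parent_id[!is.na(nodes$parent_id)]))
}

orientation_classes <- c("anticlinal_longitudinal", "anticlinal_transverse",
                         "periclinal", "radial")

#' Divide a synthetic embryo with configurable plane orientations
#'
#' Performs one round of variable divisions on every leaf cell: each cell is
#' cut by a flat plane whose orientation class is drawn from a per-domain
#' distribution, at a volume fraction of 0.5 plus noise. Orientation classes
#' (relative to the embryo axes) are `anticlinal_longitudinal` (vertical
#' wall parallel to an existing lateral wall, intersecting the outer
#' surface), `anticlinal_transverse` (horizontal wall),
#' `periclinal` (wall parallel to the outer surface) and `radial` (vertical
#' wall containing the apical-basal axis direction). Ground-truth labels are
#' appended to the tree's division records.
#'
#' @param embryo a `synthetic_embryo` at generation >= 4.
#' @param orientation_probs named list: one probability vector over
#'   orientation classes per domain tag (apical/basal x inner/outer).
#' @param volume_ratio_noise half-width of the uniform volume-fraction
#'   noise around 0.5.
#' @param seed RNG seed; fixed seeds reproduce the embryo bit-identically.
#' @return a `synthetic_embryo` one generation deeper.
#' @export
make_variable_generation <- function(embryo, orientation_probs,
                                     volume_ratio_noise = 0.05,
                                     seed = NULL) {
  tree <- embryo$tree
  leaves <- tree_leaves(tree)
  g <- unique(node_generation(tree, leaves))
  if (length(g) != 1L || g < 4L)
    stop("embryo must be at a uniform generation >= 4")
  for (dom in names(orientation_probs)) {
    p <- orientation_probs[[dom]]
    if (!all(names(p) %in% orientation_classes))
      stop("configuration error: unknown orientation class for domain ",
           dom, ": ", paste(setdiff(names(p), orientation_classes),
                            collapse = ", "))
    if (abs(sum(p) - 1) > 1e-9)
      stop("configuration error: probabilities must sum to 1 (domain ",
           dom, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  lab <- unclass(embryo$image)
  vd <- voxel_dims(embryo$image)
  nodes <- tree$nodes
  divisions <- tree$divisions
  next_id <- max(nodes$cell_id) + 1L
  ctr0 <- embryo$axes$center

  for (id in leaves) {
    dom_anc <- ancestor_at(tree, id, 4L)
    dom <- nodes$domain[nodes$cell_id == dom_anc]
    if (is.na(dom) || is.null(orientation_probs[[dom]]))
      stop("configuration error: no orientation distribution for domain ",
           dom)
    p <- orientation_probs[[dom]]
    cls <- sample(names(p), 1L, prob = p)
    idx <- which(lab == id, arr.ind = TRUE)
    xyz <- voxel_centers(idx, vd)
    ctr <- colMeans(xyz)
    rh <- c(ctr[1] - ctr0[1], ctr[2] - ctr0[2], 0)
    nr <- sqrt(sum(rh^2))
    rh <- if (nr > 1e-9) rh / nr else c(1, 0, 0)
    normal <- switch(cls,
      anticlinal_longitudinal = if (stats::runif(1) < 0.5) c(1, 0, 0)
                                else c(0, 1, 0),
      anticlinal_transverse = c(0, 0, 1),
      periclinal = if (startsWith(dom, "apical")) {
        v <- ctr - ctr0
        v / sqrt(sum(v^2))
      } else rh,
      radial = c(-rh[2], rh[1], 0))
    f <- 0.5 + stats::runif(1, -volume_ratio_noise, volume_ratio_noise)
    side <- split_by_plane(sweep(xyz, 2L, ctr), normal, f, 0)
    ids <- c(next_id, next_id + 1L)
    next_id <- next_id + 2L
    lab[idx[side, , drop = FALSE]] <- ids[1]
    lab[idx[!side, , drop = FALSE]] <- ids[2]
    nodes <- rbind(nodes, data.frame(cell_id = ids, parent_id = id,
                                     generation = g + 1L,
                                     domain = dom))
    divisions <- rbind(divisions,
                       data.frame(mother = id, daughter1 = ids[1],
                                  daughter2 = ids[2], generation = g + 1L,
                                  orientation = cls))
  }
  new_synthetic_embryo(label_image(lab, vd),
                       lineage_tree(nodes, divisions),
                       embryo$axes, embryo$suspensor_label)
}
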