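#' Cell lineage tree
#'
#' A binary division tree. Each node is a cell; a division replaces a mother
#' by exactly two daughters one generation later. The root is the first
#' embryonic cell at generation 0. Division records carry the generation at
#' which the new wall was created (the daughters' generation) and, when
#' known, the orientation class of the division plane.
#'
#' @param nodes data.frame with columns `cell_id`, `parent_id` (NA for the
#'   root), `generation`, and optionally `domain`.
#' @param divisions optional data.frame with columns `mother`, `daughter1`,
#'   `daughter2`, `generation`, and optionally `orientation`; reconstructed
#'   from `nodes` when omitted.
#' @return an object of class `lineage_tree`.
#' @export
lineage_tree <- function(nodes, divisions = NULL) {
  req <- c("cell_id", "parent_id", "generation")
  if (!all(req %in% names(nodes)))
    stop("`nodes` needs columns cell_id, parent_id, generation")
  nodes$cell_id <- as.integer(nodes$cell_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$generation <- as.integer(nodes$generation)
  if (is.null(nodes$domain)) nodes$domain <- NA_character_
  if (anyDuplicated(nodes$cell_id)) stop("duplicated cell ids")
  roots <- nodes$cell_id[is.na(nodes$parent_id)]
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (nodes$generation[nodes$cell_id == roots] != 0L)
    stop("root must be at generation 0")
  kid_count <- table(nodes$parent_id)
  if (any(kid_count != 2L))
    stop("non-binary node: every divided cell must have exactly 2 daughters")
  gen_of <- stats::setNames(nodes$generation, nodes$cell_id)
  internal <- !is.na(nodes$parent_id)
  if (any(nodes$generation[internal] !=
          gen_of[as.character(nodes$parent_id[internal])] + 1L))
    stop("child generation must equal parent generation + 1")
  if (is.null(divisions)) {
    mothers <- unique(nodes$parent_id[internal])
    divisions <- do.call(rbind, lapply(mothers, function(m) {
      ds <- sort(nodes$cell_id[!is.na(nodes$parent_id) & nodes$parent_id == m])
      data.frame(mother = m, daughter1 = ds[1], daughter2 = ds[2],
                 generation = unname(gen_of[as.character(ds[1])]),
                 orientation = NA_character_)
    }))
    if (is.null(divisions))
      divisions <- data.frame(mother = integer(0), daughter1 = integer(0),
                              daughter2 = integer(0), generation = integer(0),
                              orientation = character(0))
  }
  structure(list(nodes = nodes, divisions = divisions, root = roots),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d cells, %d divisions, generations 0..%d\n",
              nrow(x$nodes), nrow(x$divisions), max(x$nodes$generation)))
  invisible(x)
}

tree_children <- function(tree, id) {
  tree$nodes$cell_id[!is.na(tree$nodes$parent_id) & tree$nodes$parent_id == id]
}

tree_leaves <- function(tree) {
  setdiff(tree$nodes$cell_id, tree$nodes$parent_id[!is.na(tree$nodes$parent_id)])
}

node_generation <- function(tree, id) {
  g <- tree$nodes$generation[match(id, tree$nodes$cell_id)]
  if (anyNA(g)) stop("unknown cell id: ", paste(id[is.na(g)], collapse = ", "))
  g
}

# Ancestor of `id` at generation g (id itself if already at g).
ancestor_at <- function(tree, id, g) {
  cur <- id
  gen <- node_generation(tree, cur)
  if (gen < g) stop("cell ", id, " is shallower than generation ", g)
  while (gen > g) {
    cur <- tree$nodes$parent_id[match(cur, tree$nodes$cell_id)]
    gen <- gen - 1L
  }
  cur
}

#' Merge daughters back to an earlier generation
#'
#' Reconstructs the label image at generation `g` by recursively merging
#' sister regions: each voxel is relabelled with the id of its cell's
#' ancestor at generation `g`. Reserved labels (exterior 0 and any label not
#' present in the tree, such as the suspensor) are left untouched.
#'
#' @param image a [label_image()] whose cell labels are the tree's leaves.
#' @param tree a [lineage_tree()].
#' @param g target generation; all leaves must be at generation >= g.
#' @return a `label_image` with one region per generation-`g` cell.
#' @export
reconstruct_generation <- function(image, tree, g) {
  labs <- cell_labels(image)
  in_tree <- labs %in% tree$nodes$cell_id
  leaves <- labs[in_tree]
  if (length(leaves) && any(node_generation(tree, leaves) < g))
    stop("lineage-depth error: some imaged cells are shallower than ",
         "generation ", g)
  map <- vapply(leaves, function(id) ancestor_at(tree, id, g), integer(1))
  a <- unclass(image)
  out <- a
  if (length(leaves)) {
    idx <- match(a, leaves)
    hit <- !is.na(idx)
    out[hit] <- map[idx[hit]]
  }
  label_image(out, voxel_dims(image))
}

#' Origin of the interface between two cells
#'
#' Returns the generation at which the wall separating two cells was
#' created: the generation of the division of their lowest common ancestor.
#' Contacts with the exterior or the suspensor predate all divisions and
#' return the reserved origin codes `"outer_surface"` and `"suspensor_wall"`.
#'
#' @param tree a [lineage_tree()].
#' @param cell_a,cell_b cell ids, or one of the reserved labels given in
#'   `reserved`.
#' @param reserved named integer vector mapping the reserved origin codes to
#'   labels, e.g. `c(outer_surface = 0L, suspensor_wall = 1L)`.
#' @return an integer generation, or a reserved origin code (character).
#' @export
interface_generation <- function(tree, cell_a, cell_b,
                                 reserved = c(outer_surface = 0L,
                                              suspensor_wall = 1L)) {
  for (code in names(reserved)) {
    if (cell_a == reserved[[code]] || cell_b == reserved[[code]])
      return(code)
  }
  if (cell_a == cell_b) stop("identical cells have no interface")
  pa <- cell_a
  anc <- integer(0)
  while (!is.na(pa)) {
    anc <- c(anc, pa)
    pa <- tree$nodes$parent_id[match(pa, tree$nodes$cell_id)]
  }
  pb <- cell_b
  while (!is.na(pb)) {
    if (pb %in% anc) return(node_generation(tree, pb) + 1L)
    pb <- tree$nodes$parent_id[match(pb, tree$nodes$cell_id)]
  }
  stop("cells do not share an ancestor")
}

#' Number of division faces of a cell
#'
#' The topological shape descriptor: the number of distinct interface
#' origins among a cell's bounding contacts. An origin is either one of the
#' two initial interfaces of the first embryonic cell (the outer surface and
#' the suspensor wall, counted separately) or the generation of the division
#' that created the wall. Several neighbours across walls of the same origin
#' count once, so the descriptor is insensitive to how later divisions
#' subdivided a wall. The first embryonic cell has two faces; noise-free
#' stereotyped cells have 3, 4, {4,5} and {4,5,5,6} faces at generations
#' 1 to 4.
#'
#' @param image a [label_image()] at the cell's generation.
#' @param tree a [lineage_tree()].
#' @param cell_id label of the cell in `image`.
#' @param suspensor_label reserved suspensor label (NA if absent).
#' @return integer face count.
#' @export
count_division_faces <- function(image, tree, cell_id, suspensor_label = 1L) {
  nb <- neighbor_labels(image, cell_id)
  if (length(nb) == 0L)
    stop("segmentation error: cell ", cell_id, " has no boundary contacts")
  reserved <- c(outer_surface = 0L)
  if (!is.na(suspensor_label))
    reserved <- c(reserved, suspensor_wall = as.integer(suspensor_label))
  origins <- vapply(nb, function(b)
    as.character(interface_generation(tree, cell_id, b, reserved)),
    character(1))
  length(unique(origins))
}

#' Shape class from a face count
#'
#' Cells are classified by their number of division faces: 4 faces are
#' topologically equivalent to a tetrahedron (T), 5 to a triangular prism
#' (P), 6 to a cuboid (C); any other count falls in the catch-all class O.
#'
#' @param face_count integer face count(s), each >= 2.
#' @return factor with levels T, P, C, O.
#' @export
classify_shape <- function(face_count) {
  face_count <- as.integer(face_count)
  if (any(is.na(face_count)) || any(face_count < 2L))
    stop("face counts must be integers >= 2")
  cls <- rep("O", length(face_count))
  cls[face_count == 4L] <- "T"
  cls[face_count == 5L] <- "P"
  cls[face_count == 6L] <- "C"
  factor(cls, levels = c("T", "P", "C", "O"))
}

#' Distribution of face-count classes at one generation
#'
#' Counts cells per face-count class at a generation, optionally restricted
#' to one of the four 16C domains (domain tags are read from the tree's
#' generation-4 ancestors).
#'
#' @param image a [label_image()] whose cells are tree leaves.
#' @param tree a [lineage_tree()].
#' @param generation generation at which to evaluate the distribution.
#' @param domain optional domain tag filter (e.g. "basal_outer").
#' @param suspensor_label reserved suspensor label.
#' @return a `shape_distribution`: data.frame with columns `faces`, `count`,
#'   `proportion`, plus attributes `generation` and `N`.
#' @export
shape_distribution <- function(image, tree, generation, domain = NULL,
                               suspensor_label = 1L) {
  img_g <- reconstruct_generation(image, tree, generation)
  cells <- intersect(cell_labels(img_g), tree$nodes$cell_id)
  cells <- cells[node_generation(tree, cells) == generation]
  if (!is.null(domain)) {
    keep <- vapply(cells, function(id) {
      anc <- if (node_generation(tree, id) >= 4L) ancestor_at(tree, id, 4L) else id
      isTRUE(tree$nodes$domain[match(anc, tree$nodes$cell_id)] == domain)
    }, logical(1))
    cells <- cells[keep]
  }
  if (length(cells) == 0L) {
    out <- data.frame(faces = integer(0), count = integer(0),
                      proportion = numeric(0))
  } else {
    f <- vapply(cells, function(id)
      count_division_faces(img_g, tree, id, suspensor_label), integer(1))
    tab <- table(f)
    out <- data.frame(faces = as.integer(names(tab)),
                      count = as.integer(tab),
                      proportion = as.numeric(tab) / length(f))
  }
  attr(out, "generation") <- generation
  attr(out, "N") <- sum(out$count)
  class(out) <- c("shape_distribution", class(out))
  out
}

#' Entropy of a shape-class distribution
#'
#' Shannon entropy \eqn{-\sum_f p_f \log p_f} of the proportions of cells
#' per face-count class, with the convention \eqn{0 \log 0 = 0}. Reported in
#' nats by default (the analysis only uses relative comparisons); use
#' `base = 2` for bits.
#'
#' @param dist a `shape_distribution`, or a numeric vector of proportions.
#' @param base logarithm base (`exp(1)` for nats).
#' @return entropy (non-negative; 0 when all cells share one class).
#' @export
shape_entropy <- function(dist, base = exp(1)) {
  p <- if (inherits(dist, "shape_distribution")) dist$proportion
       else as.numeric(dist)
  if (length(p) == 0L) return(0)
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("distribution error: proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p, base = base)) + 0   # + 0 normalizes IEEE -0
}

#' Assign embryo domains at or beyond the 8C stage
#'
#' Tags each cell as apical or basal (side of the generation-3 transverse
#' wall along the apical-basal axis) and, from generation 4 on, as outer
#' (touching the exterior) or inner.
#'
#' @param image a [label_image()].
#' @param tree a [lineage_tree()].
#' @param axes embryo frame: list with `ab_axis` (unit vector), `g3_z`
#'   (physical height of the transverse 8C wall) as produced by
#'   [make_stereotyped_embryo()].
#' @param generation generation of the cells in `image` (>= 3).
#' @param suspensor_label reserved suspensor label.
#' @return named character vector of domain tags per cell id: "apical"/
#'   "basal" at 8C, crossed with "_inner"/"_outer" from 16C on.
#' @export
assign_domains <- function(image, tree, axes, generation,
                           suspensor_label = 1L) {
  if (is.null(axes$ab_axis) || is.null(axes$g3_z))
    stop("configuration error: embryo axes (ab_axis, g3_z) are required")
  cells <- setdiff(cell_labels(image), suspensor_label)
  cells <- intersect(cells, tree$nodes$cell_id)
  tags <- vapply(cells, function(id) {
    ctr <- cell_center(image, id)
    pole <- if (sum(ctr * axes$ab_axis) > axes$g3_z) "apical" else "basal"
    if (generation < 4L) return(pole)
    side <- if (0L %in% neighbor_labels(image, id)) "outer" else "inner"
    paste(pole, side, sep = "_")
  }, character(1))
  stats::setNames(tags, cells)
}
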