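#' Voxel grid geometry
#'
#' A voxel grid couples an integer array shape with the physical edge
#' lengths of a voxel. All physical quantities in the package are expressed
#' in micrometres (lengths) and square micrometres (areas). The default
#' calibration corresponds to a typical confocal acquisition with anisotropic
#' axial sampling.
#'
#' @param shape integer vector of length 3, the array dimensions (nx, ny, nz).
#' @param voxel_dims numeric vector of length 3, physical voxel edge lengths
#'   (dx, dy, dz) in micrometres.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_dims = c(0.17, 0.17, 0.35)) {
  shape <- as.integer(shape)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive integers")
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("`voxel_dims` must be three positive lengths (micrometres)")
  structure(list(shape = shape, voxel_dims = voxel_dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %d x %d x %d, voxel %g x %g x %g um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]))
  invisible(x)
}

#' Calibrated 3D label image
#'
#' Wraps a 3D integer array of cell labels (background 0) together with its
#' voxel calibration. Labels are arbitrary positive integers; one label may
#' be reserved for the suspensor (see [make_stereotyped_embryo()]).
#'
#' @param data 3D integer array; 0 marks background (exterior).
#' @param voxel_dims physical voxel edge lengths (dx, dy, dz) in micrometres.
#' @return an object of class `label_image` (a 3D integer array with a
#'   `voxel_dims` attribute).
#' @export
label_image <- function(data, voxel_dims = c(0.17, 0.17, 0.35)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  storage.mode(data) <- "integer"
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("`voxel_dims` must be three positive lengths")
  attr(data, "voxel_dims") <- voxel_dims
  class(data) <- c("label_image", class(data))
  data
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x)
  labs <- cell_labels(x)
  cat(sprintf("label_image %d x %d x %d (%d labels, voxel %s um)\n",
              d[1], d[2], d[3], length(labs),
              paste(signif(voxel_dims(x), 3), collapse = " x ")))
  invisible(x)
}

#' @rdname label_image
#' @param x a `label_image`.
#' @export
voxel_dims <- function(x) {
  vd <- attr(x, "voxel_dims")
  if (is.null(vd)) stop("object carries no voxel calibration")
  vd
}

#' @rdname label_image
#' @export
cell_labels <- function(x) {
  labs <- sort(unique(as.integer(x)))
  labs[labs != 0L]
}

#' Physical coordinates of voxel centers
#'
#' Voxel (i, j, k) (1-based array indices) has its center at
#' ((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz).
#'
#' @param idx integer matrix of 1-based array indices (rows = voxels).
#' @param voxel_dims voxel edge lengths.
#' @return numeric matrix of physical coordinates in micrometres.
#' @keywords internal
voxel_centers <- function(idx, voxel_dims) {
  sweep(idx - 0.5, 2L, voxel_dims, "*")
}

#' Centroid of a cell mask
#'
#' The cell center is the average physical position of the voxel centers in
#' the mask.
#'
#' @param mask logical 3D array, or a `label_image` together with `label`.
#' @param label optional label selecting a cell when `mask` is a label image.
#' @param voxel_dims voxel calibration; taken from `mask` when available.
#' @return numeric length-3 vector, micrometres.
#' @export
cell_center <- function(mask, label = NULL, voxel_dims = NULL) {
  if (!is.null(label)) {
    if (is.null(voxel_dims)) voxel_dims <- voxel_dims(mask)
    mask <- unclass(mask) == label
  } else if (is.null(voxel_dims)) {
    voxel_dims <- attr(mask, "voxel_dims")
    if (is.null(voxel_dims)) voxel_dims <- c(1, 1, 1)
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  unname(colMeans(voxel_centers(idx, voxel_dims)))
}

# Pairs of 6-adjacent labels in a label image, with face contact counts and,
# optionally, face-center coordinates. Background (0) participates, so
# exterior contacts are visible to callers.
adjacency_pairs <- function(img) {
  a <- unclass(img)
  d <- dim(a)
  pairs <- list()
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    idx_lo <- switch(axis,
                     a[-n, , , drop = FALSE],
                     a[, -n, , drop = FALSE],
                     a[, , -n, drop = FALSE])
    idx_hi <- switch(axis,
                     a[-1, , , drop = FALSE],
                     a[, -1, , drop = FALSE],
                     a[, , -1, drop = FALSE])
    diff <- idx_lo != idx_hi
    if (!any(diff)) next
    pairs[[axis]] <- cbind(pmin(idx_lo[diff], idx_hi[diff]),
                           pmax(idx_lo[diff], idx_hi[diff]))
  }
  if (length(pairs) == 0L)
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "n_faces"))))
  m <- do.call(rbind, pairs)
  key <- paste(m[, 1], m[, 2])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  out <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]),
               as.integer(tab))
  colnames(out) <- c("a", "b", "n_faces")
  out
}

# Labels 6-adjacent to a given label (including 0 = exterior).
neighbor_labels <- function(img, label) {
  adj <- adjacency_pairs(img)
  sel <- adj[, "a"] == label | adj[, "b"] == label
  if (!any(sel)) return(integer(0))
  nb <- c(adj[sel, "a"], adj[sel, "b"])
  sort(unique(nb[nb != label]))
}

# Interface voxel faces between two labels: physical face-center coordinates
# and the face-normal axis (1, 2 or 3). Used for plane orientation and
# distance-to-center computations.
interface_faces <- function(img, label_a, label_b) {
  a <- unclass(img)
  d <- dim(a)
  vd <- attr(img, "voxel_dims")
  if (is.null(vd)) vd <- c(1, 1, 1)
  centers <- list()
  axes <- list()
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    lo <- switch(axis, a[-n, , , drop = FALSE], a[, -n, , drop = FALSE],
                 a[, , -n, drop = FALSE])
    hi <- switch(axis, a[-1, , , drop = FALSE], a[, -1, , drop = FALSE],
                 a[, , -1, drop = FALSE])
    hit <- (lo == label_a & hi == label_b) | (lo == label_b & hi == label_a)
    if (!any(hit)) next
    idx <- which(hit, arr.ind = TRUE)
    ctr <- voxel_centers(idx, vd)
    ctr[, axis] <- ctr[, axis] + vd[axis] / 2  # face sits between the voxels
    centers[[length(centers) + 1L]] <- ctr
    axes[[length(axes) + 1L]] <- rep(axis, nrow(ctr))
  }
  if (length(centers) == 0L)
    return(list(centers = matrix(numeric(0), ncol = 3), axis = integer(0)))
  list(centers = do.call(rbind, centers), axis = unlist(axes))
}
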