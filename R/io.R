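#' Write and read calibrated label images
#'
#' Label images are stored as multi-page 16-bit TIFF (one page per z slice)
#' with a JSON sidecar (`<path>.json`) carrying the voxel calibration, the
#' reserved labels and the embryo axes. Round trips are lossless for
#' integer labels below 2^16.
#'
#' @param image a [label_image()].
#' @param path TIFF file path.
#' @param suspensor_label reserved suspensor label recorded in the sidecar.
#' @param axes optional embryo axes list recorded in the sidecar.
#' @return `write_label_image` returns `path` invisibly; `read_label_image`
#'   returns a `label_image` with attributes `suspensor_label` and `axes`.
#' @export
write_label_image <- function(image, path, suspensor_label = NA_integer_,
                              axes = NULL) {
  a <- unclass(image)
  if (max(a) > 65535L) stop("labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(
    voxel_dims = voxel_dims(image),
    shape = dim(a),
    axis_order = "x fastest, z slowest; 0-based voxel (i,j,k) center at ((i+0.5)dx, (j+0.5)dy, (k+0.5)dz) um",
    exterior_label = 0L,
    suspensor_label = if (is.na(suspensor_label)) NULL
                      else as.integer(suspensor_label),
    axes = axes)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("calibration error: sidecar JSON '", sidecar_path,
         "' with field 'voxel_dims' is missing")
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sidecar$voxel_dims))
    stop("calibration error: sidecar misses field 'voxel_dims'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  a <- array(0L, d)
  for (k in seq_along(pages))
    a[, , k] <- as.integer(round(pages[[k]] * 65535))
  img <- label_image(a, as.numeric(sidecar$voxel_dims))
  attr(img, "suspensor_label") <-
    if (is.null(sidecar$suspensor_label)) NA_integer_
    else as.integer(sidecar$suspensor_label)
  attr(img, "axes") <- sidecar$axes
  img
}

#' Write and read lineage trees
#'
#' Lineage trees travel as TSV with the header
#' `cell_id<TAB>parent_id<TAB>generation<TAB>domain` and one row per node;
#' the root's parent is "-". A fifth optional column `orientation` stores
#' the division-orientation class of the wall that created the cell's
#' sister pair. Binary-tree invariants are validated on read and format
#' errors are reported with their row number.
#'
#' @param tree a [lineage_tree()].
#' @param path TSV file path.
#' @return `write_lineage` returns `path` invisibly; `read_lineage` a
#'   [lineage_tree()].
#' @export
write_lineage <- function(tree, path) {
  nd <- tree$nodes
  ori <- tree$divisions$orientation[
    match(nd$cell_id, tree$divisions$daughter1)]
  ori2 <- tree$divisions$orientation[
    match(nd$cell_id, tree$divisions$daughter2)]
  ori[is.na(ori)] <- ori2[is.na(ori)]
  out <- data.frame(
    cell_id = nd$cell_id,
    parent_id = ifelse(is.na(nd$parent_id), "-", nd$parent_id),
    generation = nd$generation,
    domain = ifelse(is.na(nd$domain), "-", nd$domain),
    orientation = ifelse(is.na(ori), "-", ori))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lineage
#' @export
read_lineage <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("cell_id", "parent_id", "generation")
  if (!all(req %in% names(raw)))
    stop("format error: lineage file needs columns ",
         paste(req, collapse = ", "))
  nodes <- data.frame(
    cell_id = as.integer(raw$cell_id),
    parent_id = ifelse(raw$parent_id == "-", NA_integer_,
                       suppressWarnings(as.integer(raw$parent_id))),
    generation = as.integer(raw$generation),
    domain = if (is.null(raw$domain)) NA_character_
             else ifelse(raw$domain == "-", NA_character_, raw$domain))
  bad <- which(is.na(nodes$cell_id) | is.na(nodes$generation))
  if (length(bad))
    stop("format error at row ", bad[1] + 1L, ": unparseable node")
  gen_of <- stats::setNames(nodes$generation, nodes$cell_id)
  internal <- which(!is.na(nodes$parent_id))
  mismatch <- internal[nodes$generation[internal] !=
                         gen_of[as.character(nodes$parent_id[internal])] + 1L]
  if (length(mismatch))
    stop("format error at row ", mismatch[1] + 1L,
         ": child generation must equal parent generation + 1")
  kid_count <- table(nodes$parent_id)
  nb <- names(kid_count)[kid_count != 2L]
  if (length(nb)) {
    row <- which(nodes$cell_id == as.integer(nb[1]))
    stop("format error at row ", row + 1L, ": non-binary node ", nb[1])
  }
  tree <- lineage_tree(nodes)
  if (!is.null(raw$orientation)) {
    ori <- ifelse(raw$orientation == "-", NA_character_, raw$orientation)
    m <- match(tree$divisions$daughter1, nodes$cell_id)
    tree$divisions$orientation <- ori[m]
  }
  tree
}
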