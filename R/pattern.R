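#' Match score between two divisions of the same mother
#'
#' Overlap statistic between two binary partitions of a mother cell: with
#' observed daughters A, B and simulated daughters A', B',
#' \deqn{score = \max\{(|A \cap A'| + |B \cap B'|),
#'                     (|A \cap B'| + |B \cap A'|)\} / |A \cup B|.}
#' The score is symmetric, invariant to swapping daughter labels on either
#' side, and lies in [0.5, 1]: 0.5 is the minimum possible overlap and 1
#' perfect correspondence.
#'
#' @param observed,simulated [division_partition()]s over the same mother
#'   voxel set.
#' @return list with `value` and `pairing` ("direct" or "swapped").
#' @export
match_score <- function(observed, simulated) {
  lo <- observed$labels
  ls <- simulated$labels
  if (!identical(dim(lo), dim(ls)) || !identical(lo != 0L, ls != 0L))
    stop("partitions must cover the same mother voxel set")
  fg <- lo != 0L
  a <- lo[fg]
  b <- ls[fg]
  n <- length(a)
  direct <- sum(a == b)
  swapped <- n - direct
  list(value = max(direct, swapped) / n,
       pairing = if (direct >= swapped) "direct" else "swapped")
}

#' Solution table over a batch of simulations
#'
#' One row per simulation with its interface area, distance to the mother
#' cell center, achieved volume ratio and (optionally) match score against
#' an observed division -- the data behind the area/distance distribution
#' plots used to read off the division rule.
#'
#' @param results list of `simulation_result`s sharing one mother mask.
#' @param observed optional observed [division_partition()].
#' @return data.frame of class `solution_table` with columns `run`, `area`,
#'   `distance`, `volume_ratio`, `cleaned`, `seed` and `score`/`pairing`
#'   when `observed` is given.
#' @export
build_solution_table <- function(results, observed = NULL) {
  if (length(results) == 0L) stop("empty result list")
  tab <- data.frame(
    run = seq_along(results),
    area = vapply(results, `[[`, numeric(1), "interface_area"),
    distance = vapply(results, `[[`, numeric(1), "distance_to_center"),
    volume_ratio = vapply(results, `[[`, numeric(1), "volume_ratio"),
    cleaned = vapply(results, `[[`, logical(1), "cleaned"),
    seed = vapply(results, function(r)
      if (is.null(r$seed)) NA_integer_ else as.integer(r$seed), integer(1)))
  if (!is.null(observed)) {
    ms <- lapply(results, function(r) match_score(observed, r$partition))
    tab$score <- vapply(ms, `[[`, numeric(1), "value")
    tab$pairing <- vapply(ms, `[[`, character(1), "pairing")
  }
  class(tab) <- c("solution_table", class(tab))
  tab
}

# +1/-1 encoding of partitions over the (shared) foreground, in fixed voxel
# order; match score between runs i and j is 0.5 + |x_i . x_j| / (2N).
partition_sign_matrix <- function(results) {
  fg <- results[[1]]$partition$labels != 0L
  X <- vapply(results, function(r) {
    v <- r$partition$labels[fg]
    ifelse(v == 1L, 1, -1)
  }, numeric(sum(fg)))
  matrix(X, nrow = sum(fg))
}

#' Group simulations into solution families
#'
#' Hierarchical clustering of simulations on the match-score distance
#' (1 - score), cut at threshold `theta`. Each family gathers runs placing
#' the division plane at one orientation/position mode. Average linkage is
#' the default: under single linkage, low-volume-ratio oblique cuts bridge
#' the plane-orientation modes into one chained cluster.
#'
#' @param results list of `simulation_result`s sharing one mother mask.
#' @param theta distance threshold (default 0.25).
#' @param method linkage passed to [stats::hclust()].
#' @return integer vector of family ids (1 = largest family).
#' @export
cluster_families <- function(results, theta = 0.25, method = "average") {
  n <- length(results)
  if (n < 2L) return(rep(1L, n))
  X <- partition_sign_matrix(results)
  N <- nrow(X)
  score <- 0.5 + abs(crossprod(X)) / (2 * N)
  d <- stats::as.dist(1 - score)
  if (theta <= 0) {
    # every distinct partition its own family
    key <- apply(X, 2, paste, collapse = "")
    key2 <- apply(-X, 2, paste, collapse = "")
    canon <- pmin(key, key2)
    return(as.integer(factor(canon, levels = unique(canon))))
  }
  cl <- stats::cutree(stats::hclust(d, method = method), h = theta)
  sizes <- table(cl)
  as.integer(factor(cl, levels = names(sort(sizes, decreasing = TRUE))))
}

#' Compliance with the division rule
#'
#' Operationalizes "minimum plane area among the solutions that pass
#' through the cell center": families whose minimum distance to the center
#' falls below `delta` (by default the 10th percentile of all simulated
#' distances) count as center-passing; the family best matching the
#' observed division is compliant when it belongs to that set and attains
#' the minimal family area within it. The observed division's bottom-left
#' position is also summarized by its Pareto rank under (distance, area)
#' dominance.
#'
#' @param table a [build_solution_table()] output with match scores.
#' @param results the simulation list behind `table`.
#' @param delta distance threshold in micrometres; `NULL` for the 10th
#'   percentile of simulated distances.
#' @param theta family clustering threshold, see [cluster_families()].
#' @param method linkage for the family clustering.
#' @param area_rtol relative tolerance when comparing family area minima
#'   (discrete interfaces carry residual voxel-scale roughness).
#' @return list of class `rule_compliance` with `compliant`,
#'   `inconclusive`, `best_family`, `family_stats`, `delta` and
#'   `dominance_rank` (number of runs strictly dominating the best-matching
#'   run in both distance and area).
#' @export
rule_compliance <- function(table, results, delta = NULL, theta = 0.25,
                            method = "average", area_rtol = 0.05) {
  if (is.null(table$score))
    stop("solution table carries no match scores; supply `observed` to ",
         "build_solution_table()")
  fam <- cluster_families(results, theta = theta, method = method)
  if (is.null(delta))
    delta <- stats::quantile(table$distance, 0.1, names = FALSE)
  stats_df <- do.call(rbind, lapply(sort(unique(fam)), function(f) {
    rows <- table[fam == f, , drop = FALSE]
    cp <- rows[rows$distance <= delta, , drop = FALSE]
    data.frame(family = f, n = nrow(rows), min_area = min(rows$area),
               min_distance = min(rows$distance),
               # minimum area among this family's center-passing solutions
               min_area_centered = if (nrow(cp)) min(cp$area) else NA_real_,
               max_score = max(rows$score))
  }))
  stats_df$center_passing <- stats_df$min_distance <= delta
  best_run <- which.max(table$score)
  best_family <- fam[best_run]
  centered <- stats_df[stats_df$center_passing, , drop = FALSE]
  inconclusive <- nrow(centered) == 0L
  compliant <- if (inconclusive) NA else {
    bf <- stats_df[stats_df$family == best_family, , drop = FALSE]
    isTRUE(bf$center_passing) &&
      bf$min_area_centered <=
        min(centered$min_area_centered, na.rm = TRUE) * (1 + area_rtol)
  }
  dom <- sum(table$distance < table$distance[best_run] &
               table$area < table$area[best_run])
  structure(list(compliant = compliant, inconclusive = inconclusive,
                 best_family = best_family, best_run = best_run,
                 family_stats = stats_df, delta = delta,
                 dominance_rank = dom, families = fam),
            class = "rule_compliance")
}

#' @export
print.rule_compliance <- function(x, ...) {
  if (x$inconclusive) {
    cat("rule_compliance: inconclusive (no family passes the cell center)\n")
  } else {
    cat(sprintf(
      "rule_compliance: %s (best family %d, delta = %.3f um, %d dominating runs)\n",
      if (isTRUE(x$compliant)) "compliant" else "non-compliant",
      x$best_family, x$delta, x$dominance_rank))
  }
  invisible(x)
}

# Unit vector helper
unitv <- function(v) v / sqrt(sum(v^2))

#' Classify the orientation of a division plane
#'
#' Labels a division by the conventional embryo-frame vocabulary. The
#' primary label is anticlinal (new wall intersects the outer surface:
#' both daughters keep exterior contact; for inner cells, wall normal at
#' more than 45 degrees from the radial direction) versus periclinal. The
#' secondary label is transverse (wall normal within 45 degrees of the
#' apical-basal axis), longitudinal (vertical wall), or radial
#' (vertical wall whose normal is more than 60 degrees from the radial
#' direction, i.e. a plane containing the radial direction). The interface
#' normal is the least-variance principal axis of the interface face
#' centers; when the interface is too far from planar the label is
#' "oblique".
#'
#' @param image a [label_image()] containing both daughters.
#' @param daughter_a,daughter_b daughter labels.
#' @param axes embryo frame (see [make_stereotyped_embryo()]).
#' @param planarity_min minimum planarity (1 - smallest/middle eigenvalue
#'   ratio) below which the label is "oblique".
#' @return list with `label`, `primary`, `secondary`, `normal`,
#'   `planarity`.
#' @export
classify_orientation <- function(image, daughter_a, daughter_b, axes,
                                 planarity_min = 0.6) {
  faces <- interface_faces(image, daughter_a, daughter_b)
  if (nrow(faces$centers) == 0L) stop("cells share no interface")
  ctr <- colMeans(faces$centers)
  normal <- c(1, 0, 0)
  planarity <- 1
  if (nrow(faces$centers) >= 3L) {
    cov <- stats::cov(faces$centers)
    eig <- eigen(cov, symmetric = TRUE)
    normal <- eig$vectors[, 3]
    ev <- pmax(eig$values, 0)
    planarity <- if (ev[2] > 0) 1 - ev[3] / ev[2] else 1
  } else {
    ax <- faces$axis[1]
    normal <- replace(c(0, 0, 0), ax, 1)
  }
  if (planarity < planarity_min)
    return(list(label = "oblique", primary = "oblique",
                secondary = "oblique", normal = normal,
                planarity = planarity))
  ab <- unitv(axes$ab_axis)
  mother_ctr <- (cell_center(image, daughter_a) * 1 +
                   cell_center(image, daughter_b)) / 2
  rh <- c(mother_ctr[1] - axes$radial_origin[1],
          mother_ctr[2] - axes$radial_origin[2], 0)
  rh <- if (sqrt(sum(rh^2)) > 1e-9) unitv(rh) else c(1, 0, 0)
  # outer-surface contact of each daughter, in voxel faces: an anticlinal
  # wall splits the outer surface into comparable parts, a periclinal wall
  # leaves at most a rim on the inner daughter
  ext_contact <- function(lbl) {
    adj <- adjacency_pairs(image)
    sel <- (adj[, "a"] == 0L & adj[, "b"] == lbl) |
      (adj[, "b"] == 0L & adj[, "a"] == lbl)
    if (any(sel)) sum(adj[sel, "n_faces"]) else 0L
  }
  ea <- ext_contact(daughter_a)
  eb <- ext_contact(daughter_b)
  primary <- if (ea + eb > 0L) {
    if (min(ea, eb) / max(ea, eb) >= 0.25) "anticlinal" else "periclinal"
  } else {
    # inner cell: compare the wall normal with the radial direction
    if (abs(sum(normal * rh)) > cos(pi / 4)) "periclinal" else "anticlinal"
  }
  cos_ab <- abs(sum(normal * ab))
  secondary <- if (cos_ab >= cos(pi / 4)) {
    "transverse"
  } else if (abs(sum(normal * rh)) < cos(pi / 3)) {
    "radial"
  } else {
    "longitudinal"
  }
  list(label = paste(primary, secondary, sep = "_"), primary = primary,
       secondary = secondary, normal = normal, planarity = planarity)
}

#' Directional length asymmetries of a cell
#'
#' Chord lengths through the cell center along the embryo frame: L and R
#' are the center-to-boundary distances along the left and right radial
#' directions and H the full chord along the apical-basal (longitudinal)
#' axis. Returns the radial asymmetry L/R and the relative longitudinal
#' length H/max(L, R).
#'
#' @param mask logical 3D cell mask (with `voxel_dims` attribute) or
#'   `label_image` plus `label`.
#' @param axes list with `ab_axis` and `left` (unit radial direction toward
#'   the cell's left side); `right` defaults to `-left`.
#' @param label optional cell label.
#' @param center measurement center (micrometres); defaults to the mask's
#'   recorded construction center when present (synthetic shapes), else the
#'   centroid. Centroid chords are blind to affine left/right skew, so for
#'   generated shapes the construction center is the faithful reference.
#' @param step ray-marching step in voxel fractions.
#' @return list with `L`, `R`, `H` (micrometres), `left_right` = L/R and
#'   `longitudinal` = H/max(L, R).
#' @export
length_asymmetries <- function(mask, axes, label = NULL, center = NULL,
                               step = 0.25) {
  if (!is.null(label)) {
    vd <- voxel_dims(mask)
    mask0 <- unclass(mask) == label
    attr(mask0, "voxel_dims") <- vd
    mask <- mask0
  }
  vd <- attr(mask, "voxel_dims")
  if (is.null(vd)) vd <- c(1, 1, 1)
  ctr <- center
  if (is.null(ctr)) ctr <- attr(mask, "center")
  if (is.null(ctr)) ctr <- cell_center(mask, voxel_dims = vd)
  d <- dim(mask)
  ray_length <- function(dir) {
    dir <- unitv(dir)
    h <- step * min(vd)
    t <- 0
    repeat {
      p <- ctr + (t + h) * dir
      ijk <- ceiling(p / vd)
      inside <- all(ijk >= 1) && all(ijk <= d) &&
        mask[ijk[1], ijk[2], ijk[3]]
      if (!inside) break
      t <- t + h
    }
    t
  }
  left <- unitv(axes$left)
  right <- if (!is.null(axes$right)) unitv(axes$right) else -left
  ab <- unitv(axes$ab_axis)
  L <- ray_length(left)
  R <- ray_length(right)
  H <- ray_length(ab) + ray_length(-ab)
  if (L == 0 || R == 0 || H == 0)
    stop("geometry error: chord leaves the mask at the center")
  list(L = L, R = R, H = H, left_right = L / R,
       longitudinal = H / max(L, R))
}

#' Ordered division-orientation sequences over two generations
#'
#' For every grandmother cell whose daughters both divided, records the
#' sequence (mother orientation, daughter orientations) and counts
#' sequences per domain. Sequences that generate topologically identical
#' granddaughter arrangements are mapped to a common attractor class: two
#' crossed flat cuts (the mother's orientation followed by the orthogonal
#' orientation in both daughters) yield the same 2x2 checkerboard whichever
#' orientation comes first.
#'
#' @param tree a [lineage_tree()] whose division records carry orientation
#'   labels for at least two consecutive generations.
#' @param generation generation of the first division of the pair.
#' @return data.frame with columns `domain`, `sequence`, `attractor`,
#'   `count`.
#' @export
pattern_sequences <- function(tree, generation) {
  div <- tree$divisions
  first <- div[div$generation == generation, , drop = FALSE]
  second <- div[div$generation == generation + 1L, , drop = FALSE]
  if (nrow(first) == 0L || nrow(second) == 0L)
    stop("depth error: need divisions at two consecutive generations")
  rows <- list()
  for (i in seq_len(nrow(first))) {
    o1 <- first$orientation[i]
    ds <- c(first$daughter1[i], first$daughter2[i])
    sub <- second[second$mother %in% ds, , drop = FALSE]
    if (nrow(sub) != 2L) next
    o2 <- sort(sub$orientation)
    dom <- tree$nodes$domain[match(first$mother[i], tree$nodes$cell_id)]
    if (is.na(dom)) {
      anc <- tryCatch(ancestor_at(tree, first$mother[i], 4L),
                      error = function(e) NA_integer_)
      if (!is.na(anc))
        dom <- tree$nodes$domain[match(anc, tree$nodes$cell_id)]
    }
    seq_label <- paste(o1, "->", paste(o2, collapse = "+"))
    attractor <- if (o2[1] == o2[2] && o2[1] != o1) {
      paste("checkerboard:", paste(sort(c(o1, o2[1])), collapse = "|"))
    } else if (o2[1] == o2[2] && o2[1] == o1) {
      paste("stack:", o1)
    } else {
      seq_label
    }
    rows[[length(rows) + 1L]] <- data.frame(
      domain = if (is.na(dom)) "unassigned" else dom,
      sequence = seq_label, attractor = attractor)
  }
  if (length(rows) == 0L)
    stop("depth error: no grandmother with two divided daughters")
  all_rows <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(all_rows))),
                          all_rows[c("domain", "sequence", "attractor")],
                          FUN = sum)
  agg[order(agg$domain, -agg$count), , drop = FALSE]
}
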