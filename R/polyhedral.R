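#' Planar polyhedral graph
#'
#' The vertex/edge/face graph of a polyhedral cell shape with a fixed planar
#' embedding (faces as ordered vertex cycles), as displayed by a Schlegel
#' diagram. Valid graphs satisfy the Euler relation V - E + F = 2 and have
#' every edge on exactly two faces.
#'
#' @param n_vertices number of vertices (ids 1..n).
#' @param faces list of integer vectors, each an ordered vertex cycle.
#' @param validate check the polyhedral invariants.
#' @return an object of class `poly_graph` with elements `n_vertices`,
#'   `edges` (2-column matrix) and `faces`.
#' @export
poly_graph <- function(n_vertices, faces, validate = TRUE) {
  edges <- face_edges(faces)
  g <- structure(list(n_vertices = as.integer(n_vertices), edges = edges,
                      faces = lapply(faces, as.integer)),
                 class = "poly_graph")
  if (validate) validate_poly_graph(g)
  g
}

face_edges <- function(faces) {
  e <- do.call(rbind, lapply(faces, function(f) {
    k <- length(f)
    cbind(f, f[c(2:k, 1)])
  }))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

validate_poly_graph <- function(g) {
  V <- g$n_vertices
  E <- nrow(g$edges)
  F <- length(g$faces)
  if (V - E + F != 2L)
    stop("structure error: Euler relation V - E + F = 2 violated")
  # every edge on exactly 2 faces, faces simple
  counts <- new.env()
  for (f in g$faces) {
    if (anyDuplicated(f) || length(f) < 3L)
      stop("structure error: faces must be simple cycles of length >= 3")
    k <- length(f)
    for (i in seq_len(k)) {
      key <- paste(sort(c(f[i], f[i %% k + 1L])), collapse = "-")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  cnt <- unlist(as.list(counts))
  if (length(cnt) != E || any(cnt != 2L))
    stop("structure error: every edge must lie on exactly 2 faces")
  invisible(g)
}

#' @export
print.poly_graph <- function(x, ...) {
  cat(sprintf("poly_graph: V=%d E=%d F=%d\n", x$n_vertices,
              nrow(x$edges), length(x$faces)))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE)
}

#' Canonical polyhedral graphs of the main cell shapes
#'
#' The three cell-shape topologies dominating the late generations:
#' tetrahedron (V=4, E=6, F=4), triangular prism (V=6, E=9, F=5) and cuboid
#' (V=8, E=12, F=6), each with a fixed embedding.
#'
#' @param shape "T", "P" or "C" (see [classify_shape()]).
#' @return a [poly_graph()].
#' @export
canonical_graph <- function(shape = c("T", "P", "C")) {
  shape <- match.arg(as.character(shape), c("T", "P", "C"))
  faces <- switch(shape,
    T = list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
    P = list(c(1, 2, 3), c(4, 6, 5), c(1, 2, 5, 4), c(2, 3, 6, 5),
             c(3, 1, 4, 6)),
    C = list(c(1, 2, 3, 4), c(5, 8, 7, 6), c(1, 2, 6, 5), c(2, 3, 7, 6),
             c(3, 4, 8, 7), c(4, 1, 5, 8)))
  poly_graph(switch(shape, T = 4L, P = 6L, C = 8L), faces)
}

#' Classify a polyhedral graph against the canonical catalogue
#'
#' Graph isomorphism against the canonical tetrahedron, prism and cuboid
#' skeletons (with matching face counts); anything else is O.
#'
#' @param g a [poly_graph()].
#' @return one of "T", "P", "C", "O".
#' @export
classify_graph_shape <- function(g) {
  sig <- c(g$n_vertices, nrow(g$edges), length(g$faces))
  for (s in c("T", "P", "C")) {
    ref <- canonical_graph(s)
    if (all(sig == c(ref$n_vertices, nrow(ref$edges), length(ref$faces))) &&
        igraph::isomorphic(as_igraph(g), as_igraph(ref)))
      return(s)
  }
  "O"
}

connected_subset <- function(adj, s) {
  if (length(s) <= 1L) return(TRUE)
  seen <- s[1]
  frontier <- s[1]
  while (length(frontier)) {
    nb <- unique(unlist(adj[frontier]))
    frontier <- setdiff(intersect(nb, s), seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(s)
}

# Build the daughter graph on side S of a bipartition. Each mother face is
# truncated at the cut: maximal arcs of S-vertices are closed by one new
# edge between the new vertices sitting on the entry and exit cut edges.
# The new vertices and new edges must form a single cycle (the new face
# created by the division); otherwise the cut does not correspond to a
# single closed curve on the cell surface and NULL is returned.
daughter_graph <- function(g, side) {
  in_s <- rep(FALSE, g$n_vertices)
  in_s[side] <- TRUE
  cut <- g$edges[xor(in_s[g$edges[, 1]], in_s[g$edges[, 2]]), , drop = FALSE]
  if (nrow(cut) == 0L) return(NULL)
  cut_key <- paste(cut[, 1], cut[, 2], sep = "-")
  new_id <- stats::setNames(g$n_vertices + seq_len(nrow(cut)), cut_key)
  ekey <- function(a, b) paste(min(a, b), max(a, b), sep = "-")
  d_faces <- list()
  new_edges <- matrix(integer(0), ncol = 2)
  for (f in g$faces) {
    k <- length(f)
    ins <- in_s[f]
    if (all(ins)) {
      d_faces[[length(d_faces) + 1L]] <- f
      next
    }
    if (!any(ins)) next
    starts <- which(ins & !ins[c(k, seq_len(k - 1L))])
    for (s0 in starts) {
      arc <- integer(0)
      i <- s0
      while (ins[(i - 1L) %% k + 1L]) {
        arc <- c(arc, f[(i - 1L) %% k + 1L])
        i <- i + 1L
        if (length(arc) == k) break
      }
      entry <- ekey(f[(s0 - 2L) %% k + 1L], f[s0])
      exit <- ekey(arc[length(arc)], f[(i - 1L) %% k + 1L])
      a <- new_id[[exit]]
      b <- new_id[[entry]]
      d_faces[[length(d_faces) + 1L]] <- c(arc, a, b)
      new_edges <- rbind(new_edges, c(min(a, b), max(a, b)))
    }
  }
  # the new vertices + new edges must form one simple cycle
  nv <- unname(new_id)
  if (nrow(new_edges) != length(nv)) return(NULL)
  if (anyDuplicated(paste(new_edges[, 1], new_edges[, 2]))) return(NULL)
  deg <- table(factor(c(new_edges[, 1], new_edges[, 2]), levels = nv))
  if (any(deg != 2L)) return(NULL)
  nadj <- lapply(nv, function(v) {
    r <- new_edges[, 1] == v | new_edges[, 2] == v
    setdiff(unique(c(new_edges[r, ])), v)
  })
  names(nadj) <- nv
  cyc <- nv[1]
  prev <- NA_integer_
  repeat {
    nxt <- setdiff(nadj[[as.character(cyc[length(cyc)])]], prev)[1]
    if (nxt == nv[1]) break
    prev <- cyc[length(cyc)]
    cyc <- c(cyc, nxt)
    if (length(cyc) > length(nv)) return(NULL)
  }
  if (length(cyc) != length(nv)) return(NULL)
  d_faces[[length(d_faces) + 1L]] <- cyc

  # relabel to 1..Vd
  verts <- c(sort(side), nv)
  remap <- stats::setNames(seq_along(verts), verts)
  d_faces <- lapply(d_faces, function(f) unname(remap[as.character(f)]))
  out <- tryCatch(poly_graph(length(verts), d_faces, validate = TRUE),
                  error = function(e) NULL)
  out
}

#' Enumerate admissible division cuts of a polyhedral graph
#'
#' A division is a bipartition of the mother's vertices into two connected
#' subsets whose cut edges can be crossed once each by a single closed curve
#' on the cell surface (divisions avoid existing vertices, in accordance
#' with four-way junction avoidance). Operationally, both daughter graphs
#' built by [apply_cut()] must be valid polyhedral graphs with one new face
#' each. Bipartitions with |S| = V/2 are listed once.
#'
#' @param g a [poly_graph()].
#' @return list of `graph_cut` objects with elements `side` (the p-vertex
#'   subset), `p`, `cut_edges`, `inherited_cyclic` and `daughter_classes`.
#' @export
enumerate_cuts <- function(g) {
  validate_poly_graph(g)
  V <- g$n_vertices
  adj <- lapply(seq_len(V), function(v) {
    r <- g$edges[, 1] == v | g$edges[, 2] == v
    setdiff(unique(c(g$edges[r, ])), v)
  })
  cuts <- list()
  for (p in seq_len(V %/% 2)) {
    for (side in utils::combn(V, p, simplify = FALSE)) {
      if (2L * p == V && !(1L %in% side)) next
      comp <- setdiff(seq_len(V), side)
      if (!connected_subset(adj, side) || !connected_subset(adj, comp)) next
      d1 <- daughter_graph(g, side)
      if (is.null(d1)) next
      d2 <- daughter_graph(g, comp)
      if (is.null(d2)) next
      in_s <- rep(FALSE, V)
      in_s[side] <- TRUE
      cut_e <- g$edges[xor(in_s[g$edges[, 1]], in_s[g$edges[, 2]]), ,
                       drop = FALSE]
      cuts[[length(cuts) + 1L]] <- structure(
        list(side = side, p = p, cut_edges = cut_e,
             inherited_cyclic = inherited_cyclic_side(g, side),
             daughter_classes = c(classify_graph_shape(d1),
                                  classify_graph_shape(d2))),
        class = "graph_cut")
    }
  }
  cuts
}

inherited_cyclic_side <- function(g, side) {
  in_s <- rep(FALSE, g$n_vertices)
  in_s[side] <- TRUE
  keep <- in_s[g$edges[, 1]] & in_s[g$edges[, 2]]
  ne <- sum(keep)
  if (ne == 0L) return(FALSE)
  sub <- igraph::graph_from_edgelist(
    matrix(as.character(g$edges[keep, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  ne > igraph::vcount(sub) - igraph::count_components(sub)
}

#' Do the edges inherited by the p-side daughter contain a cycle?
#'
#' Governs whether a division can preserve the mother's face count: with a
#' cyclic inherited subgraph one daughter keeps exactly the mother's number
#' of faces (and the other at most it); with an acyclic one at least one
#' daughter gains a face.
#'
#' @param cut a `graph_cut` from [enumerate_cuts()].
#' @param g the mother [poly_graph()].
#' @return logical.
#' @export
inherited_cyclic <- function(cut, g) {
  inherited_cyclic_side(g, cut$side)
}

#' Build the two daughter graphs of a cut
#'
#' Each daughter is the induced subgraph on its side, plus one new vertex
#' per cut edge and new edges linking consecutive new vertices around the
#' cut curve, which together form the daughter's new face.
#'
#' @param g the mother [poly_graph()].
#' @param cut a `graph_cut` (or a vertex subset).
#' @return list of two [poly_graph()] objects (p-side first).
#' @export
apply_cut <- function(g, cut) {
  side <- if (inherits(cut, "graph_cut")) cut$side else as.integer(cut)
  comp <- setdiff(seq_len(g$n_vertices), side)
  d1 <- daughter_graph(g, side)
  d2 <- daughter_graph(g, comp)
  if (is.null(d1) || is.null(d2))
    stop("cut error: bipartition is not an admissible division")
  list(d1, d2)
}

#' Daughter-shape distribution under topologically random division
#'
#' Classifies both daughters of every admissible cut of a canonical shape
#' under a uniform distribution over cuts (the random-division null) and
#' returns the proportions of daughter shapes per class.
#'
#' @param shape "T", "P" or "C".
#' @param weighting "cuts" (uniform over admissible cuts, the default) or
#'   "p_classes" (uniform over p, then uniform over cuts within p).
#' @return named numeric vector of proportions over T, P, C, O.
#' @export
theoretical_daughter_distribution <- function(shape,
                                              weighting = c("cuts",
                                                            "p_classes")) {
  weighting <- match.arg(weighting)
  cuts <- enumerate_cuts(canonical_graph(shape))
  w <- cut_weights(cuts, weighting)
  out <- c(T = 0, P = 0, C = 0, O = 0)
  for (i in seq_along(cuts))
    for (cl in cuts[[i]]$daughter_classes)
      out[cl] <- out[cl] + w[i] / 2
  out
}

cut_weights <- function(cuts, weighting) {
  if (weighting == "cuts")
    return(rep(1 / length(cuts), length(cuts)))
  ps <- vapply(cuts, `[[`, integer(1), "p")
  tab <- table(ps)
  1 / (length(tab) * as.numeric(tab[as.character(ps)]))
}

#' Self-reproducibility of the prism and cuboid shapes
#'
#' Probability, under the random-cut null, that a division reproduces the
#' mother shape in both daughters, and the cuboid-to-prism ratio of these
#' probabilities.
#'
#' @inheritParams theoretical_daughter_distribution
#' @return list with `p_prism`, `p_cuboid` and `ratio` (cuboid / prism).
#' @export
self_reproducibility_ratio <- function(weighting = c("cuts", "p_classes")) {
  weighting <- match.arg(weighting)
  prob_self <- function(shape) {
    cuts <- enumerate_cuts(canonical_graph(shape))
    w <- cut_weights(cuts, weighting)
    sum(w[vapply(cuts, function(ct)
      all(ct$daughter_classes == shape), logical(1))])
  }
  p_p <- prob_self("P")
  p_c <- prob_self("C")
  list(p_prism = p_p, p_cuboid = p_c, ratio = p_c / p_p)
}

#' Goodness of fit of observed daughter-shape counts
#'
#' Pearson chi-square test of observed per-class counts against theoretical
#' proportions, pooling classes with expected count below 5 into the
#' largest-expectation class.
#'
#' @param observed named integer vector of counts per shape class.
#' @param expected_props named numeric proportions (same classes).
#' @return `htest` object from [stats::chisq.test()].
#' @export
shape_gof_test <- function(observed, expected_props) {
  cls <- names(expected_props)
  obs <- observed[cls]
  obs[is.na(obs)] <- 0
  names(obs) <- cls
  if (sum(obs) <= 0) stop("observed counts must be positive")
  p <- as.numeric(expected_props)
  exp_n <- sum(obs) * p
  pool <- exp_n < 5
  host <- which.max(exp_n)
  pool[host] <- FALSE
  if (any(pool)) {
    obs[host] <- obs[host] + sum(obs[pool])
    p[host] <- p[host] + sum(p[pool])
    obs <- obs[!pool]
    p <- p[!pool]
  }
  if (length(obs) < 2L) stop("not enough classes after pooling")
  stats::chisq.test(obs, p = p / sum(p))
}

#' One generation of the shape-class Markov chain
#'
#' Propagates shape-class proportions through one round of divisions given
#' per-mother-class daughter distributions (theoretical or empirical).
#'
#' @param proportions named numeric vector over classes, summing to 1.
#' @param kernels named list: for each mother class, the distribution of a
#'   daughter's class.
#' @return named numeric vector: next-generation proportions.
#' @export
shape_markov_step <- function(proportions, kernels) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  cls <- names(proportions)
  out <- stats::setNames(numeric(length(cls)), cls)
  for (s in cls) {
    if (proportions[[s]] == 0) next
    k <- kernels[[s]]
    if (is.null(k)) stop("no daughter distribution for class ", s)
    if (abs(sum(k) - 1) > 1e-9)
      stop("daughter distribution for class ", s, " must sum to 1")
    for (t in names(k)) out[t] <- out[t] + proportions[[s]] * k[[t]]
  }
  out / sum(out)
}
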