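test_that("canonical graphs satisfy the polyhedral invariants", {
  sig <- list(T = c(4L, 6L, 4L), P = c(6L, 9L, 5L), C = c(8L, 12L, 6L))
  for (s in names(sig)) {
    g <- canonical_graph(s)
    expect_identical(c(g$n_vertices, nrow(g$edges), length(g$faces)),
                     sig[[s]])
    expect_identical(g$n_vertices - nrow(g$edges) + length(g$faces), 2L)
  }
  expect_error(canonical_graph("O"), "arg")
})

# expected values frozen from an independent brute-force enumeration of all
# connected vertex bipartitions with the closed-cut-curve daughter check
test_that("cut enumeration matches the brute-force counts", {
  expect_length(enumerate_cuts(canonical_graph("T")), 7L)
  expect_length(enumerate_cuts(canonical_graph("P")), 22L)
  expect_length(enumerate_cuts(canonical_graph("C")), 63L)
  # tetrahedron: 4 vertex-isolating cuts and 3 edge-isolating cuts
  tcuts <- enumerate_cuts(canonical_graph("T"))
  expect_identical(table(vapply(tcuts, `[[`, integer(1), "p")),
                   table(rep(c(1L, 2L), c(4, 3))))
})

test_that("prism cuts split into the printed daughter-pair classes", {
  cuts <- enumerate_cuts(canonical_graph("P"))
  pairs <- vapply(cuts, function(ct)
    paste(sort(ct$daughter_classes), collapse = ""), character(1))
  expect_identical(sum(pairs == "CP"), 3L)  # prism + cuboid, one per side
  expect_identical(sum(pairs == "PP"), 1L)  # parallel to the triangles
  ccuts <- enumerate_cuts(canonical_graph("C"))
  cpairs <- vapply(ccuts, function(ct)
    paste(sort(ct$daughter_classes), collapse = ""), character(1))
  expect_identical(sum(cpairs == "CC"), 3L)
})

test_that("daughter construction preserves planarity and face counts", {
  # cuboid, axis-parallel 4-edge cut: two cuboids
  g <- canonical_graph("C")
  ds <- apply_cut(g, 1:4)
  expect_identical(vapply(ds, function(d) length(d$faces), integer(1)),
                   c(6L, 6L))
  expect_identical(vapply(ds, classify_graph_shape, character(1)),
                   c("C", "C"))
  # tetrahedron, vertex-isolating cut: daughters with 4 and 5 faces
  t <- canonical_graph("T")
  dt <- apply_cut(t, 1L)
  expect_setequal(vapply(dt, function(d) length(d$faces), integer(1)),
                  c(4L, 5L))
  # every admissible cut yields Euler-valid daughters
  for (s in c("T", "P", "C")) {
    gg <- canonical_graph(s)
    for (ct in enumerate_cuts(gg)) {
      for (d in apply_cut(gg, ct)) {
        expect_identical(d$n_vertices - nrow(d$edges) + length(d$faces), 2L)
        expect_no_error(embryodiv:::validate_poly_graph(d))
      }
    }
  }
  expect_error(apply_cut(canonical_graph("C"), c(1L, 3L)), "cut error")
})

test_that("daughter vertex counts sum to V plus twice the cut size", {
  for (s in c("T", "P", "C")) {
    g <- canonical_graph(s)
    for (ct in enumerate_cuts(g)) {
      ds <- apply_cut(g, ct)
      expect_identical(ds[[1]]$n_vertices + ds[[2]]$n_vertices,
                       g$n_vertices + 2L * nrow(ct$cut_edges))
    }
  }
})

test_that("cyclic/acyclic inherited edges govern daughter face counts", {
  g <- canonical_graph("C")
  cuts <- enumerate_cuts(g)
  # face-parallel cut: p-side is one 4-cycle face
  face_cut <- Filter(function(ct) ct$p == 4L &&
                       all(ct$daughter_classes == "C"), cuts)[[1]]
  expect_true(inherited_cyclic(face_cut, g))
  t <- canonical_graph("T")
  tcuts <- enumerate_cuts(t)
  expect_false(inherited_cyclic(tcuts[[1]], t))          # single vertex
  edge_cut <- Filter(function(ct) ct$p == 2L, tcuts)[[1]]
  expect_false(inherited_cyclic(edge_cut, t))            # one edge
  # theorem, exhaustively over all enumerated cuts of T, P and C
  for (s in c("T", "P", "C")) {
    gg <- canonical_graph(s)
    mother_f <- length(gg$faces)
    for (ct in enumerate_cuts(gg)) {
      fs <- vapply(apply_cut(gg, ct), function(d) length(d$faces),
                   integer(1))
      if (inherited_cyclic(ct, gg)) {
        expect_identical(max(fs), mother_f)
        expect_lte(min(fs), mother_f)
      } else {
        expect_gt(max(fs), mother_f)
      }
    }
  }
})

test_that("no tetrahedron cut yields two four-face daughters", {
  for (ct in enumerate_cuts(canonical_graph("T")))
    expect_false(all(ct$daughter_classes == "T"))
})

test_that("enumeration is invariant under vertex relabeling", {
  set.seed(31)
  for (s in c("T", "P", "C")) {
    g <- canonical_graph(s)
    perm <- sample(g$n_vertices)
    g2 <- poly_graph(g$n_vertices,
                     lapply(g$faces, function(f) perm[f]))
    c1 <- enumerate_cuts(g)
    c2 <- enumerate_cuts(g2)
    expect_identical(length(c1), length(c2))
    tab <- function(cc) sort(vapply(cc, function(ct)
      paste(sort(ct$daughter_classes), collapse = ""), character(1)))
    expect_identical(tab(c1), tab(c2))
  }
})

test_that("random-cut daughter distributions match the enumeration", {
  dt <- theoretical_daughter_distribution("T")
  expect_equal(unname(dt), c(4, 10, 0, 0) / 14, tolerance = 1e-12)
  dc <- theoretical_daughter_distribution("C")
  expect_equal(unname(dc["C"]), 6 / 126, tolerance = 1e-12)
  for (s in c("T", "P", "C")) {
    for (w in c("cuts", "p_classes"))
      expect_equal(sum(theoretical_daughter_distribution(s, w)), 1,
                   tolerance = 1e-12)
  }
})

test_that("self-reproduction probabilities come from the enumeration", {
  sr <- self_reproducibility_ratio()
  expect_equal(sr$p_prism, 1 / 22, tolerance = 1e-12)
  expect_equal(sr$p_cuboid, 3 / 63, tolerance = 1e-12)
  expect_equal(sr$ratio, (3 / 63) / (1 / 22), tolerance = 1e-12)
})

test_that("goodness of fit behaves at its reference points", {
  p <- c(T = 0.3, P = 0.5, C = 0.2)
  # observed exactly proportional to expected: statistic 0
  gof <- shape_gof_test(c(T = 30, P = 50, C = 20), p)
  expect_equal(unname(gof$statistic), 0, tolerance = 1e-12)
  # mass concentrated in a (nearly) zero-probability class: p ~ 0
  gof2 <- shape_gof_test(c(T = 0, P = 0, C = 100),
                         c(T = 0.499, P = 0.499, C = 0.002))
  expect_lt(gof2$p.value, 1e-10)
  expect_error(shape_gof_test(c(T = 0, P = 0, C = 0), p), "positive")
  # seeded draws from the null: rejection rate near the nominal level
  set.seed(99)
  rej <- 0
  for (i in 1:200) {
    x <- stats::rmultinom(1, 1000, p)[, 1]
    names(x) <- names(p)
    rej <- rej + (shape_gof_test(x, p)$p.value < 0.05)
  }
  expect_gte(rej, 2)   # binomial 99.9% band around 5% of 200
  expect_lte(rej, 22)
})

test_that("the shape-class chain absorbs into the cuboid state", {
  kernels <- list(
    T = c(T = 4 / 14, P = 10 / 14, C = 0, O = 0),
    P = c(T = 0, P = 5 / 8, C = 3 / 8, O = 0),
    C = c(T = 0, P = 0, C = 1, O = 0),
    O = c(T = 0, P = 0, C = 0, O = 1))
  p <- c(T = 1, P = 0, C = 0, O = 0)
  last_t <- 1
  for (g in 1:12) {
    p <- shape_markov_step(p, kernels)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_lt(p[["T"]], last_t)     # tetrahedra strictly decay
    last_t <- p[["T"]]
  }
  expect_gt(p[["C"]], 0.8)
  # deterministic self-reproduction is a fixed point
  pc <- c(T = 0, P = 0, C = 1, O = 0)
  expect_equal(shape_markov_step(pc, kernels), pc, tolerance = 1e-12)
  expect_error(shape_markov_step(c(T = 0.5, P = 0.4, C = 0, O = 0), kernels),
               "sum to 1")
})
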