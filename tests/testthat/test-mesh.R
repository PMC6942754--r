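test_that("CNT-free mesh has two closed conforming membrane contours", {
  m <- fx_cell_mesh()
  sc <- m$scene
  for (spec in list(c("outer", sc$r_c), c("inner", sc$r_n))) {
    f <- m$interfaces[[spec[1]]]
    expect_false(is.null(f))
    # closed contour: as many edges as nodes, circumference ~ 2 pi r
    expect_length(f$edge_len, length(f$nodes))
    r <- as.numeric(spec[2])
    expect_equal(sum(f$edge_len), 2 * pi * r, tolerance = 1e-3)
    expect_equal(sum(f$w), sum(f$edge_len))
    # every contour node sits exactly on the circle
    d <- sqrt(rowSums(sweep(m$nodes[f$nodes, ], 2, sc$center)^2))
    expect_equal(d, rep(r, length(d)), tolerance = 1e-12)
  }
})

test_that("region tags agree with a brute-force point-location oracle", {
  skip_if_not_installed("sp")
  m <- fx_cnt_mesh()
  sc <- m$scene
  cen <- (m$nodes[m$tri[, 1], ] + m$nodes[m$tri[, 2], ] + m$nodes[m$tri[, 3], ]) / 3
  pin <- function(poly) sp::point.in.polygon(cen[, 1], cen[, 2], poly[, 1], poly[, 2]) > 0
  in_cell <- pin(circle_polygon(sc$center, sc$r_c, 4096))
  in_nuc <- pin(circle_polygon(sc$center, sc$r_n, 4096))
  oracle <- rep("medium", nrow(cen))
  oracle[in_cell] <- "cytoplasm"
  oracle[in_nuc] <- "nucleoplasm"
  for (k in seq_along(sc$cnts))
    oracle[pin(capsule_polygon(sc$cnts[[k]], 256))] <- paste0("cnt_", k)
  mismatch <- mean(oracle != m$region)
  # the only legitimate disagreements are centroids within one polygon-chord
  # sagitta of a curved boundary
  expect_lt(mismatch, 2e-3)
})

test_that("meshing is deterministic and meets the quality bound", {
  m1 <- fx_cnt_mesh()
  m2 <- suppressWarnings(build_mesh(fx_cnt_scene()))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tri, m2$tri)
  expect_gte(fx_cell_mesh()$min_angle, 8)
  expect_gte(m1$min_angle, 8)
})

test_that("triangle extraction from Delaunay edges matches deldir's own face list", {
  set.seed(7)
  P <- cbind(runif(60), runif(60))
  edges <- porefield:::.delaunay_edges(P, 1)
  T1 <- porefield:::.edges_to_triangles(edges, P)
  key1 <- sort(apply(t(apply(T1, 1, sort)), 1, paste, collapse = "-"))
  d <- deldir::deldir(P[, 1], P[, 2], suppressMsge = TRUE)
  T2 <- t(vapply(deldir::triang.list(d), function(tr) sort(tr$ptNum), integer(3)))
  key2 <- sort(apply(T2, 1, paste, collapse = "-"))
  expect_identical(key1, key2)
})

test_that("graded sizing refines capsule tips and interface duplication is consistent", {
  m <- fx_cnt_mesh()
  sc <- m$scene
  # every capsule boundary node lies on the stadium surface
  for (k in seq_along(sc$cnts)) {
    cp <- sc$cnts[[k]]
    sp <- porefield:::capsule_spine(cp)
    d <- porefield:::.dist_point_seg(m$nodes[m$capsule_nodes[[k]], ], sp[1, ], sp[2, ])
    expect_equal(d, rep(cp$D / 2, length(d)), tolerance = 1e-9)
  }
  # duplicated DOFs: tri_dof differs from tri exactly on the inner side of
  # each membrane, and duplicate indices extend the DOF count
  expect_identical(m$n_dof, m$n_nodes + length(m$interfaces$outer$dup) +
                     length(m$interfaces$inner$dup))
  changed <- which(apply(m$tri_dof != m$tri, 1, any))
  cen <- (m$nodes[m$tri[, 1], ] + m$nodes[m$tri[, 2], ] + m$nodes[m$tri[, 3], ]) / 3
  dcen <- sqrt(rowSums(sweep(cen, 2, sc$center)^2))
  expect_true(all(dcen[changed] < sc$r_c))
})

test_that("mesh sizing arguments must be ordered h_tip <= h_membrane <= h_far", {
  sc <- build_scene(default_params(), seed = 0L)
  expect_error(build_mesh(sc, h_far = 1e-6, h_membrane = 5e-6, h_tip = 2e-6))
})
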