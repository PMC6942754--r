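# Region-tagged triangulation of a scene.  Strategy: build a graded point
# cloud (exact nodes on the two membrane circles and on every capsule
# boundary, structured collar rings around each feature, a staggered
# background grid), triangulate with deldir, and verify that every membrane
# contour is conforming (each consecutive contour pair is a Delaunay edge).
# Membranes are interface contours, never meshed as thin regions: the solver
# duplicates the contour DOFs to carry the transmembrane jump.

# ---- sizing -----------------------------------------------------------------

# per-capsule cap/side target sizes; D/12 at the caps resolves the tip field
# maximum to within ~5% of further refinement
.cap_sizes <- function(cap, h_tip) {
  ht <- cap$D / 12
  if (is.finite(h_tip)) ht <- min(h_tip, cap$D / 3)
  list(h_tip = ht, h_side = 1.5 * cap$D)
}

# local target size near/inside one capsule, vectorised over P (n x 2)
.capsule_h <- function(P, cap, grade, h_tip) {
  cs <- .cap_sizes(cap, h_tip)
  sp <- capsule_spine(cap)
  R <- cap$D / 2
  d_spine <- .dist_point_seg(P, sp[1, ], sp[2, ])
  d_surf <- abs(d_spine - R)
  d1 <- sqrt((P[, 1] - sp[1, 1])^2 + (P[, 2] - sp[1, 2])^2)
  d2 <- sqrt((P[, 1] - sp[2, 1])^2 + (P[, 2] - sp[2, 2])^2)
  d_cap <- pmax(pmin(d1, d2) - R, 0)              # along-surface distance from the caps
  h_loc <- pmin(cs$h_tip + 0.7 * d_cap, cs$h_side)
  h_loc + grade * d_surf
}

# global sizing function h(x): target edge length at any point
.make_sizing <- function(scene, sz) {
  force(scene); force(sz)
  function(P) {
    if (is.null(dim(P))) P <- matrix(P, ncol = 2)
    h <- rep(sz$h_far, nrow(P))
    if (scene$has_cell) {
      d <- sqrt((P[, 1] - scene$center[1])^2 + (P[, 2] - scene$center[2])^2)
      h <- pmin(h, sz$h_membrane + sz$grade * abs(d - scene$r_c))
      h <- pmin(h, sz$h_membrane + sz$grade * abs(d - scene$r_n))
    }
    for (cap in scene$cnts)
      h <- pmin(h, .capsule_h(P, cap, sz$grade, sz$h_tip))
    h
  }
}

# ---- feature point construction --------------------------------------------

.circle_points <- function(center, radius, spacing, phase = 0) {
  n <- max(16L, round(2 * pi * radius / spacing))
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# graded positions along [0, len]: fine (h0) at both ends, up to hmax
# mid-span.  `wobble_phase` adds a small deterministic tangential
# perturbation (a fraction of the local step) so that points on opposite
# sides of a thin capsule are never exactly cocircular, which degenerate
# configurations some Delaunay implementations reject.
.graded_side <- function(len, h0, hmax, offset = 0, wobble_phase = NA) {
  if (len <= h0) return(numeric(0))
  t <- offset
  out <- if (offset > 0 && offset < len) offset else numeric(0)
  steps <- numeric(length(out))
  repeat {
    step <- min(h0 + 0.7 * min(t, max(len - t, 0)), hmax)
    t <- t + step
    if (t >= len - 0.55 * step) break
    out <- c(out, t)
    steps <- c(steps, step)
  }
  if (!is.na(wobble_phase) && length(out))
    out <- out + 0.13 * steps * sin(2.399 * seq_along(out) + wobble_phase)
  out
}

# ordered closed loop of boundary points of one capsule
.capsule_boundary <- function(cap, h_tip) {
  cs <- .cap_sizes(cap, h_tip)
  sp <- capsule_spine(cap)
  R <- cap$D / 2
  u <- c(cos(cap$angle), sin(cap$angle))
  v <- c(-u[2], u[1])
  frame_pt <- function(e, a) cbind(e[1] + R * (cos(a) * u[1] + sin(a) * v[1]),
                                   e[2] + R * (cos(a) * u[2] + sin(a) * v[2]))
  n_arc <- max(6L, ceiling(pi * R / cs$h_tip))
  a2 <- seq(-pi / 2, pi / 2, length.out = n_arc + 1)        # cap at sp[2,] (+u tip)
  a1 <- seq(pi / 2, 3 * pi / 2, length.out = n_arc + 1)     # cap at sp[1,] (-u tip), inclusive
  Ls <- cap$L - cap$D
  tA <- .graded_side(Ls, cs$h_tip, cs$h_side, wobble_phase = 0.3)   # side +v: sp2 -> sp1
  tB <- .graded_side(Ls, cs$h_tip, cs$h_side, wobble_phase = 2.1)   # side -v
  sideA <- cbind(sp[2, 1] - tA * u[1] + R * v[1], sp[2, 2] - tA * u[2] + R * v[2])
  sideB <- cbind(sp[1, 1] + tB * u[1] - R * v[1], sp[1, 2] + tB * u[2] - R * v[2])
  rbind(frame_pt(sp[2, ], a2),   # -v junction .. +v junction, both inclusive
        sideA,                   # interior side points only
        frame_pt(sp[1, ], a1),   # +v junction .. -v junction, both inclusive
        sideB)
}

# interior spine points of a capsule (helps quality in long capsules)
.capsule_spine_points <- function(cap, h_tip) {
  cs <- .cap_sizes(cap, h_tip)
  sp <- capsule_spine(cap)
  Ls <- cap$L - cap$D
  u <- c(cos(cap$angle), sin(cap$angle))
  # the cap centres anchor the fan at the core of each semicircular cap
  h_axis <- cs$h_tip + 0.35 * cap$D        # local target size on the axis
  t <- if (Ls >= 2 * cap$D) .graded_side(Ls, h_axis, cs$h_side) else numeric(0)
  rbind(sp, cbind(sp[1, 1] + t * u[1], sp[1, 2] + t * u[2]))
}

# collar/offset rings around a circle feature; returns list of matrices
.circle_rings <- function(center, radius, h0, grade, h_far, side, inward_limit = 0) {
  out <- list()
  for (dir in c(-1, 1)) {
    delta <- 0.9 * h0
    j <- 0
    repeat {
      h_here <- h0 + grade * delta
      r <- radius + dir * delta
      if (h_here >= h_far || r <= max(inward_limit, 1.2 * h_here)) break
      j <- j + 1
      out[[length(out) + 1]] <-
        list(pts = .circle_points(center, r, 0.9 * h_here, phase = 0.37 * j),
             h = h_here)
      delta <- delta + 0.85 * h_here
      if (j > 200) break
    }
  }
  out
}

# offset rings around a capsule; stadium offsets (outward and inward) are
# stadiums, so the boundary walker is reused for both
.capsule_rings <- function(cap, h_tip, grade, h_far) {
  cs <- .cap_sizes(cap, h_tip)
  out <- list()
  for (dir in c(1, -1)) {
    delta <- 0.9 * cs$h_tip
    j <- 0
    repeat {
      h_here <- cs$h_tip + grade * delta
      if (h_here >= h_far || j > 120) break
      D_off <- cap$D + 2 * dir * delta
      if (dir < 0 && D_off < 2.5 * h_here) break    # core covered by spine points
      j <- j + 1
      off <- capsule(cap$center, cap$angle, cap$L + 2 * dir * delta, D_off)
      # walk the offset boundary with spacing graded like the parent capsule
      bp <- .capsule_boundary(off, h_tip = cs$h_tip + 0.7 * grade * delta)
      out[[length(out) + 1]] <- list(pts = bp, h = h_here)
      delta <- delta + 0.85 * h_here
    }
  }
  out
}

# domain boundary points walked with the local sizing; returns list with
# per-edge ordered matrices
.domain_boundary_points <- function(scene, hfun, h_far) {
  side <- scene$side
  walk_edge <- function(a, b) {
    len <- sqrt(sum((b - a)^2))
    t <- 0
    ts <- 0
    repeat {
      p <- a + (t / len) * (b - a)
      step <- 0.9 * min(hfun(matrix(p, ncol = 2)), h_far)
      t <- t + step
      if (t >= len - 0.55 * step) break
      ts <- c(ts, t)
    }
    cbind(a[1] + (ts / len) * (b[1] - a[1]), a[2] + (ts / len) * (b[2] - a[2]))
  }
  list(left   = walk_edge(c(0, 0), c(0, side)),
       top    = walk_edge(c(0, side), c(side, side)),
       right  = walk_edge(c(side, side), c(side, 0)),
       bottom = walk_edge(c(side, 0), c(0, 0)))
}

# ---- triangulation ----------------------------------------------------------

# Delaunay edges via deldir (points scaled to O(1)); returns edge matrix.
# Exactly axis-aligned feature constellations can trip deldir's internal
# adjacency checks; on failure the point set is retried under a tiny global
# rotation (combinatorially equivalent, indices unchanged).
.delaunay_edges <- function(P, side) {
  x <- P[, 1] / side; y <- P[, 2] / side
  for (k in 0:3) {
    if (k > 0) {
      th <- k * 2.3e-4
      xr <- 0.5 + cos(th) * (x - 0.5) - sin(th) * (y - 0.5)
      yr <- 0.5 + sin(th) * (x - 0.5) + cos(th) * (y - 0.5)
    } else {
      xr <- x; yr <- y
    }
    d <- tryCatch(
      deldir::deldir(xr, yr, round = FALSE, suppressMsge = TRUE),
      error = function(e) NULL)
    if (!is.null(d)) return(cbind(d$delsgs$ind1, d$delsgs$ind2))
  }
  stop("Delaunay triangulation failed for this point set")
}

# triangle faces from the Delaunay edge set by 3-clique enumeration.
# In a planar Delaunay triangulation every 3-clique is a face except the
# neighbour-triangle of an interior degree-3 vertex; those are removed.
.edges_to_triangles <- function(edges, P) {
  n <- nrow(P)
  i <- pmin(edges[, 1], edges[, 2])
  j <- pmax(edges[, 1], edges[, 2])
  adj_fwd <- split(j, factor(i, levels = seq_len(n)))  # neighbours with larger index
  tri <- vector("list", length(i))
  for (e in seq_along(i)) {
    a <- adj_fwd[[i[e]]]
    b <- adj_fwd[[j[e]]]
    k <- a[match(a, b, nomatch = 0L) > 0L]  # common larger neighbours
    if (length(k)) tri[[e]] <- cbind(i[e], j[e], k)
  }
  T <- do.call(rbind, tri)
  # remove non-face cliques: triangles strictly containing a degree-3 vertex
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  d3 <- which(deg == 3)
  if (length(d3)) {
    all_adj <- split(c(j, i), factor(c(i, j), levels = seq_len(n)))
    bad <- rep(FALSE, nrow(T))
    for (v in d3) {
      nb <- sort(all_adj[[v]])
      hit <- which(T[, 1] == nb[1] & T[, 2] == nb[2] & T[, 3] == nb[3])
      if (length(hit)) {
        # non-face only if v lies strictly inside that triangle
        A <- P[nb[1], ]; B <- P[nb[2], ]; C <- P[nb[3], ]; Q <- P[v, ]
        s1 <- (B[1] - A[1]) * (Q[2] - A[2]) - (B[2] - A[2]) * (Q[1] - A[1])
        s2 <- (C[1] - B[1]) * (Q[2] - B[2]) - (C[2] - B[2]) * (Q[1] - B[1])
        s3 <- (A[1] - C[1]) * (Q[2] - C[2]) - (A[2] - C[2]) * (Q[1] - C[1])
        if (all(c(s1, s2, s3) > 0) || all(c(s1, s2, s3) < 0)) bad[hit] <- TRUE
      }
    }
    T <- T[!bad, , drop = FALSE]
  }
  # orient counter-clockwise
  ax <- P[T[, 1], 1]; ay <- P[T[, 1], 2]
  bx <- P[T[, 2], 1]; by <- P[T[, 2], 2]
  cx <- P[T[, 3], 1]; cy <- P[T[, 3], 2]
  a2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  sw <- a2 < 0
  if (any(sw)) T[sw, c(2, 3)] <- T[sw, c(3, 2)]
  T[abs(a2) > 0, , drop = FALSE]
}

.tri_min_angles <- function(P, T) {
  a <- sqrt(rowSums((P[T[, 2], , drop = FALSE] - P[T[, 3], , drop = FALSE])^2))
  b <- sqrt(rowSums((P[T[, 1], , drop = FALSE] - P[T[, 3], , drop = FALSE])^2))
  cc <- sqrt(rowSums((P[T[, 1], , drop = FALSE] - P[T[, 2], , drop = FALSE])^2))
  clamp <- function(x) pmin(1, pmax(-1, x))
  A <- acos(clamp((b^2 + cc^2 - a^2) / (2 * b * cc)))
  B <- acos(clamp((a^2 + cc^2 - b^2) / (2 * a * cc)))
  C <- pi - A - B
  pmin(A, pmin(B, C)) * 180 / pi
}

# ---- region tagging ---------------------------------------------------------

.tag_regions <- function(P, T, scene) {
  cx <- (P[T[, 1], 1] + P[T[, 2], 1] + P[T[, 3], 1]) / 3
  cy <- (P[T[, 1], 2] + P[T[, 2], 2] + P[T[, 3], 2]) / 3
  C <- cbind(cx, cy)
  tag <- rep("medium", nrow(T))
  if (scene$has_cell) {
    d <- sqrt((cx - scene$center[1])^2 + (cy - scene$center[2])^2)
    tag[d < scene$r_c] <- "cytoplasm"
    tag[d < scene$r_n] <- "nucleoplasm"
  }
  for (k in seq_along(scene$cnts)) {
    cap <- scene$cnts[[k]]
    sp <- capsule_spine(cap)
    inside <- .dist_point_seg(C, sp[1, ], sp[2, ]) < cap$D / 2
    tag[inside] <- paste0("cnt_", k)
  }
  tag
}

# ---- interface extraction ---------------------------------------------------

.extract_interface <- function(name, node_idx, P, T, tag, center, radius) {
  n <- length(node_idx)
  nxt <- c(node_idx[-1], node_idx[1])
  ekey <- paste(pmin(T[, 1], T[, 2]), pmax(T[, 1], T[, 2]))
  ekey <- c(ekey, paste(pmin(T[, 2], T[, 3]), pmax(T[, 2], T[, 3])),
            paste(pmin(T[, 1], T[, 3]), pmax(T[, 1], T[, 3])))
  want <- paste(pmin(node_idx, nxt), pmax(node_idx, nxt))
  missing <- which(!(want %in% ekey))
  if (length(missing))
    stop(sprintf("mesh is not conforming on the %s contour: %d of %d contour edges missing (first at node %d)",
                 name, length(missing), n, missing[1]))
  len <- sqrt(rowSums((P[nxt, , drop = FALSE] - P[node_idx, , drop = FALSE])^2))
  w <- (len + c(len[n], len[-n])) / 2            # lumped node weights
  theta <- atan2(P[node_idx, 2] - center[2], P[node_idx, 1] - center[1])
  list(name = name, nodes = node_idx, next_node = nxt, edge_len = len,
       w = w, theta = theta, radius = radius, center = center)
}

# ---- main entry -------------------------------------------------------------

#' Build a region-tagged triangular mesh for a scene
#'
#' Generates a graded point cloud (membrane contours at `h_membrane`, CNT
#' caps at `h_tip`, background at `h_far`, geometric growth in between),
#' triangulates it with a Delaunay algorithm, smooths the free points,
#' tags every triangle with its region, and extracts the membrane interface
#' contours.  Membranes are zero-thickness interface contours, not meshed
#' layers; the returned object carries a duplicated-DOF map (`tri_dof`)
#' where triangles on the inner side of each membrane reference duplicate
#' node indices so the potential may jump across the contour.
#'
#' @param scene an `ep_scene`.
#' @param h_far background element size (m).
#' @param h_membrane element size on the membrane contours (m).
#' @param h_tip element size at CNT caps (m); `NA` sizes each capsule at D/12.
#' @param grade growth rate of element size with distance from features.
#' @param smooth Laplacian smoothing rounds applied to free points.
#' @param min_angle quality bound (degrees); a warning is raised if violated.
#' @param interfaces when `FALSE` the membrane contours are kept as ordinary
#'   conforming region boundaries without duplicated DOFs (continuous
#'   potential; used by the analytic bulk-only benchmarks).
#' @return An `ep_mesh` object: `nodes` (n x 2, m), `tri` (faces), `region`
#'   (per-triangle tag), `tri_dof` (faces with duplicated interface DOFs),
#'   `n_dof`, `interfaces` (list with `outer`/`inner` contour descriptors,
#'   each with ordered nodes, duplicate indices, lumped weights and polar
#'   angles), boundary node sets, triangle areas and quality statistics.
#' @export
build_mesh <- function(scene, h_far = 10e-6, h_membrane = 0.35e-6,
                       h_tip = NA_real_, grade = 0.5, smooth = 3,
                       min_angle = 8, interfaces = TRUE) {
  stopifnot(inherits(scene, "ep_scene"))
  if (is.finite(h_tip) && !(h_tip <= h_membrane && h_membrane <= h_far))
    stopifnot(h_tip <= h_membrane, h_membrane <= h_far)
  sz <- list(h_far = h_far, h_membrane = h_membrane, h_tip = h_tip, grade = grade)
  hfun <- .make_sizing(scene, sz)
  side <- scene$side

  # -- feature points (fixed, in a known order) --
  feat <- list(); feat_meta <- list()
  outer_idx <- inner_idx <- integer(0)
  cap_ranges <- list()
  n_acc <- 0L
  push <- function(pts) {
    feat[[length(feat) + 1]] <<- pts
    rng <- n_acc + seq_len(nrow(pts))
    n_acc <<- n_acc + nrow(pts)
    rng
  }
  if (scene$has_cell) {
    outer_idx <- push(.circle_points(scene$center, scene$r_c, h_membrane))
    inner_idx <- push(.circle_points(scene$center, scene$r_n, h_membrane, phase = 0.21))
  }
  for (k in seq_along(scene$cnts))
    cap_ranges[[k]] <- push(.capsule_boundary(scene$cnts[[k]], h_tip))
  bpts <- .domain_boundary_points(scene, hfun, h_far)
  b_idx <- lapply(bpts, push)
  P_feat <- do.call(rbind, feat)
  n_feat <- nrow(P_feat)

  # -- free candidate batches, finest first --
  batches <- list()
  addb <- function(pts, h) if (nrow(pts)) batches[[length(batches) + 1]] <<- list(pts = pts, h = h)
  for (k in seq_along(scene$cnts)) {
    for (r in .capsule_rings(scene$cnts[[k]], h_tip, grade, h_far)) addb(r$pts, r$h)
    sp <- .capsule_spine_points(scene$cnts[[k]], h_tip)
    if (nrow(sp)) addb(sp, .cap_sizes(scene$cnts[[k]], h_tip)$h_tip * 2)
  }
  if (scene$has_cell) {
    for (r in .circle_rings(scene$center, scene$r_c, h_membrane, grade, h_far, side))
      addb(r$pts, r$h)
    for (r in .circle_rings(scene$center, scene$r_n, h_membrane, grade, h_far, side))
      addb(r$pts, r$h)
    addb(matrix(scene$center, ncol = 2), h_membrane + grade * scene$r_n)
  }
  s0 <- 0.95 * h_far
  gx <- seq(s0, side - s0 / 2, by = s0)
  gy <- seq(s0, side - s0 / 2, by = s0)
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  G[, 1] <- G[, 1] + rep(c(0, s0 / 2), length.out = length(gy))[rep(seq_along(gy), each = length(gx))]
  G <- G[G[, 1] < side - s0 / 2, , drop = FALSE]
  G <- G[hfun(G) >= 0.75 * s0, , drop = FALSE]
  addb(G, s0)
  batches <- batches[order(vapply(batches, `[[`, numeric(1), "h"))]

  # -- jitter, guards, priority filter --
  jit_rng <- pf_substream_seed(if (is.na(scene$seed)) 0L else scene$seed, "mesh-jitter")
  kept <- P_feat
  P_free <- pf_with_seed(jit_rng, {
    out <- list()
    for (b in batches) {
      pts <- b$pts
      hl <- hfun(pts)
      amp <- 0.08 * hl
      pts <- pts + cbind(stats::runif(nrow(pts), -1, 1) * amp,
                         stats::runif(nrow(pts), -1, 1) * amp)
      ok <- .candidate_ok(pts, hl, scene, sz)
      pts <- pts[ok, , drop = FALSE]; hl <- hl[ok]
      if (!nrow(pts)) next
      nn <- RANN::nn2(kept, pts, k = 1)
      keep <- nn$nn.dists[, 1] >= 0.55 * hl
      pts <- pts[keep, , drop = FALSE]
      if (!nrow(pts)) next
      # thin within-batch collisions caused by jitter/overlapping rings
      nn2 <- if (nrow(pts) >= 2) RANN::nn2(pts, pts, k = 2) else NULL
      dup <- if (is.null(nn2)) FALSE else nn2$nn.dists[, 2] < 0.5 * hl[keep]
      if (any(dup)) {
        drop <- rep(FALSE, nrow(pts))
        for (ii in which(dup)) if (!drop[ii]) drop[nn2$nn.idx[ii, 2]] <- TRUE
        pts <- pts[!drop, , drop = FALSE]
      }
      kept <- rbind(kept, pts)
      out[[length(out) + 1]] <- pts
    }
    do.call(rbind, out)
  })
  P <- rbind(P_feat, P_free)

  # -- triangulate (+ optional smoothing of free points) --
  for (round in seq_len(smooth + 1)) {
    edges <- .delaunay_edges(P, side)
    if (round > smooth) break
    nb_i <- c(edges[, 1], edges[, 2])
    nb_j <- c(edges[, 2], edges[, 1])
    sx <- rowsum(P[nb_j, 1], nb_i, reorder = TRUE)
    sy <- rowsum(P[nb_j, 2], nb_i, reorder = TRUE)
    cnt <- tabulate(nb_i, nbins = nrow(P))
    idx <- as.integer(rownames(sx))
    newx <- P[, 1]; newy <- P[, 2]
    newx[idx] <- sx[, 1] / cnt[idx]
    newy[idx] <- sy[, 1] / cnt[idx]
    free <- seq_len(nrow(P)) > n_feat
    old <- P
    P[free, 1] <- newx[free]
    P[free, 2] <- newy[free]
    # smoothing must not drag a free point across a feature curve
    Pf <- P[free, , drop = FALSE]
    bad <- !.candidate_ok(Pf, hfun(Pf), scene, sz)
    if (any(bad)) P[which(free)[bad], ] <- old[which(free)[bad], ]
  }
  T <- .edges_to_triangles(edges, P)
  tag <- .tag_regions(P, T, scene)

  # -- interfaces and duplicated DOFs --
  ifc <- list()
  tri_dof <- T
  n_dof <- nrow(P)
  if (scene$has_cell) {
    cxy <- (P[T[, 1], ] + P[T[, 2], ] + P[T[, 3], ]) / 3
    dcen <- sqrt((cxy[, 1] - scene$center[1])^2 + (cxy[, 2] - scene$center[2])^2)
    for (mem in list(list(nm = "outer", idx = outer_idx, r = scene$r_c),
                     list(nm = "inner", idx = inner_idx, r = scene$r_n))) {
      iface <- .extract_interface(mem$nm, mem$idx, P, T, tag, scene$center, mem$r)
      if (!interfaces) next                    # conformity checked, no jump DOFs
      dup <- n_dof + seq_along(mem$idx)
      n_dof <- n_dof + length(mem$idx)
      iface$dup <- dup            # inner-side trace DOFs
      map <- integer(nrow(P)); map[mem$idx] <- dup
      inside_tri <- dcen < mem$r
      for (col in 1:3) {
        hit <- inside_tri & map[T[, col]] > 0L
        tri_dof[hit, col] <- map[T[hit, col]]
      }
      ifc[[mem$nm]] <- iface
    }
  }

  ax <- P[T[, 1], 1]; ay <- P[T[, 1], 2]
  area <- 0.5 * abs((P[T[, 2], 1] - ax) * (P[T[, 3], 2] - ay) -
                    (P[T[, 2], 2] - ay) * (P[T[, 3], 1] - ax))
  minang <- .tri_min_angles(P, T)
  if (min(minang) < min_angle)
    warning(sprintf("mesh quality below bound: min angle %.2f deg < %g deg",
                    min(minang), min_angle))

  structure(list(
    nodes = P, tri = T, region = tag, area = area,
    tri_dof = tri_dof, n_dof = n_dof, n_nodes = nrow(P),
    interfaces = ifc,
    boundary = local({
      # classify by coordinate so the domain corners land on the electrodes
      bidx <- sort(unique(unlist(b_idx)))
      tol <- 1e-9 * side
      list(left  = bidx[P[bidx, 1] < tol],
           right = bidx[P[bidx, 1] > side - tol],
           top   = bidx[P[bidx, 2] > side - tol & P[bidx, 1] >= tol & P[bidx, 1] <= side - tol],
           bottom = bidx[P[bidx, 2] < tol & P[bidx, 1] >= tol & P[bidx, 1] <= side - tol])
    }),
    capsule_nodes = cap_ranges,
    sizes = sz, min_angle = min(minang), scene = scene
  ), class = "ep_mesh")
}

# guards applied to free candidate points: inside the domain, away from the
# domain boundary and from every feature curve (conformity protection)
.candidate_ok <- function(pts, hl, scene, sz) {
  side <- scene$side
  dedge <- pmin(pts[, 1], side - pts[, 1], pts[, 2], side - pts[, 2])
  ok <- pts[, 1] > 0 & pts[, 1] < side & pts[, 2] > 0 & pts[, 2] < side &
    dedge >= 0.45 * hl
  if (scene$has_cell) {
    d <- sqrt((pts[, 1] - scene$center[1])^2 + (pts[, 2] - scene$center[2])^2)
    ok <- ok & abs(d - scene$r_c) >= 0.5 * sz$h_membrane
    ok <- ok & abs(d - scene$r_n) >= 0.5 * sz$h_membrane
  }
  for (cap in scene$cnts) {
    sp <- capsule_spine(cap)
    dsurf <- abs(.dist_point_seg(pts, sp[1, ], sp[2, ]) - cap$D / 2)
    ok <- ok & dsurf >= 0.5 * pmin(hl, .capsule_h(pts, cap, sz$grade, sz$h_tip))
  }
  ok
}

#' @export
print.ep_mesh <- function(x, ...) {
  cat(sprintf("<ep_mesh> %d nodes (%d DOFs), %d triangles, min angle %.1f deg\n",
              x$n_nodes, x$n_dof, nrow(x$tri), x$min_angle))
  cat(sprintf("  regions: %s\n", paste(sprintf("%s (%d)", names(table(x$region)),
                                               as.integer(table(x$region))), collapse = ", ")))
  if (length(x$interfaces))
    cat(sprintf("  interfaces: %s\n",
                paste(vapply(x$interfaces, function(i)
                  sprintf("%s (%d nodes)", i$name, length(i$nodes)), character(1)),
                  collapse = ", ")))
  invisible(x)
}
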