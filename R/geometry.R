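# Scene geometry: the five-layer cell in a square domain with plate
# electrodes, plus capsule-shaped CNTs placed by Monte Carlo rejection.
# A capsule (2D stadium) is the cross-section of a cylindrical CNT: a
# rectangle of length L - D with two semicircular caps of radius D/2.

# deterministic RNG substreams: one global seed feeds a named substream per
# module so adding CNT sampling never perturbs other randomness
pf_substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h + 1) %% 2147483647)
}

# evaluate `expr` under a given seed without disturbing the caller's RNG
pf_with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct a capsule (2D stadium)
#'
#' @param center numeric length-2, centre of the capsule (m).
#' @param angle orientation of the long axis relative to the field (x) axis (rad).
#' @param L tip-to-tip length (m); must exceed `D`.
#' @param D diameter (m).
#' @return A `capsule` object.
#' @export
capsule <- function(center, angle, L, D) {
  stopifnot(length(center) == 2, is.finite(angle), L > D, D > 0)
  structure(list(center = as.numeric(center), angle = as.numeric(angle),
                 L = as.numeric(L), D = as.numeric(D)),
            class = "capsule")
}

# spine segment endpoints (the centres of the two caps)
capsule_spine <- function(cap) {
  s <- (cap$L - cap$D) / 2
  u <- c(cos(cap$angle), sin(cap$angle))
  rbind(cap$center - s * u, cap$center + s * u)
}

# distance from points (matrix nx2) to a segment [a, b]
.dist_point_seg <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- p[, 1] - (a[1] + t * ab[1])
  dy <- p[, 2] - (a[2] + t * ab[2])
  sqrt(dx^2 + dy^2)
}

# minimum distance between two segments [a1,a2], [b1,b2]
.dist_seg_seg <- function(a1, a2, b1, b2) {
  # if they intersect the distance is 0
  orient <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- orient(b1, b2, a1); d2 <- orient(b1, b2, a2)
  d3 <- orient(a1, a2, b1); d4 <- orient(a1, a2, b2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(.dist_point_seg(rbind(a1), b1, b2), .dist_point_seg(rbind(a2), b1, b2),
      .dist_point_seg(rbind(b1), a1, a2), .dist_point_seg(rbind(b2), a1, a2))
}

# signed clearance between two capsules (negative = overlap)
capsule_gap <- function(c1, c2) {
  s1 <- capsule_spine(c1); s2 <- capsule_spine(c2)
  .dist_seg_seg(s1[1, ], s1[2, ], s2[1, ], s2[2, ]) - (c1$D + c2$D) / 2
}

# signed clearance between a capsule and a circle (negative = intersects;
# the capsule is required to lie outside the circle)
capsule_circle_gap <- function(cap, center, radius) {
  s <- capsule_spine(cap)
  d <- .dist_point_seg(rbind(center), s[1, ], s[2, ])
  d - radius - cap$D / 2
}

# TRUE when the whole capsule lies inside [0, side]^2 with margin
capsule_in_domain <- function(cap, side, margin = 0) {
  s <- capsule_spine(cap)
  r <- cap$D / 2 + margin
  all(s[, 1] >= r & s[, 1] <= side - r & s[, 2] >= r & s[, 2] <= side - r)
}

#' Polygonal outline of a capsule
#'
#' Used by the brute-force geometric test oracle and for plotting/export;
#' the mesh generator works from the exact stadium geometry.
#'
#' @param cap a `capsule`.
#' @param n_arc points per semicircular cap.
#' @return A matrix of xy vertices (counter-clockwise, open).
#' @export
capsule_polygon <- function(cap, n_arc = 24) {
  s <- capsule_spine(cap)
  R <- cap$D / 2
  phi <- cap$angle
  th1 <- phi - pi / 2 + seq(0, pi, length.out = n_arc)        # cap at spine end 2
  th2 <- phi + pi / 2 + seq(0, pi, length.out = n_arc)        # cap at spine end 1
  rbind(cbind(s[2, 1] + R * cos(th1), s[2, 2] + R * sin(th1)),
        cbind(s[1, 1] + R * cos(th2), s[1, 2] + R * sin(th2)))
}

#' Sample non-overlapping CNT capsules by Monte Carlo rejection
#'
#' Capsule centres are uniform over the annular placement band around the
#' cell, orientations uniform, and lengths/diameters uniform in their
#' ranges.  Candidates intersecting the cell, another capsule, an electrode
#' or the domain boundary (all with the configured clearance) are rejected
#' and redrawn; the same seed always reproduces the same configuration.
#'
#' @param params an `ep_params` registry (supplies the domain and cell).
#' @param n number of capsules; defaults to the registry value.
#' @param L_range,D_range,band overrides of the registry sampling ranges (m).
#' @param seed integer seed for the geometry substream.
#' @return A list of `capsule` objects of length `n`.
#' @examples
#' cnts <- sample_cnts(default_params(), seed = 42)
#' length(cnts)  # 5
#' @export
sample_cnts <- function(params, n = params$cnt_sampling$n,
                        L_range = params$cnt_sampling$L_range,
                        D_range = params$cnt_sampling$D_range,
                        band = params$cnt_sampling$band,
                        seed = 1) {
  stopifnot(n >= 0, all(L_range > 0), L_range[1] <= L_range[2],
            all(D_range > 0), D_range[1] <= D_range[2], band[1] <= band[2])
  if (n == 0) return(list())
  cs <- params$cnt_sampling
  g <- params$geometry
  cc <- c(g$side / 2, g$side / 2)
  clr <- cs$clearance
  pf_with_seed(pf_substream_seed(seed, "geometry"), {
    caps <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(cs$max_attempts)) {
        rad <- sqrt(stats::runif(1, band[1]^2, band[2]^2))  # area-uniform in the annulus
        ang <- stats::runif(1, 0, 2 * pi)
        cap <- capsule(center = cc + rad * c(cos(ang), sin(ang)),
                       angle = stats::runif(1, 0, pi),
                       L = stats::runif(1, L_range[1], L_range[2]),
                       D = stats::runif(1, D_range[1], D_range[2]))
        if (!capsule_in_domain(cap, g$side, margin = clr)) next
        if (capsule_circle_gap(cap, cc, g$r_c) < clr) next
        if (i > 1 && any(vapply(caps[seq_len(i - 1)],
                                function(o) capsule_gap(cap, o) < clr, logical(1)))) next
        caps[[i]] <- cap
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("CNT placement infeasible: rejection budget exhausted after %d capsules placed",
                     i - 1L))
    }
    caps
  })
}

#' Build the simulation scene
#'
#' Assembles the square domain with its two plate electrodes (left edge
#' driven, right edge grounded), the centred five-layer cell, and the
#' supplied CNT capsules, checking every scene invariant.
#'
#' @param params an `ep_params` registry.
#' @param cnts list of `capsule` objects (possibly empty) from [sample_cnts()].
#' @param seed seed recorded for provenance (the one used to draw `cnts`).
#' @param cell set `FALSE` for a cell-free bench scene (used by the
#'   single-capsule tip-field diagnostics).
#' @return An `ep_scene` object.
#' @export
build_scene <- function(params, cnts = list(), seed = NA_integer_, cell = TRUE) {
  g <- params$geometry
  cc <- c(g$side / 2, g$side / 2)
  clr <- params$cnt_sampling$clearance
  for (i in seq_along(cnts)) {
    cap <- cnts[[i]]
    if (!inherits(cap, "capsule")) stop(sprintf("cnts[[%d]] is not a capsule", i))
    if (!capsule_in_domain(cap, g$side, margin = clr))
      stop(sprintf("capsule %d extends outside the domain or touches an electrode", i))
    if (cell && capsule_circle_gap(cap, cc, g$r_c) < clr)
      stop(sprintf("capsule %d intersects the cell membrane (or its clearance band)", i))
    for (j in seq_len(i - 1L)) if (capsule_gap(cap, cnts[[j]]) < clr)
      stop(sprintf("capsule %d overlaps capsule %d", i, j))
  }
  if (cell && 2 * g$r_c >= g$side) stop("cell does not fit inside the domain")
  structure(list(
    side = g$side,
    center = cc,
    has_cell = cell,
    r_c = if (cell) g$r_c else NA_real_,
    r_n = if (cell) g$r_n else NA_real_,
    d_mem = g$d_mem, d_ne = g$d_ne,
    cnts = cnts,
    seed = seed
  ), class = "ep_scene")
}

#' @export
print.ep_scene <- function(x, ...) {
  cat(sprintf("<ep_scene> %g um square, %s, %d CNT capsule(s), seed %s\n",
              x$side * 1e6,
              if (x$has_cell) sprintf("cell r_c = %g um / r_n = %g um", x$r_c * 1e6, x$r_n * 1e6)
              else "no cell",
              length(x$cnts), format(x$seed)))
  invisible(x)
}

#' Serialize a scene to JSON (coordinates in micrometres)
#'
#' @param scene an `ep_scene`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
scene_to_json <- function(scene, path) {
  um <- 1e6
  obj <- list(
    side_um = scene$side * um,
    has_cell = scene$has_cell,
    center_um = scene$center * um,
    r_c_um = scene$r_c * um, r_n_um = scene$r_n * um,
    d_mem_um = scene$d_mem * um, d_ne_um = scene$d_ne * um,
    seed = scene$seed,
    cnts = lapply(scene$cnts, function(cp) list(
      center_um = cp$center * um, angle_rad = cp$angle,
      L_um = cp$L * um, D_um = cp$D * um))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
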