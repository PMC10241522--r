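dendrite_edges <- function(morph) {
  n <- morph$nodes
  idx <- match(n$parent, n$id)
  child_ok <- n$type != 5 & n$parent != -1
  par_ok <- !is.na(idx) & n$type[idx] != 5
  which(child_ok & par_ok)
}

node_xyz <- function(nodes, ids) {
  as.matrix(nodes[match(ids, nodes$id), c("x", "y", "z")])
}

#' Sholl analysis: dendritic crossings of concentric circles/spheres
#'
#' For each radius, counts how many dendritic inter-node segments cross the
#' circle (2D, after projecting out Z) or sphere (3D) centered on the root.
#' Crossings are found exactly by solving the quadratic
#' `|p1 + t (p2 - p1)| = R` for t in (0, 1]; a segment can contribute up to
#' two crossings.
#'
#' @param morph an [swc_morphology()]
#' @param radii increasing positive radii (um); default 20 to 200 um in
#'   20 um steps
#' @param mode `"2D"` (projection, default, matching max-projection image
#'   analysis) or `"3D"`
#' @return data.frame with `radius` and `crossings`
#' @export
sholl <- function(morph, radii = seq(20, 200, by = 20),
                  mode = c("2D", "3D")) {
  mode <- match.arg(mode)
  stopifnot(all(radii > 0), !is.unsorted(radii))
  n <- morph$nodes
  edges <- dendrite_edges(morph)
  if (!length(edges)) stop("no dendritic segments")
  root <- n[n$parent == -1, ]
  center <- c(root$x, root$y, if (mode == "3D") root$z else NULL)
  dims <- if (mode == "3D") c("x", "y", "z") else c("x", "y")
  p1 <- as.matrix(n[match(n$parent[edges], n$id), dims, drop = FALSE])
  p2 <- as.matrix(n[edges, dims, drop = FALSE])
  p1 <- sweep(p1, 2, center); p2 <- sweep(p2, 2, center)
  d <- p2 - p1
  a <- rowSums(d^2)
  b <- 2 * rowSums(p1 * d)
  c0 <- rowSums(p1^2)
  counts <- vapply(radii, function(R) {
    cc <- c0 - R^2
    disc <- b^2 - 4 * a * cc
    ok <- disc >= 0 & a > 0
    t1 <- (-b[ok] - sqrt(disc[ok])) / (2 * a[ok])
    t2 <- (-b[ok] + sqrt(disc[ok])) / (2 * a[ok])
    sum(t1 > 0 & t1 <= 1) + sum(t2 > 0 & t2 <= 1 & t2 != t1)
  }, numeric(1))
  data.frame(radius = radii, crossings = counts)
}

# decompose the dendritic tree into unbranched segments; order = number of
# branch points on the path from the root to the segment start
build_segments <- function(morph) {
  n <- morph$nodes
  dn <- n[n$type != 5, ]
  kids <- split(dn$id[dn$parent != -1], dn$parent[dn$parent != -1])
  root_id <- dn$id[dn$parent == -1]
  n_children <- function(id) length(kids[[as.character(id)]])
  segs <- list()
  # start a segment at each child of the root or of a branch point
  walk <- function(start_id, order) {
    path <- start_id
    cur <- start_id
    repeat {
      ch <- kids[[as.character(cur)]]
      if (is.null(ch) || length(ch) != 1) break
      cur <- ch
      path <- c(path, cur)
    }
    xyz <- node_xyz(dn, path)
    first_par <- dn$parent[match(start_id, dn$id)]
    pxyz <- node_xyz(dn, first_par)
    first_step <- sqrt(sum((xyz[1, ] - pxyz)^2))
    if (dn$type[match(first_par, dn$id)] == 1) {
      # measure from the soma surface, not its center
      first_step <- max(0, first_step - dn$radius[match(first_par, dn$id)])
    }
    steps <- c(first_step,
               if (length(path) > 1)
                 sqrt(rowSums(diff(xyz)^2)) else numeric())
    segs[[length(segs) + 1]] <<- list(
      nodes = path, start_parent = first_par, order = order,
      step_lengths = steps, length = sum(steps))
    ch <- kids[[as.character(cur)]]
    if (!is.null(ch) && length(ch) > 1)
      for (c2 in ch) walk(c2, order + 1)
  }
  for (c1 in kids[[as.character(root_id)]] %||% integer())
    walk(c1, 0)
  segs
}

spine_attachments <- function(morph) {
  n <- morph$nodes
  vapply(morph$spines, function(sp)
    n$parent[match(sp$nodes[1], n$id)], numeric(1))
}

# path length "owned" by each node of a segment: half of each adjacent
# inter-node step (the step to the segment's parent included for the first)
node_ownership <- function(seg) {
  k <- length(seg$nodes)
  own <- numeric(k)
  st <- seg$step_lengths  # st[i] = step arriving at node i
  for (i in seq_len(k)) {
    own[i] <- st[i] / 2 + if (i < k) st[i + 1] / 2 else st[i] / 2
  }
  own
}

#' Spine density along dendrites
#'
#' Two estimators. `mode = "segment"`: the count of spines on the first
#' 30 um of dendritic segments lying after the second branch point, divided
#' by 30 and averaged over up to four such segments (the classical
#' image-based protocol). `mode = "rolling"`: a rolling window of
#' `window_points` SWC points advanced one point at a time along each
#' unbranched segment; the density at each window is the number of attached
#' spines divided by the path length owned by the window's nodes. Segments
#' branching straight off the soma with fewer than `min_spines` spines, and
#' segments shorter than `min_length` um, are excluded from the per-segment
#' averages.
#'
#' @param morph an [swc_morphology()] with spine annotations
#' @param mode `"segment"` or `"rolling"`
#' @param segment_length analysis stretch for segment mode (um)
#' @param max_segments number of segments averaged in segment mode
#' @param window_points rolling window width (SWC points)
#' @param min_spines,min_length exclusion thresholds for rolling averages
#' @return segment mode: list with `density` (spines/um) and `per_segment`
#'   data.frame. Rolling mode: list with `profile` (per-window densities per
#'   segment) and `per_segment` (data.frame of segment averages after
#'   exclusions) and `density` (grand mean over retained segments)
#' @export
spine_density <- function(morph, mode = c("segment", "rolling"),
                          segment_length = 30, max_segments = 4,
                          window_points = 20, min_spines = 10,
                          min_length = 20) {
  mode <- match.arg(mode)
  if (!length(morph$spines)) stop("no spine annotations present")
  segs <- build_segments(morph)
  att <- spine_attachments(morph)

  if (mode == "segment") {
    cand <- Filter(function(s) s$order >= 2 && s$length >= segment_length,
                   segs)
    if (!length(cand))
      stop("no branch of sufficient depth/length for segment mode")
    cand <- cand[seq_len(min(max_segments, length(cand)))]
    dens <- vapply(cand, function(s) {
      cum <- cumsum(s$step_lengths)
      in_nodes <- s$nodes[cum <= segment_length + 1e-9]
      sum(att %in% in_nodes) / segment_length
    }, numeric(1))
    return(list(density = mean(dens),
                per_segment = data.frame(
                  segment = seq_along(dens),
                  order = vapply(cand, `[[`, numeric(1), "order"),
                  density = dens)))
  }

  profiles <- list(); seg_rows <- list()
  for (si in seq_along(segs)) {
    s <- segs[[si]]
    k <- length(s$nodes)
    own <- node_ownership(s)
    spine_per_node <- vapply(s$nodes, function(id) sum(att == id),
                             numeric(1))
    w <- min(window_points, k)
    n_win <- k - w + 1
    dens <- numeric(n_win)
    for (i in seq_len(n_win)) {
      idx <- i:(i + w - 1)
      dens[i] <- sum(spine_per_node[idx]) / sum(own[idx])
    }
    profiles[[si]] <- dens
    n_sp <- sum(spine_per_node)
    soma_adjacent <- s$order == 0
    excluded <- (soma_adjacent && n_sp < min_spines) ||
      s$length < min_length
    seg_rows[[si]] <- data.frame(segment = si, order = s$order,
                                 length = s$length, n_spines = n_sp,
                                 mean_density = mean(dens),
                                 excluded = excluded)
  }
  per_seg <- do.call(rbind, seg_rows)
  kept <- per_seg[!per_seg$excluded, , drop = FALSE]
  list(profile = profiles, per_segment = per_seg,
       density = if (nrow(kept)) mean(kept$mean_density) else NA_real_)
}

#' Per-spine surface areas and volumes
#'
#' Single-point spines are modelled as a sphere attached by a cylindrical
#' neck of radius `neck_radius`: area `4 pi r^2 + 2 pi neck_radius * L`
#' where the neck length L is the attachment-to-head distance minus the head
#' radius (floored at zero). Multi-point spines use the lateral areas of the
#' frusta between consecutive points plus a hemispherical dome
#' `2 pi r_last^2` on the final point. Volumes are the sums of the node
#' sphere volumes `(4/3) pi r^3`.
#'
#' @param morph an [swc_morphology()] with spine annotations
#' @param neck_radius assumed neck radius for single-point spines (um)
#' @return data.frame with one row per spine: `spine`, `multi`, `area`,
#'   `volume` (um^2, um^3)
#' @export
spine_geometry <- function(morph, neck_radius = 0.066) {
  if (!length(morph$spines)) stop("no spine annotations present")
  n <- morph$nodes
  rows <- lapply(seq_along(morph$spines), function(si) {
    sp <- morph$spines[[si]]
    ids <- sp$nodes
    xyz <- node_xyz(n, ids)
    rads <- n$radius[match(ids, n$id)]
    if (!isTRUE(sp$multi)) {
      att <- n$parent[match(ids[1], n$id)]
      axyz <- node_xyz(n, att)
      d <- sqrt(sum((xyz[1, ] - axyz)^2))
      neck_len <- max(0, d - rads[1])
      area <- 4 * pi * rads[1]^2 + 2 * pi * neck_radius * neck_len
      vol <- 4 / 3 * pi * rads[1]^3
    } else {
      if (nrow(xyz) < 2) stop("multi-point spine with a single node")
      seg <- sqrt(rowSums(diff(xyz)^2))
      if (all(seg == 0)) stop("zero-length multi-point spine chain")
      slant <- sqrt(seg^2 + diff(rads)^2)
      area <- sum(pi * (rads[-length(rads)] + rads[-1]) * slant) +
        2 * pi * rads[length(rads)]^2
      vol <- sum(4 / 3 * pi * rads^3)
    }
    data.frame(spine = si, multi = isTRUE(sp$multi), area = area,
               volume = vol)
  })
  do.call(rbind, rows)
}

#' Dendritic length, frustum surface area and voxelized volume
#'
#' Length is the sum of inter-node Euclidean distances; surface area the sum
#' of lateral frustum areas `pi (r1 + r2) * slant`; volume is computed by
#' voxelizing the union of all frusta on a grid of `voxel_size` and counting
#' each occupied voxel once, so overlaps at branch points are not double
#' counted.
#'
#' @param morph an [swc_morphology()] (Z assumed isotropic)
#' @param voxel_size voxel edge (um)
#' @param max_voxels guard on the per-edge candidate grid
#' @return list with `length` (um), `area` (um^2), `volume` (um^3)
#' @export
dendrite_geometry <- function(morph, voxel_size = 0.1, max_voxels = 5e7) {
  n <- morph$nodes
  edges <- dendrite_edges(morph)
  if (!length(edges)) stop("no dendritic segments")
  p1 <- node_xyz(n, n$parent[edges])
  p2 <- node_xyz(n, n$id[edges])
  r1 <- n$radius[match(n$parent[edges], n$id)]
  r2 <- n$radius[edges]
  # edges leaving the soma sphere are truncated at its surface and treated
  # as cylinders of the child radius (the interior part belongs to the soma)
  soma_par <- n$type[match(n$parent[edges], n$id)] == 1
  if (any(soma_par)) {
    for (e in which(soma_par)) {
      d <- p2[e, ] - p1[e, ]
      len <- sqrt(sum(d^2))
      rs <- r1[e]
      if (len <= rs) { p1[e, ] <- p2[e, ]; r1[e] <- r2[e]; next }
      p1[e, ] <- p1[e, ] + d / len * rs
      r1[e] <- r2[e]
    }
  }
  seg_len <- sqrt(rowSums((p2 - p1)^2))
  slant <- sqrt(seg_len^2 + (r2 - r1)^2)
  total_len <- sum(seg_len)
  total_area <- sum(pi * (r1 + r2) * slant)

  origin <- apply(rbind(p1, p2), 2, min) - max(c(r1, r2)) - voxel_size
  top <- apply(rbind(p1, p2), 2, max) + max(c(r1, r2)) + voxel_size
  gdim <- ceiling((top - origin) / voxel_size) + 2  # global grid extents
  if (prod(gdim) > 2^52) stop("voxel grid too large; increase voxel_size")
  keys <- vector("list", length(edges))
  for (e in seq_along(edges)) {
    if (seg_len[e] == 0 && r1[e] == r2[e]) next
    lo <- pmin(p1[e, ], p2[e, ]) - max(r1[e], r2[e])
    hi <- pmax(p1[e, ], p2[e, ]) + max(r1[e], r2[e])
    i0 <- floor((lo - origin) / voxel_size)
    i1 <- ceiling((hi - origin) / voxel_size)
    nx <- i1 - i0 + 1
    if (prod(nx) > max_voxels)
      stop("voxel grid too large (", prod(nx),
           " candidates); increase voxel_size")
    gx <- origin[1] + (i0[1]:i1[1] + 0.5) * voxel_size
    gy <- origin[2] + (i0[2]:i1[2] + 0.5) * voxel_size
    gz <- origin[3] + (i0[3]:i1[3] + 0.5) * voxel_size
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    d <- p2[e, ] - p1[e, ]
    L2 <- sum(d^2)
    if (L2 == 0) next
    rel <- sweep(pts, 2, p1[e, ])
    t <- (rel %*% d)[, 1] / L2
    closest <- matrix(p1[e, ], nrow(pts), 3, byrow = TRUE) + outer(t, d)
    dist2 <- rowSums((pts - closest)^2)
    rad <- r1[e] + (r2[e] - r1[e]) * t
    # frustum body only (no spherical end caps): axial range [0, 1] and
    # radial distance within the interpolated radius
    inside <- t >= 0 & t <= 1 & dist2 <= rad^2
    if (!any(inside)) next
    ii <- floor((pts[inside, , drop = FALSE] - origin) / voxel_size)
    keys[[e]] <- ii[, 1] + gdim[1] * (ii[, 2] + gdim[2] * ii[, 3])
  }
  occupied <- unique(unlist(keys))
  list(length = total_len, area = total_area,
       volume = length(occupied) * voxel_size^3)
}

align_polygons <- function(a, b) {
  # best cyclic shift (and orientation flip) of b minimizing total distance
  n <- nrow(a)
  best <- NULL; best_d <- Inf
  for (flip in c(FALSE, TRUE)) {
    bb <- if (flip) b[c(1, n:2), , drop = FALSE] else b
    for (s in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      d <- sum((a - bb[idx, ])^2)
      if (d < best_d) { best_d <- d; best <- bb[idx, , drop = FALSE] }
    }
  }
  best
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

ensure_ccw <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (s < 0) poly[c(1, nrow(poly):2), , drop = FALSE] else poly
}

#' Soma surface area and volume from a contour stack
#'
#' Adjacent polygonal contours (same vertex count, correspondence fixed by
#' minimizing total inter-vertex distance over cyclic shifts and flips, then
#' smoothed by a three-point moving average along Z) are joined by triangle
#' bands; the areas of the first and last contours close the caps. The
#' cross-sectional areas of attached dendrites (`pi r^2` each) are
#' subtracted from the surface. Volume comes from the signed-tetrahedron sum
#' over the closed triangulated surface (bands plus centroid fans on the
#' caps).
#'
#' @param stack a `contour_stack` from [generate_soma_stack()] or equivalent
#' @param first_dendrite_radius radii (um) of the first SWC point of each
#'   attached dendrite; may be empty
#' @param smooth apply the three-point moving average along Z
#' @return list with `area` (um^2), `volume` (um^3), `area_2d` (um^2,
#'   largest projected contour area)
#' @export
soma_geometry <- function(stack, first_dendrite_radius = numeric(),
                          smooth = TRUE) {
  sl <- stack$slices
  if (length(sl) < 2) stop("need at least two non-empty slices")
  nv <- nrow(sl[[1]]$polygon)
  polys <- lapply(sl, function(s) {
    if (nrow(s$polygon) != nv) stop("contours must share vertex count")
    ensure_ccw(s$polygon)
  })
  zs <- vapply(sl, `[[`, numeric(1), "z")
  if (is.unsorted(zs)) stop("slices must be in increasing z order")
  # fix correspondence sequentially
  for (k in 2:length(polys)) polys[[k]] <- align_polygons(polys[[k - 1]],
                                                          polys[[k]])
  if (smooth && length(polys) >= 3) {
    sm <- polys
    for (k in 2:(length(polys) - 1)) {
      sm[[k]] <- (polys[[k - 1]] + polys[[k]] + polys[[k + 1]]) / 3
    }
    polys <- sm
  }
  v3 <- function(k, i) c(polys[[k]][i, ], zs[k])

  lateral <- 0
  tets <- 0
  tri_area <- function(p, q, r) {
    0.5 * sqrt(sum(crossprod3(q - p, r - p)^2))
  }
  signed_vol <- function(p, q, r) sum(p * crossprod3(q, r)) / 6
  for (k in 1:(length(polys) - 1)) {
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      a1 <- v3(k, i); a2 <- v3(k, j); b1 <- v3(k + 1, i); b2 <- v3(k + 1, j)
      lateral <- lateral + tri_area(a1, a2, b1) + tri_area(a2, b2, b1)
      tets <- tets + signed_vol(a1, a2, b1) + signed_vol(a2, b2, b1)
    }
  }
  cap_low <- polygon_area(polys[[1]])
  cap_high <- polygon_area(polys[[length(polys)]])
  # cap fans (low cap oriented downward, high cap upward)
  c_lo <- c(colMeans(polys[[1]]), zs[1])
  c_hi <- c(colMeans(polys[[length(polys)]]), zs[length(zs)])
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    tets <- tets + signed_vol(v3(1, j), v3(1, i), c_lo)
    tets <- tets + signed_vol(v3(length(polys), i), v3(length(polys), j),
                              c_hi)
  }
  area <- lateral + cap_low + cap_high -
    sum(pi * first_dendrite_radius^2)
  area_2d <- max(vapply(polys, polygon_area, numeric(1)))
  list(area = area, volume = abs(tets), area_2d = area_2d)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Combine compartment geometry into a morphometry report
#'
#' Totals per compartment, the surface-to-volume ratio, and (optionally) a
#' tissue-shrinkage correction applied to the areas: `"areal"` divides areas
#' by `1 - shrinkage` (default, 20% areal shrinkage), `"linear"` divides by
#' `(1 - shrinkage)^2`; `"none"` leaves them untouched. Missing compartments
#' may be passed as `NULL` and yield `NA` fields.
#'
#' @param soma list with `area`, `volume` (and optionally `area_2d`)
#' @param dendrite list with `length`, `area`, `volume`
#' @param spines data.frame from [spine_geometry()] or a list with
#'   `area`/`volume` totals
#' @param shrinkage shrinkage fraction (0.2 = 20%)
#' @param shrinkage_mode `"areal"`, `"linear"` or `"none"`
#' @return one-row data.frame (a morphometry report)
#' @export
summarize_morphometry <- function(soma = NULL, dendrite = NULL,
                                  spines = NULL, shrinkage = 0.2,
                                  shrinkage_mode = c("areal", "linear",
                                                     "none")) {
  shrinkage_mode <- match.arg(shrinkage_mode)
  corr <- switch(shrinkage_mode,
                 none = 1,
                 areal = 1 - shrinkage,
                 linear = (1 - shrinkage)^2)
  g <- function(x, f) if (is.null(x)) NA_real_ else
    (if (is.data.frame(x)) sum(x[[f]]) else x[[f]] %||% NA_real_)
  soma_area <- g(soma, "area"); soma_vol <- g(soma, "volume")
  dend_area <- g(dendrite, "area"); dend_vol <- g(dendrite, "volume")
  dend_len <- g(dendrite, "length")
  sp_area <- g(spines, "area"); sp_vol <- g(spines, "volume")
  total_area <- sum(c(soma_area, dend_area, sp_area), na.rm = TRUE)
  total_vol <- sum(c(soma_vol, dend_vol, sp_vol), na.rm = TRUE)
  data.frame(
    soma_area = soma_area, soma_volume = soma_vol,
    dendrite_length = dend_len, dendrite_area = dend_area,
    dendrite_volume = dend_vol,
    spine_area_total = sp_area, spine_volume_total = sp_vol,
    spine_count = if (is.data.frame(spines)) nrow(spines) else NA_integer_,
    total_area = total_area,
    total_area_adjusted = total_area / corr,
    surface_to_volume = total_area / total_vol,
    soma_area_2d = if (!is.null(soma)) soma$area_2d %||% NA_real_
                   else NA_real_)
}
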