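#' SWC morphology container
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (SWC column order; um). Type codes: 1 soma,
#'   3 dendrite, 5 spine.
#' @param spines list of spine annotations, each a list with `nodes`
#'   (id chain, attachment-first) and `multi` (logical)
#' @param z_scale_applied has the Z axis been rescaled to isotropic?
#' @return an `swc_morphology` object
#' @export
swc_morphology <- function(nodes, spines = list(), z_scale_applied = FALSE) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "type", "x", "y", "z", "radius", "parent") %in%
                  names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  roots <- sum(nodes$parent == -1)
  if (roots != 1) stop("expected exactly one root, found ", roots)
  known <- c(-1, nodes$id)
  if (!all(nodes$parent %in% known))
    stop("orphan parent id: ",
         paste(setdiff(nodes$parent, known), collapse = ", "))
  if (any(nodes$radius <= 0)) {
    bad <- nodes$id[nodes$radius <= 0]
    warning("non-positive radius at node(s) ", paste(bad, collapse = ", "),
            "; quarantined in attr 'quarantine'")
  }
  # cycle check: walking up parents must terminate
  idx <- match(nodes$parent, nodes$id)
  for (start in seq_len(nrow(nodes))) {
    seen <- 0L; i <- start
    while (!is.na(i)) {
      seen <- seen + 1L
      if (seen > nrow(nodes)) stop("cycle detected involving node ",
                                   nodes$id[start])
      i <- idx[i]
    }
  }
  for (sp in spines) {
    if (!all(sp$nodes %in% nodes$id))
      stop("spine annotation references unknown node ids")
  }
  out <- structure(list(nodes = nodes, spines = spines,
                        z_scale_applied = z_scale_applied),
                   class = "swc_morphology")
  attr(out, "quarantine") <- nodes$id[nodes$radius <= 0]
  out
}

#' @export
print.swc_morphology <- function(x, ...) {
  cat(sprintf("<swc_morphology> %d nodes, %d spine annotations\n",
              nrow(x$nodes), length(x$spines)))
  invisible(x)
}

#' Read / write morphologies in standard 7-column SWC
#'
#' Comment lines start with `#`. Spine annotations travel in a JSON sidecar
#' (`<path>.spines.json`) listing node-id chains. `z_scale` multiplies the
#' Z coordinate on read (reconstructions are often compressed along Z by
#' tissue processing and need rescaling to isotropic units).
#'
#' @param path SWC file path
#' @param z_scale factor applied to Z on read (1 = none)
#' @return an [swc_morphology()] (`read_swc`); `path` invisibly (`write_swc`)
#' @export
read_swc <- function(path, z_scale = 1) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- utils::read.table(text = lines, col.names =
    c("id", "type", "x", "y", "z", "radius", "parent"))
  if (z_scale != 1) fields$z <- fields$z * z_scale
  spines <- list()
  side <- paste0(path, ".spines.json")
  if (file.exists(side)) {
    raw <- jsonlite::read_json(side, simplifyVector = FALSE)
    spines <- lapply(raw, function(s)
      list(nodes = as.integer(unlist(s$nodes)), multi = isTRUE(s$multi)))
  }
  swc_morphology(fields, spines, z_scale_applied = z_scale != 1)
}

#' @rdname read_swc
#' @param morph an [swc_morphology()]
#' @export
write_swc <- function(morph, path) {
  n <- morph$nodes
  con <- file(path, "w")
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                     n$id, n$type, n$x, n$y, n$z, n$radius, n$parent), con)
  close(con)
  if (length(morph$spines)) {
    jsonlite::write_json(
      lapply(morph$spines, function(s)
        list(nodes = s$nodes, multi = s$multi)),
      paste0(path, ".spines.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Ground-truth morphology recipe for the synthetic generator
#'
#' Describes a simple planar tree: `n_primary` trunks leave the soma, each
#' trunk runs `trunk_length` then bifurcates `n_bifurcations` times into
#' daughters of `branch_length`. Spines are planted at `spine_density`
#' per um on all terminal (deepest) branches.
#'
#' @param n_primary number of primary dendrites
#' @param trunk_length,branch_length segment lengths (um)
#' @param radius,taper start radius (um) and per-segment radius ratio
#' @param n_bifurcations bifurcation rounds after the trunk
#' @param spine_density planted spines per um of terminal branch
#' @param spine_radius mean spine head radius (um)
#' @param spine_radius_sd spread of head radii (um, truncated at 20% of mean)
#' @param multi_fraction fraction of spines annotated as multi-point chains
#' @param neck_length planted neck length for single-point spines (um)
#' @param soma_radius soma radius (um; 0 = no soma sphere, bare cable)
#' @param pixel_size,slice_thickness imaging geometry (um)
#' @param seed integer seed
#' @return a `morph_spec` list
#' @export
morph_spec <- function(n_primary = 4, trunk_length = 40, branch_length = 50,
                       radius = 1.2, taper = 0.8, n_bifurcations = 2,
                       spine_density = 0.5, spine_radius = 0.35,
                       spine_radius_sd = 0.05, multi_fraction = 0.25,
                       neck_length = 1.0, soma_radius = 8,
                       pixel_size = 0.132, slice_thickness = 0.5,
                       seed = 1L) {
  stopifnot(trunk_length > 0, branch_length > 0, radius > 0, taper > 0,
            spine_density >= 0, spine_radius > 0, soma_radius >= 0,
            pixel_size > 0, slice_thickness > 0)
  structure(as.list(environment()), class = "morph_spec")
}

rotate2d <- function(xy, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy %*% t(R)
}

#' Generate a synthetic SWC morphology with planted spines
#'
#' Builds the tree described by a [morph_spec()] and returns both the
#' morphology and an analytic ground-truth record (total dendritic length,
#' frustum lateral area, frustum volume, spine count and spine geometry
#' totals) against which the morphometry estimators can be validated.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [morph_spec()]
#' @return list with `morphology` ([swc_morphology()]) and `ground_truth`
#'   (list of analytic totals)
#' @export
generate_swc <- function(spec) {
  stopifnot(inherits(spec, "morph_spec"))
  set.seed(spec$seed)
  nodes <- list()
  nid <- 0L
  add_node <- function(type, x, y, z, r, parent) {
    nid <<- nid + 1L
    nodes[[nid]] <<- data.frame(id = nid, type = type, x = x, y = y, z = z,
                                radius = r, parent = parent)
    nid
  }
  root_r <- if (spec$soma_radius > 0) spec$soma_radius else spec$radius
  root <- add_node(if (spec$soma_radius > 0) 1L else 3L, 0, 0, 0, root_r, -1L)

  gt_len <- 0; gt_area <- 0; gt_vol <- 0
  terminals <- list()  # list of (node id vector along branch)
  n_sub <- 5L  # nodes per segment

  grow_segment <- function(parent_id, origin, direction, length, r0, r1,
                           surface_node = FALSE) {
    ids <- integer(n_sub)
    prev <- parent_id
    if (surface_node) {
      # explicit node at the soma surface so downstream geometry sees the
      # full planted trunk with its exact radii
      prev <- add_node(3L, origin[1], origin[2], 0, r0, prev)
    }
    for (k in seq_len(n_sub)) {
      f <- k / n_sub
      pos <- origin + direction * (length * f)
      rk <- r0 + (r1 - r0) * f
      ids[k] <- add_node(3L, pos[1], pos[2], 0, rk, prev)
      prev <- ids[k]
    }
    seg_l <- length / n_sub
    for (k in seq_len(n_sub)) {
      ra <- r0 + (r1 - r0) * (k - 1) / n_sub
      rb <- r0 + (r1 - r0) * k / n_sub
      slant <- sqrt(seg_l^2 + (rb - ra)^2)
      gt_area <<- gt_area + pi * (ra + rb) * slant
      gt_vol <<- gt_vol + pi / 3 * seg_l * (ra^2 + ra * rb + rb^2)
    }
    gt_len <<- gt_len + length
    ids
  }

  for (b in seq_len(spec$n_primary)) {
    theta <- 2 * pi * (b - 1) / spec$n_primary
    dir0 <- c(cos(theta), sin(theta))
    start <- dir0 * spec$soma_radius
    r0 <- spec$radius; r1 <- r0 * spec$taper
    trunk <- grow_segment(root, start, dir0, spec$trunk_length, r0, r1,
                          surface_node = spec$soma_radius > 0)
    tips <- list(list(id = trunk[n_sub],
                      pos = start + dir0 * spec$trunk_length,
                      dir = dir0, r = r1, ids = trunk))
    for (lev in seq_len(spec$n_bifurcations)) {
      new_tips <- list()
      for (tp in tips) {
        for (sgn in c(-1, 1)) {
          nd <- as.numeric(rotate2d(matrix(tp$dir, 1), sgn * pi / 7))
          rr <- tp$r * spec$taper
          seg <- grow_segment(tp$id, tp$pos, nd, spec$branch_length,
                              tp$r, rr)
          new_tips[[length(new_tips) + 1]] <-
            list(id = seg[n_sub], pos = tp$pos + nd * spec$branch_length,
                 dir = nd, r = rr, ids = seg)
          # the primary dendrite stays aspinous; every branch past the
          # first branch point carries spines at the planted density
          terminals[[length(terminals) + 1]] <- new_tips[[length(new_tips)]]
        }
      }
      tips <- new_tips
    }
  }

  # plant spines on terminal branches
  spines <- list()
  spine_area <- 0; spine_vol <- 0
  node_df <- do.call(rbind, nodes)
  for (tp in terminals) {
    n_sp <- round(spec$spine_density * spec$branch_length)
    if (n_sp == 0) next
    along <- (seq_len(n_sp) - 0.5) / n_sp * spec$branch_length
    for (si in seq_len(n_sp)) {
      # attach to nearest branch node
      att_idx <- tp$ids[pmin(n_sub, ceiling(along[si] / spec$branch_length *
                                              n_sub))]
      att <- node_df[att_idx, ]
      perp <- c(-tp$dir[2], tp$dir[1]) *
        (if (stats::runif(1) < 0.5) 1 else -1)
      r_sp <- spec$spine_radius +
        stats::rnorm(1, 0, spec$spine_radius_sd)
      r_sp <- max(spec$spine_radius * 0.2, min(r_sp, spec$spine_radius * 5))
      multi <- stats::runif(1) < spec$multi_fraction
      if (!multi) {
        d <- spec$neck_length + r_sp
        sp_id <- add_node(5L, att$x + perp[1] * d, att$y + perp[2] * d, 0,
                          r_sp, att$id)
        spines[[length(spines) + 1]] <- list(nodes = sp_id, multi = FALSE)
        spine_area <- spine_area + 4 * pi * r_sp^2 +
          2 * pi * 0.066 * spec$neck_length
        spine_vol <- spine_vol + 4 / 3 * pi * r_sp^3
      } else {
        d1 <- spec$neck_length / 2; d2 <- spec$neck_length
        r1 <- r_sp * 0.6; r2 <- r_sp
        id1 <- add_node(5L, att$x + perp[1] * d1, att$y + perp[2] * d1, 0,
                        r1, att$id)
        id2 <- add_node(5L, att$x + perp[1] * d2, att$y + perp[2] * d2, 0,
                        r2, id1)
        spines[[length(spines) + 1]] <- list(nodes = c(id1, id2),
                                             multi = TRUE)
        slant <- sqrt((d2 - d1)^2 + (r2 - r1)^2)
        spine_area <- spine_area + pi * (r1 + r2) * slant + 2 * pi * r2^2
        spine_vol <- spine_vol + 4 / 3 * pi * (r1^3 + r2^3)
      }
    }
  }

  morph <- swc_morphology(do.call(rbind, nodes), spines)
  gt <- list(dendrite_length = gt_len, dendrite_area = gt_area,
             dendrite_volume = gt_vol, spine_count = length(spines),
             spine_area_total = spine_area, spine_volume_total = spine_vol,
             soma_radius = spec$soma_radius)
  list(morphology = morph, ground_truth = gt)
}

#' Generate a bare unbranched cable (validation helper)
#'
#' @param length cable length (um)
#' @param radius constant radius (um)
#' @param n_nodes number of nodes (>= 2, collinear along +x)
#' @return an [swc_morphology()] with a dendrite-type root
#' @export
generate_cable <- function(length = 100, radius = 1, n_nodes = 21) {
  stopifnot(length > 0, radius > 0, n_nodes >= 2)
  xs <- seq(0, length, length.out = n_nodes)
  nodes <- data.frame(id = seq_len(n_nodes), type = 3L, x = xs, y = 0, z = 0,
                      radius = radius,
                      parent = c(-1L, seq_len(n_nodes - 1)))
  swc_morphology(nodes)
}

#' Generate a cable with uniformly planted single-point spines
#'
#' Nodes every `node_spacing` um; `n_spines` spines attached to equally
#' spaced nodes (midpoints of equal subdivisions), all with the same head
#' radius and planted neck length. Deterministic.
#'
#' @inheritParams generate_cable
#' @param n_spines number of spines
#' @param spine_radius head radius (um)
#' @param neck_length planted neck length (um)
#' @param node_spacing distance between consecutive cable nodes (um)
#' @return list with `morphology` and `ground_truth` (as [generate_swc()])
#' @export
generate_spiny_cable <- function(length = 100, radius = 1, n_spines = 50,
                                 spine_radius = 0.5, neck_length = 1,
                                 node_spacing = 1) {
  n_nodes <- round(length / node_spacing) + 1
  morph <- generate_cable(length, radius, n_nodes)
  nodes <- morph$nodes
  spines <- list()
  nid <- nrow(nodes)
  positions <- (seq_len(n_spines) - 0.5) / n_spines * length
  for (pos in positions) {
    att <- which.min(abs(nodes$x[seq_len(n_nodes)] - pos))
    nid <- nid + 1
    nodes <- rbind(nodes, data.frame(
      id = nid, type = 5L, x = nodes$x[att],
      y = radius + neck_length + spine_radius, z = 0,
      radius = spine_radius, parent = att))
    spines[[length(spines) + 1]] <- list(nodes = nid, multi = FALSE)
  }
  gt <- list(dendrite_length = length,
             dendrite_area = 2 * pi * radius * length,
             dendrite_volume = pi * radius^2 * length,
             spine_count = n_spines,
             spine_density = n_spines / length,
             spine_area_total = n_spines *
               (4 * pi * spine_radius^2 + 2 * pi * 0.066 *
                  (radius + neck_length)),
             spine_volume_total = n_spines * 4 / 3 * pi * spine_radius^3)
  list(morphology = swc_morphology(nodes, spines), ground_truth = gt)
}

#' Soma contour stack of an analytic solid
#'
#' Slices a sphere or axis-aligned ellipsoid into polygonal contours: the
#' slice at height z of a sphere of radius r is a circle of radius
#' `sqrt(r^2 - z^2)`. Contours are sampled densely then resampled to
#' `n_vertices` equally spaced points. Slices beyond the solid are empty
#' (dropped, with their z recorded in `empty_z`).
#'
#' @param radii one radius (sphere) or three semi-axes (ellipsoid), um
#' @param slice_thickness spacing between slices (um)
#' @param n_vertices polygon vertex count after resampling
#' @param pixel_size um per pixel (metadata)
#' @param center xyz center (um)
#' @return a `contour_stack`: list of `slices` (each `z`, `polygon` matrix),
#'   plus `slice_thickness`, `pixel_size`, `empty_z`
#' @export
generate_soma_stack <- function(radii = 10, slice_thickness = 0.25,
                                n_vertices = 20, pixel_size = 0.132,
                                center = c(0, 0, 0)) {
  stopifnot(all(radii > 0), slice_thickness > 0, n_vertices >= 3)
  if (length(radii) == 1) radii <- rep(radii, 3)
  zs <- seq(-radii[3], radii[3], by = slice_thickness) + center[3]
  slices <- list(); empty_z <- numeric()
  for (z in zs) {
    u <- (z - center[3]) / radii[3]
    if (abs(u) >= 1) { empty_z <- c(empty_z, z); next }
    scale <- sqrt(1 - u^2)
    a <- radii[1] * scale; b <- radii[2] * scale
    th <- seq(0, 2 * pi, length.out = 181)[-181]
    poly <- cbind(center[1] + a * cos(th), center[2] + b * sin(th))
    slices[[length(slices) + 1]] <-
      list(z = z, polygon = resample_polygon(poly, n_vertices))
  }
  structure(list(slices = slices, slice_thickness = slice_thickness,
                 pixel_size = pixel_size, empty_z = empty_z),
            class = "contour_stack")
}

#' Resample a closed polygon to n equally spaced vertices
#'
#' @param poly two-column matrix of vertices (closed implicitly)
#' @param n target vertex count
#' @return `n` x 2 matrix
#' @export
resample_polygon <- function(poly, n = 20) {
  p <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1)[-(n + 1)]
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- findInterval(target[i], s, rightmost.closed = TRUE)
    f <- (target[i] - s[j]) / max(seg[j], .Machine$double.eps)
    out[i, ] <- p[j, ] + f * (p[j + 1, ] - p[j, ])
  }
  out
}
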