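# Independent brute-force oracles used to validate the fast implementations.

# exhaustive spike scan: every local maximum above min_peak that has a
# centered-difference dV/dt crossing of the threshold somewhere between the
# previous sub-threshold-voltage sample and the peak
oracle_count_spikes <- function(trace, dvdt_threshold = 10, min_peak = 0) {
  v <- trace$samples
  n <- length(v)
  d <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * trace$dt), NA)
  peaks <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1
  peaks <- peaks[v[peaks] >= min_peak]
  count <- 0L
  last_counted_cross <- -1L
  for (p in peaks) {
    j <- p
    cross <- NA_integer_
    while (j > 1) {
      if (!is.na(d[j]) && d[j] >= dvdt_threshold &&
          (j == 2 || is.na(d[j - 1]) || d[j - 1] < dvdt_threshold)) {
        cross <- j
        break
      }
      j <- j - 1
    }
    if (is.na(cross)) next
    if (cross == last_counted_cross) next  # same upstroke, one event
    count <- count + 1L
    last_counted_cross <- cross
  }
  count
}

# dense-resampling Sholl counter: walk every segment in tiny steps and count
# sign changes of (distance - R)
oracle_sholl <- function(morph, radii, step = 0.1, mode = "2D") {
  n <- morph$nodes
  keep <- n$type != 5
  dn <- n[keep, ]
  dims <- if (mode == "3D") c("x", "y", "z") else c("x", "y")
  root <- dn[dn$parent == -1, ]
  center <- as.numeric(root[1, dims])
  counts <- integer(length(radii))
  for (i in which(dn$parent != -1)) {
    pi_ <- match(dn$parent[i], dn$id)
    if (is.na(pi_) || n$type[match(dn$parent[i], n$id)] == 5) next
    p1 <- as.numeric(dn[pi_, dims]); p2 <- as.numeric(dn[i, dims])
    L <- sqrt(sum((p2 - p1)^2))
    if (L == 0) next
    ts <- seq(0, 1, by = min(1, step / L))
    if (ts[length(ts)] < 1) ts <- c(ts, 1)
    pts <- outer(1 - ts, p1) + outer(ts, p2)
    dists <- sqrt(rowSums(sweep(pts, 2, center)^2))
    for (k in seq_along(radii)) {
      s <- sign(dists - radii[k])
      s[s == 0] <- 1e-12
      counts[k] <- counts[k] + sum(diff(sign(s)) != 0)
    }
  }
  data.frame(radius = radii, crossings = counts)
}

# recursive flood-fill connected-component count on a binary matrix
# (4-connectivity would differ from EBImage's default; use 8-connectivity
# to match bwlabel)
oracle_label_count <- function(bin, min_area = 1, max_area = Inf) {
  nr <- nrow(bin); nc <- ncol(bin)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!bin[i, j] || seen[i, j]) next
    # iterative flood fill
    stack <- list(c(i, j)); seen[i, j] <- TRUE; area <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii < 1 || jj < 1 || ii > nr || jj > nc) next
        if (bin[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    if (area >= min_area && area <= max_area) count <- count + 1L
  }
  count
}

# naive per-spine geometry recomputation (independent loop, scalar math)
oracle_spine_totals <- function(morph, neck_radius = 0.066) {
  n <- morph$nodes
  tot_a <- 0; tot_v <- 0
  for (sp in morph$spines) {
    ids <- sp$nodes
    r <- n$radius[match(ids, n$id)]
    xyz <- as.matrix(n[match(ids, n$id), c("x", "y", "z")])
    if (!isTRUE(sp$multi)) {
      par <- n$parent[match(ids[1], n$id)]
      pxyz <- as.numeric(n[match(par, n$id), c("x", "y", "z")])
      d <- sqrt(sum((xyz[1, ] - pxyz)^2))
      tot_a <- tot_a + 4 * pi * r[1]^2 +
        2 * pi * neck_radius * max(0, d - r[1])
      tot_v <- tot_v + 4 / 3 * pi * r[1]^3
    } else {
      for (k in seq_len(length(ids) - 1)) {
        L <- sqrt(sum((xyz[k + 1, ] - xyz[k, ])^2))
        tot_a <- tot_a + pi * (r[k] + r[k + 1]) *
          sqrt(L^2 + (r[k + 1] - r[k])^2)
      }
      tot_a <- tot_a + 2 * pi * r[length(r)]^2
      tot_v <- tot_v + sum(4 / 3 * pi * r^3)
    }
  }
  list(area = tot_a, volume = tot_v)
}

# brute-force rolling-window recount: for each window of w consecutive nodes
# of a segment, recount attached spines directly from the annotation table
oracle_rolling_counts <- function(morph, seg, w = 20) {
  att <- vapply(morph$spines, function(sp)
    morph$nodes$parent[match(sp$nodes[1], morph$nodes$id)], numeric(1))
  k <- length(seg$nodes)
  w <- min(w, k)
  vapply(seq_len(k - w + 1), function(i)
    sum(att %in% seg$nodes[i:(i + w - 1)]), numeric(1))
}

# rigid 3D rotation helper for invariance tests
rotate_morph <- function(morph, angles = c(0.3, 0.5, 0.7),
                         shift = c(5, -3, 2)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  xyz <- as.matrix(morph$nodes[, c("x", "y", "z")]) %*% t(R)
  m2 <- morph
  m2$nodes$x <- xyz[, 1] + shift[1]
  m2$nodes$y <- xyz[, 2] + shift[2]
  m2$nodes$z <- xyz[, 3] + shift[3]
  m2
}
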