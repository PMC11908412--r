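# Accessible-volume (AV) engine: grid-based dye positioning of the AV1 type.
# A dye sphere tethered by a flexible linker of given length to an attachment
# atom may occupy any grid point that (a) does not clash with the structure and
# (b) is reachable from the attachment atom by a clash-free path no longer than
# the linker. Reachability uses exact Euclidean distance where the straight
# line of sight is clash-free, and a 26-connected geodesic relaxation seeded
# from the visible set for points hidden behind obstacles, so that the
# free-space AV is an exact ball of the linker radius (up to discretisation).

#' Dye parameters for accessible-volume calculations
#'
#' Single-sphere (AV1) dye model. Defaults are typical for a rhodamine-class
#' dye on a C5/C6 maleimide- or iodoacetamide-type linker; the grid spacing
#' must not exceed the linker width so the path the linker threads is
#' resolvable.
#'
#' @param linker_length Tether length from attachment atom to dye centre (A).
#' @param linker_width Linker thickness (A); constrains `grid_spacing`.
#' @param dye_radius Dye sphere radius (A).
#' @param grid_spacing Grid resolution (A).
#' @return An object of class `dye_parameters`.
#' @export
dye_parameters <- function(linker_length = 15, linker_width = 4.5,
                           dye_radius = 3.5, grid_spacing = 0.9) {
  stopifnot(linker_length > 0, linker_width > 0, dye_radius > 0,
            grid_spacing > 0)
  if (grid_spacing > linker_width)
    stop("grid_spacing must not exceed linker_width")
  structure(list(linker_length = linker_length, linker_width = linker_width,
                 dye_radius = dye_radius, grid_spacing = grid_spacing),
            class = "dye_parameters")
}

# 26-neighbourhood offsets and Euclidean step lengths (in grid units)
.offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  g$w <- sqrt(g$dx^2 + g$dy^2 + g$dz^2)
  g
})

#' Compute the dye-accessible volume at an attachment atom
#'
#' Grid points within the linker length of the attachment atom (measured along
#' clash-free paths) whose dye-radius sphere does not overlap any structure
#' atom. The attachment atom itself is excluded from the clash set, since the
#' dye replaces its substituent. A fully buried attachment site yields an
#' empty AV flagged via `ok = FALSE` rather than an error, so callers can
#' distinguish "no accessible positions" from invalid input.
#'
#' @param structure A `quench_structure`.
#' @param attachment Row index into `structure$atoms` of the attachment atom
#'   (typically one of `structure$attachment_atoms`).
#' @param dye A `dye_parameters` object.
#' @return An object of class `accessible_volume`: list with `points` (n x 3
#'   matrix, A), `mean_position` (length-3), `n_points`, `grid_spacing`,
#'   `attachment_xyz` and `ok`.
#' @export
accessible_volume <- function(structure, attachment, dye = dye_parameters()) {
  stopifnot(inherits(dye, "dye_parameters"),
            attachment %in% seq_len(nrow(structure$atoms)))
  a <- structure$atoms
  origin <- as.numeric(a[attachment, c("x", "y", "z")])
  L <- dye$linker_length
  g <- dye$grid_spacing
  half <- L + dye$dye_radius
  nside <- ceiling(half / g)
  ax <- seq(-nside, nside) * g  # grid centred on the attachment atom
  nx <- length(ax)

  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  euc <- sqrt(rowSums(pts^2))
  obst <- a[-attachment, , drop = FALSE]

  # Two clearance radii per obstacle: the dye sphere (for where the dye centre
  # may sit) and the linker half-width (for where the tether may thread).
  # Cells within one linker width of the anchor are always traversable: the
  # proximal linker segment necessarily hugs the atoms the anchor is bonded
  # to, and without this exemption every attachment site would be self-buried.
  r0 <- dye$linker_width
  dye_blocked <- rep(FALSE, nrow(pts))
  path_blocked <- rep(FALSE, nrow(pts))
  if (nrow(obst) > 0) {
    ox <- obst$x - origin[1]; oy <- obst$y - origin[2]; oz <- obst$z - origin[3]
    rr_dye <- (obst$vdw + dye$dye_radius)^2
    rr_path <- (obst$vdw + dye$linker_width / 2)^2
    for (k in seq_len(nrow(obst))) {
      d2 <- (pts[, 1] - ox[k])^2 + (pts[, 2] - oy[k])^2 + (pts[, 3] - oz[k])^2
      dye_blocked <- dye_blocked | d2 < rr_dye[k]
      path_blocked <- path_blocked | d2 < rr_path[k]
    }
    path_blocked <- path_blocked & euc > r0
  }
  cand <- !path_blocked & euc <= L

  dist <- rep(Inf, nrow(pts))
  if (any(cand)) {
    # line of sight: the straight segment from the anchor (its part beyond the
    # proximal exemption radius) clears every obstacle's linker clearance
    vis <- cand
    if (nrow(obst) > 0) {
      idx <- which(cand)
      px <- pts[idx, 1]; py <- pts[idx, 2]; pz <- pts[idx, 3]
      p2 <- pmax(px^2 + py^2 + pz^2, 1e-12)
      t0 <- pmin(r0 / sqrt(p2), 1)  # start of the checked sub-segment
      seen <- rep(TRUE, length(idx))
      for (k in seq_len(nrow(obst))) {
        t <- (px * ox[k] + py * oy[k] + pz * oz[k]) / p2
        t <- pmin(pmax(t, t0), 1)
        d2 <- (t * px - ox[k])^2 + (t * py - oy[k])^2 + (t * pz - oz[k])^2
        seen <- seen & d2 >= rr_path[k]
      }
      vis[idx] <- seen
    }
    dist[vis] <- euc[vis]

    if (any(cand & !vis)) {
      # label-correcting relaxation on the 26-connected grid over traversable
      # cells; geodesic >= Euclidean, so this only shrinks the hidden fringe
      darr <- array(dist, dim = c(nx, nx, nx))
      free <- array(!path_blocked, dim = c(nx, nx, nx))
      off <- .offsets26
      repeat {
        changed <- FALSE
        for (k in seq_len(nrow(off))) {
          dx <- off$dx[k]; dy <- off$dy[k]; dz <- off$dz[k]
          w <- off$w[k] * g
          xs <- max(1, 1 + dx):min(nx, nx + dx)
          ys <- max(1, 1 + dy):min(nx, nx + dy)
          zs <- max(1, 1 + dz):min(nx, nx + dz)
          src <- darr[xs - dx, ys - dy, zs - dz] + w
          tgt <- darr[xs, ys, zs]
          upd <- src < tgt & free[xs, ys, zs]
          if (any(upd)) {
            tgt[upd] <- src[upd]
            darr[xs, ys, zs] <- tgt
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      dist <- as.numeric(darr)
    }
  }

  keep <- is.finite(dist) & dist <= L & !dye_blocked
  points <- pts[keep, , drop = FALSE]
  n_points <- nrow(points)
  if (n_points == 0) {
    return(structure(list(points = points, mean_position = rep(NA_real_, 3),
                          n_points = 0L, grid_spacing = g,
                          attachment_xyz = origin, ok = FALSE),
                     class = "accessible_volume"))
  }
  points <- sweep(points, 2, -origin)  # back to absolute coordinates
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, mean_position = colMeans(points),
                 n_points = as.integer(n_points), grid_spacing = g,
                 attachment_xyz = origin, ok = TRUE),
            class = "accessible_volume")
}

#' @export
print.accessible_volume <- function(x, ...) {
  if (!x$ok) {
    cat("Accessible volume: EMPTY (attachment site buried)\n")
  } else {
    cat(sprintf(
      "Accessible volume: %d grid points (%.0f A^3), mean position (%.2f, %.2f, %.2f)\n",
      x$n_points, x$n_points * x$grid_spacing^3,
      x$mean_position[1], x$mean_position[2], x$mean_position[3]))
  }
  invisible(x)
}

#' Distance between mean dye positions of two accessible volumes
#'
#' The inter-dye distance convention used throughout the calibration
#' (R_mp): the Euclidean distance between AV centroids.
#'
#' @param av_a,av_b `accessible_volume` objects.
#' @return Distance in Angstroms.
#' @export
mean_position_distance <- function(av_a, av_b) {
  if (!isTRUE(av_a$ok) || !isTRUE(av_b$ok))
    stop("empty accessible volume: dye site unreachable")
  sqrt(sum((av_a$mean_position - av_b$mean_position)^2))
}

#' Mean dye separations for a polyproline ruler series
#'
#' Convenience pipeline: build each Cys-(Pro)n-Cys model, compute both
#' terminal accessible volumes and return the mean-position distances.
#'
#' @param n_pro Integer vector of proline counts.
#' @param dye A `dye_parameters` object.
#' @return Data frame with columns `n_pro` and `distance` (A).
#' @export
ruler_distances <- function(n_pro = c(0, 3, 5, 6), dye = dye_parameters()) {
  distance <- vapply(n_pro, function(n) {
    s <- build_polyproline(n)
    av1 <- accessible_volume(s, s$attachment_atoms[1], dye)
    av2 <- accessible_volume(s, s$attachment_atoms[2], dye)
    mean_position_distance(av1, av2)
  }, numeric(1))
  data.frame(n_pro = n_pro, distance = distance)
}
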