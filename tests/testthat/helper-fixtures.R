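# Shared fixtures built in code.

# small, fast acquisition used by most image tests
small_acq <- function(frame = 128) {
  acquisition_params(frame_shape = c(frame, frame))
}

# a hand-built projection (no generator): background plus the given discs
# (list of c(y, x, r, intensity)) in the actin channel and optional nuclei
# blobs (list of c(y, x)) in the nuclei channel
manual_projection <- function(frame = 128, discs = list(), blobs = list(),
                              bg = 140, blob_amp = 1100) {
  set.seed(42)
  actin <- matrix(bg + rnorm(frame * frame, 0, 3), frame, frame)
  nuc <- matrix(bg + rnorm(frame * frame, 0, 3), frame, frame)
  ix <- matrix(rep(seq_len(frame), each = frame), frame, frame)
  iy <- matrix(rep(seq_len(frame), frame), frame, frame)
  for (d in discs) {
    sel <- (iy - d[1])^2 + (ix - d[2])^2 <= d[3]^2
    actin[sel] <- actin[sel] + d[4]
  }
  for (b in blobs) {
    g <- exp(-((iy - b[1])^2 + (ix - b[2])^2) / (2 * 2^2))
    nuc <- nuc + blob_amp * g
  }
  structure(list(nuclei_2d = nuc, actin_2d = actin,
                 focus_map = matrix(1L, frame, frame)),
            class = "channel_projection")
}

# pixel mask of a disc on an n x n grid
disc_mask <- function(n, cy, cx, r) {
  ix <- matrix(rep(seq_len(n), each = n), n, n)
  iy <- matrix(rep(seq_len(n), n), n, n)
  (iy - cy)^2 + (ix - cx)^2 <= r^2
}

# independent brute-force region oracles (used against region_props paths)

# hull area by lattice-point counting inside the convex hull polygon
# (ray-casting point-in-polygon, boundary-inclusive via tiny tolerance)
oracle_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- unique(cbind(idx[, 2], idx[, 1]))  # x, y
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) < 3) return(nrow(pts))
  xs <- range(pts[, 1]); ys <- range(pts[, 2])
  count <- 0L
  for (x in xs[1]:xs[2]) for (y in ys[1]:ys[2]) {
    if (point_in_poly(x, y, poly)) count <- count + 1L
  }
  count
}

point_in_poly <- function(x, y, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    d <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi))
    len2 <- (xj - xi)^2 + (yj - yi)^2
    if (len2 > 0 && d^2 <= eps * len2 &&
        x >= min(xi, xj) - eps && x <= max(xi, xj) + eps &&
        y >= min(yi, yj) - eps && y <= max(yi, yj) + eps) return(TRUE)
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# boundary polygon length by nearest-neighbour marching over boundary pixels
oracle_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  bnd <- mask & !(pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
                    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)])
  pts <- which(bnd, arr.ind = TRUE)
  n <- nrow(pts)
  if (n < 2) return(0)
  used <- rep(FALSE, n)
  cur <- 1L; used[1] <- TRUE
  total <- 0
  start <- pts[1, ]
  for (step in seq_len(n - 1)) {
    d2 <- (pts[, 1] - pts[cur, 1])^2 + (pts[, 2] - pts[cur, 2])^2
    d2[used] <- Inf
    nxt <- which.min(d2)
    total <- total + sqrt(d2[nxt])
    used[nxt] <- TRUE
    cur <- nxt
  }
  total + sqrt(sum((pts[cur, ] - start)^2))
}
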