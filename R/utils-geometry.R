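# Geometry helpers shared by segmentation and morphometry.

# Zhang-Suen thinning of a logical matrix; returns the 1-pixel skeleton.
skeletonize_mask <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(m)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(p, dy, dx) p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- matrix(FALSE, h + 2, w + 2)
      p[2:(h + 1), 2:(w + 1)] <- pad[2:(h + 1), 2:(w + 1)]
      pad2 <- pad
      P2 <- shift(pad2, -1, 0); P3 <- shift(pad2, -1, 1)
      P4 <- shift(pad2, 0, 1);  P5 <- shift(pad2, 1, 1)
      P6 <- shift(pad2, 1, 0);  P7 <- shift(pad2, 1, -1)
      P8 <- shift(pad2, 0, -1); P9 <- shift(pad2, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cur <- shift(pad2, 0, 0)
      if (step == 1) {
        del <- cur & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        del <- cur & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(del)) {
        changed <- TRUE
        inner <- pad[2:(h + 1), 2:(w + 1)]
        inner[del] <- FALSE
        pad[2:(h + 1), 2:(w + 1)] <- inner
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)]
}

# number of skeleton branch points: skeleton pixels with >= 3 skeleton
# neighbours (8-connectivity)
count_branch_points <- function(mask) {
  sk <- skeletonize_mask(mask)
  if (!any(sk)) return(0L)
  h <- nrow(sk); w <- ncol(sk)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- sk
  nb <- matrix(0L, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- nb + pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  }
  sum(sk & nb >= 3)
}

# area of the convex hull of a pixel set, in pixel units. Lattice-polygon
# area from the shoelace formula on pixel centres, corrected by Pick's
# theorem (boundary/2 + 1) so a convex digital disc has hull area equal to
# its pixel count.
hull_area_px <- function(ys, xs) {
  n <- length(xs)
  if (n <= 2) return(n)
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) <= 2) return(n)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  m <- length(h)
  if (m < 3) return(n)
  j <- c(2:m, 1)
  shoelace <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  perim_lattice <- sum(vapply(seq_len(m), function(i) {
    k <- j[i]
    gcd2(abs(hx[k] - hx[i]), abs(hy[k] - hy[i]))
  }, numeric(1)))
  shoelace + perim_lattice / 2 + 1
}

gcd2 <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

# local maxima of a smoothed image within a mask, with minimum separation:
# plateau-tolerant (dilate-compare), clusters of maxima closer than min_dist
# are merged to their centroid. Returns a matrix with columns y, x ordered
# row-major (deterministic).
find_seeds <- function(img, mask, min_dist) {
  r <- max(3, round(min_dist / 2))
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  mx <- EBImage::dilate(EBImage::Image(img), brush)
  peaks <- (img >= as.matrix(mx) - 1e-9) & mask
  if (!any(peaks)) return(matrix(numeric(0), 0, 2))
  lab <- EBImage::bwlabel(EBImage::Image(peaks))
  lab <- as.matrix(lab)
  ids <- sort(unique(lab[lab > 0]))
  cent <- t(vapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2)))
  # greedy merge of near-duplicate seeds, processed in row-major order
  ord <- order(cent[, 1], cent[, 2])
  cent <- cent[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cent))
  for (i in seq_len(nrow(cent))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cent))) {
      if (j <= i || !keep[j]) next
      if (sqrt(sum((cent[i, ] - cent[j, ])^2)) < min_dist) keep[j] <- FALSE
    }
  }
  cent[keep, , drop = FALSE]
}

# relabel a label matrix so labels are consecutive positive integers ordered
# by first pixel in row-major (column-major R index) order
relabel_consecutive <- function(lab) {
  ids <- unique(as.vector(lab))
  ids <- ids[ids > 0]
  if (!length(ids)) return(list(labels = lab, map = integer(0)))
  first <- vapply(ids, function(i) which(lab == i)[1], numeric(1))
  ord <- ids[order(first)]
  out <- array(0L, dim = dim(lab))
  for (k in seq_along(ord)) out[lab == ord[k]] <- k
  list(labels = out, map = stats::setNames(seq_along(ord), ord))
}

mode_int <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}
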