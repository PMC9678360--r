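# Medial-axis machinery for rod-shaped objects.
#
# Morphological thinning (Zhang-Suen), pruning of the skeleton to its
# longest geodesic path, tangential extension of the path to the object
# boundary, and resampling to 1-pixel arc-length steps. No installed
# package provides 2-D skeletonization, so the thinning pass is implemented
# here; it is only ever applied to small single-cell masks.

# Zhang-Suen thinning of a logical matrix; returns a logical matrix
thin_mask <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      idx <- which(m == 1L, arr.ind = TRUE)
      if (nrow(idx) == 0) break
      r <- idx[, 1]; c <- idx[, 2]
      p2 <- m[cbind(r - 1, c)];     p3 <- m[cbind(r - 1, c + 1)]
      p4 <- m[cbind(r, c + 1)];     p5 <- m[cbind(r + 1, c + 1)]
      p6 <- m[cbind(r + 1, c)];     p7 <- m[cbind(r + 1, c - 1)]
      p8 <- m[cbind(r, c - 1)];     p9 <- m[cbind(r - 1, c - 1)]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- rowSums(seqs[, 1:8, drop = FALSE] == 0 & seqs[, 2:9, drop = FALSE] == 1)
      if (phase == 1) {
        del <- b >= 2 & b <= 6 & a == 1 & p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        del <- b >= 2 & b <= 6 & a == 1 & p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(del)) {
        m[idx[del, , drop = FALSE]] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] == 1L
}

# longest geodesic path through a skeleton (8-connected), as a two-column
# (row, col) matrix; two passes of BFS from an extremal pixel
skeleton_longest_path <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)
  np <- nrow(pix)
  if (np == 0) abort("empty skeleton", class = "polegrow_shape_error")
  if (np == 1) return(pix)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[pix] <- seq_len(np)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  neighbours <- function(i) {
    r <- pix[i, 1] + offs$dr
    c <- pix[i, 2] + offs$dc
    ok <- r >= 1 & r <= nrow(skel) & c >= 1 & c <= ncol(skel)
    n <- id[cbind(r[ok], c[ok])]
    n[n > 0]
  }
  bfs <- function(start) {
    dist <- rep(NA_integer_, np)
    parent <- rep(NA_integer_, np)
    dist[start] <- 0L
    queue <- start
    while (length(queue) > 0) {
      i <- queue[1]
      queue <- queue[-1]
      for (j in neighbours(i)) {
        if (is.na(dist[j])) {
          dist[j] <- dist[i] + 1L
          parent[j] <- i
          queue <- c(queue, j)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  if (anyNA(b1$dist)) {
    abort("skeleton is disconnected; mask does not describe a single object",
          class = "polegrow_shape_error")
  }
  u <- which.max(b1$dist)
  b2 <- bfs(u)
  v <- which.max(b2$dist)
  path <- integer(0)
  i <- v
  while (!is.na(i)) {
    path <- c(i, path)
    i <- b2$parent[i]
  }
  pix[path, , drop = FALSE]
}

# extend a path tangentially (1-px steps) until it leaves the mask
extend_to_boundary <- function(path, mask) {
  step_out <- function(anchor_idx, tip_idx) {
    k <- min(5, nrow(path) - 1)
    dir <- path[tip_idx, ] - path[anchor_idx, ]
    len <- sqrt(sum(dir^2))
    if (len == 0) return(NULL)
    dir <- dir / len
    pts <- NULL
    p <- path[tip_idx, ]
    repeat {
      p <- p + dir
      pr <- round(p)
      if (pr[1] < 1 || pr[1] > nrow(mask) || pr[2] < 1 || pr[2] > ncol(mask) ||
          !mask[pr[1], pr[2]]) {
        break
      }
      pts <- rbind(pts, p)
    }
    pts
  }
  k <- min(5, nrow(path) - 1)
  head_ext <- step_out(1 + k, 1)
  tail_ext <- step_out(nrow(path) - k, nrow(path))
  rbind(
    if (!is.null(head_ext)) head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE],
    path,
    tail_ext
  )
}

# resample a polyline to 1-px arc-length steps
resample_path <- function(path) {
  if (nrow(path) < 2) return(path)
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- seq(0, total, by = 1)
  cbind(
    approx(s, path[, 1], xout = targets)$y,
    approx(s, path[, 2], xout = targets)$y
  )
}

# full medial-axis path for one object mask: (row, col) matrix, 1-px steps
medial_axis_path <- function(mask) {
  skel <- thin_mask(mask)
  path <- skeleton_longest_path(skel)
  path <- extend_to_boundary(path, mask)
  resample_path(path)
}
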