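# Independent oracles used across the suite.

# queue-based flood fill, 8-connected; returns number of components
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  n
}

# rasterize a polygon with the half-open pixel-centre convention:
# count integer points (x, y) with x in [min, max) etc. inside the
# polygon (even-odd rule)
rasterize_area <- function(poly) {
  xs <- poly[, 2]; ys <- poly[, 1]
  gx <- seq(floor(min(xs)), ceiling(max(xs)))
  gy <- seq(floor(min(ys)), ceiling(max(ys)))
  pts <- expand.grid(x = gx, y = gy)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cross <- ((yi > pts$y) != (yj > pts$y)) &
      (pts$x < (xj - xi) * (pts$y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  sum(inside)
}

# draw a filled disk mask
disk_mask <- function(nr, nc, r0, c0, rad) {
  outer(seq_len(nr), seq_len(nc),
        function(r, c) (r - r0)^2 + (c - c0)^2 <= rad^2)
}

make_constants <- function() physical_constants()

quiet_env <- function(v_mm_s = 5, H_um = 250)
  fluid_env(v_mm_s * 1e-3, channel_height = H_um * 1e-6)
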