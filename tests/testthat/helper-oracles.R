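# Independent oracles and small fixtures, built in code.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# all-true mask volume matching a phantom
full_mask <- function(vol) {
  voxel_volume(array(1L, dim(vol)), voxel_size(vol))
}

# Brute-force directional MIL crossing counter. Implements the same sampling
# contract as the compiled scanner (basis construction, offset grid, step
# lattice, nearest-voxel rounding, per-line minimum length) but written
# independently in vectorised R. Returns total in-mask length (voxel units)
# and marrow->bone crossings per direction.
mil_bruteforce <- function(bone, mask, center, radius, dirs,
                           line_spacing = 1, step = 1, min_len = 2) {
  d <- dim(bone)
  out <- matrix(0, nrow(dirs), 2)
  for (di in seq_len(nrow(dirs))) {
    w <- dirs[di, ]
    aw <- abs(w)
    e <- c(0, 0, 0)
    e[which.min(aw)] <- 1
    u <- c(w[2] * e[3] - w[3] * e[2],
           w[3] * e[1] - w[1] * e[3],
           w[1] * e[2] - w[2] * e[1])
    u <- u / sqrt(sum(u^2))
    v <- c(w[2] * u[3] - w[3] * u[2],
           w[3] * u[1] - w[1] * u[3],
           w[1] * u[2] - w[2] * u[1])
    K <- floor(radius / line_spacing)
    totlen <- 0
    totcr <- 0
    for (ia in -K:K) for (ib in -K:K) {
      a <- ia * line_spacing
      b <- ib * line_spacing
      rho2 <- a * a + b * b
      if (rho2 > radius^2) next
      L <- sqrt(radius^2 - rho2)
      M <- floor(L / step)
      base <- center + a * u + b * v
      ms <- (-M):M
      px <- base[1] + ms * step * w[1]
      py <- base[2] + ms * step * w[2]
      pz <- base[3] + ms * step * w[3]
      i <- floor(px + 0.5)
      j <- floor(py + 0.5)
      k <- floor(pz + 0.5)
      inside <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
      idx <- 1 + i + d[1] * (j + d[2] * k)
      inm <- inside
      inm[inside] <- mask[idx[inside]] != 0
      bv <- rep(NA_integer_, length(ms))
      bv[inm] <- bone[idx[inm]]
      nin <- sum(inm)
      n <- length(ms)
      cr <- if (n > 1)
        sum(inm[-1] & inm[-n] & bv[-n] == 0 & bv[-1] == 1, na.rm = TRUE)
      else 0
      if (nin * step >= min_len) {
        totlen <- totlen + nin * step
        totcr <- totcr + cr
      }
    }
    out[di, ] <- c(totlen, totcr)
  }
  out
}

# brute-force squared EDT (distance to nearest background voxel)
edt_bruteforce <- function(fg) {
  d <- dim(fg)
  bg <- which(!fg, arr.ind = TRUE)
  out <- array(0, d)
  for (i in which(fg)) {
    ai <- arrayInd(i, d)
    out[i] <- min((bg[, 1] - ai[1])^2 + (bg[, 2] - ai[2])^2 +
                    (bg[, 3] - ai[3])^2)
  }
  out
}

# small hollow tube along dim 1 with closed end caps (a closed shell)
hollow_tube <- function(n = 40, r_out = 15, wall = 5, vs = 0.1) {
  a <- array(0L, c(n, n, n))
  cy <- cx <- (n + 1) / 2
  for (z in 3:(n - 2)) {
    yy <- matrix(seq_len(n), n, n)
    xx <- t(yy)
    rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
    ring <- rr <= r_out & (rr > r_out - wall | z <= 2 + wall | z >= n - 1 - wall)
    a[z, , ][ring] <- 1L
  }
  voxel_volume(a, vs)
}
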