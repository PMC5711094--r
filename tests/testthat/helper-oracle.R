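# Brute-force gamma oracle, kept independent of the engine: its own bilinear
# interpolation (index arithmetic written from the definition, not shared
# with the package), exhaustive enumeration of every candidate shift on the
# search disc per reference pixel, no early termination and no running
# minimum across pixels.

oracle_interp_vec <- function(plane, ys, xs) {
  v <- plane$values
  ny <- nrow(v); nx <- ncol(v)
  y0 <- plane$origin[1]; x0 <- plane$origin[2]
  sy <- plane$spacing[1]; sx <- plane$spacing[2]
  gy <- (ys - y0) / sy
  gx <- (xs - x0) / sx
  out <- rep(NA_real_, length(gy))
  ok <- gy >= 0 & gy <= ny - 1 & gx >= 0 & gx <= nx - 1
  gy <- gy[ok]; gx <- gx[ok]
  iy <- pmin(floor(gy), ny - 2); ix <- pmin(floor(gx), nx - 2)
  ty <- gy - iy; tx <- gx - ix
  # linear (column-major) indices of the four corners
  idx00 <- ix * ny + iy + 1
  idx10 <- idx00 + 1
  idx01 <- idx00 + ny
  idx11 <- idx01 + 1
  out[ok] <- v[idx00] * (1 - ty) * (1 - tx) + v[idx10] * ty * (1 - tx) +
    v[idx01] * (1 - ty) * tx + v[idx11] * ty * tx
  out
}

gamma_oracle <- function(reference, evaluated, dose_tol = 3, dta = 3,
                         step = dta / 20, radius = 3 * dta) {
  ax <- plane_axes(reference)
  refv <- reference$values
  dD <- dose_tol / 100 * max(refv)
  k <- seq(-floor(radius / step), floor(radius / step)) * step
  offs <- expand.grid(dx = k, dy = k)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2 + 1e-12, ]
  dist2 <- (offs$dx^2 + offs$dy^2) / dta^2
  gm <- matrix(NA_real_, nrow(refv), ncol(refv))
  for (i in seq_len(nrow(refv))) for (j in seq_len(ncol(refv))) {
    ev <- oracle_interp_vec(evaluated, ax$y[i] + offs$dy, ax$x[j] + offs$dx)
    g2 <- ((ev - refv[i, j]) / dD)^2 + dist2
    if (any(!is.na(g2))) gm[i, j] <- sqrt(min(g2, na.rm = TRUE))
  }
  gm
}
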