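# Grid resampling helpers shared by the three stages.

# Resize a (nz, ny, nx) array to out_dim; bilinear in-plane + linear in z for
# intensities, nearest neighbour everywhere for masks.
resize_volume <- function(vox, out_dim, bilinear = TRUE) {
  d <- dim(vox)
  oz <- out_dim[1]; oy <- out_dim[2]; ox <- out_dim[3]
  tmp <- array(0, c(d[1], oy, ox))
  for (z in seq_len(d[1]))
    tmp[z, , ] <- cpp_resize2d(vox[z, , ], oy, ox, as.integer(bilinear))
  if (oz == d[1]) return(tmp)
  out <- array(0, c(oz, oy, ox))
  src <- (seq_len(oz) - 0.5) * d[1] / oz - 0.5  # 0-based source position
  if (bilinear) {
    for (i in seq_len(oz)) {
      z0 <- floor(src[i]); f <- src[i] - z0
      za <- min(max(z0, 0), d[1] - 1) + 1
      zb <- min(max(z0 + 1, 0), d[1] - 1) + 1
      out[i, , ] <- (1 - f) * tmp[za, , ] + f * tmp[zb, , ]
    }
  } else {
    for (i in seq_len(oz)) {
      zi <- min(max(round(src[i]), 0), d[1] - 1) + 1
      out[i, , ] <- tmp[zi, , ]
    }
  }
  out
}

# Random rotation/shift/zoom applied consistently to an intensity slice and
# its target mask (2D matrices).  Draws use the current RNG stream.
draw_augment <- function(rot = 8, shift = 4, zoom = c(0.95, 1.08)) {
  list(angle = stats::runif(1, -rot, rot),
       dy = sample(-shift:shift, 1), dx = sample(-shift:shift, 1),
       zoom = stats::runif(1, zoom[1], zoom[2]))
}

apply_augment2d <- function(m, aug, bilinear = TRUE, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  zy <- max(2, round(ny * aug$zoom)); zx <- max(2, round(nx * aug$zoom))
  z <- cpp_resize2d(m, zy, zx, as.integer(bilinear))
  out <- matrix(fill, ny, nx)
  # centre crop or pad back to the original shape
  sy <- max(1, (zy - ny) %/% 2 + 1); sx <- max(1, (zx - nx) %/% 2 + 1)
  ty <- max(1, (ny - zy) %/% 2 + 1); tx <- max(1, (nx - zx) %/% 2 + 1)
  h <- min(ny, zy); w <- min(nx, zx)
  out[ty:(ty + h - 1), tx:(tx + w - 1)] <- z[sy:(sy + h - 1), sx:(sx + w - 1)]
  out <- cpp_rotate2d(out, aug$angle, as.integer(bilinear), fill)
  # integer shift
  sh <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - aug$dy; xs <- seq_len(nx) - aug$dx
  ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
  sh[which(ok_y), which(ok_x)] <- out[ys[ok_y], xs[ok_x]]
  sh
}
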