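# Shared fixtures, generated in code and memoised per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one deterministic stroke phantom, reused across files
fixture_phantom <- function() {
  memo("phantom", generate_phantom(phantom_params(seed = 101L), "fix1"))
}

# a small cohort shared by several structural tests
fixture_cohort <- function() {
  memo("cohort", generate_cohort(8, 0.5, seed = 202L,
                                 split_fractions = c(train = 0.5, val = 0.25,
                                                     test = 0.25)))
}

# independent flood-fill component labelling (26-connectivity), used as an
# oracle against the package's labelling and filtering
oracle_label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask != 0)
  for (start in idx_all) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      i <- queue[[1]]; queue <- queue[-1]
      z <- (i - 1) %% d[1] + 1
      y <- ((i - 1) %/% d[1]) %% d[2] + 1
      x <- (i - 1) %/% (d[1] * d[2]) + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        zz <- z + dz; yy <- y + dy; xx <- x + dx
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
            xx < 1 || xx > d[3]) next
        j <- zz + d[1] * (yy - 1) + d[1] * d[2] * (xx - 1)
        if (mask[j] != 0 && lab[j] == 0) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# brute-force in-plane Euclidean distance from each pixel to a point set
oracle_dist2d <- function(ny, nx, pts) {
  out <- matrix(Inf, ny, nx)
  if (nrow(pts) == 0) return(out)
  for (y in seq_len(ny)) for (x in seq_len(nx))
    out[y, x] <- sqrt(min((pts[, 1] - y)^2 + (pts[, 2] - x)^2))
  out
}
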