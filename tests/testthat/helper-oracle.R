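# Adaptive-quadrature oracle for the cuboid-source potential, independent of
# the closed-form implementation. Exterior field points: direct 3-D adaptive
# quadrature of 1/r. Points inside (or on the boundary of) the box: split at
# the field point into octants, reflect each into the positive octant, and
# substitute t = u^2 per axis, which removes the corner singularity
# (integrand 8uvw / sqrt(u^4 + v^4 + w^4), bounded). pracma::integral3 is
# more robust when the longest axis comes first, so octant extents are
# sorted; on failure the remaining axis orders are tried.

box_potential_oracle <- function(box_center, box_dims, p, sigma = 1) {
  lo <- box_center - box_dims / 2 - p
  hi <- box_center + box_dims / 2 - p
  touching <- all(lo <= 0) && all(hi >= 0)
  if (!touching) {
    f <- function(x, y, z) 1 / sqrt(x^2 + y^2 + z^2)
    val <- pracma::integral3(f, lo[1], hi[1], lo[2], hi[2], lo[3], hi[3],
                             reltol = 1e-8)
    return(val / (4 * pi * sigma))
  }
  h2 <- function(u, v, w) {
    s <- sqrt(u^4 + v^4 + w^4)
    r <- 8 * u * v * w / s
    r[s == 0] <- 0
    r
  }
  corner_piece <- function(len) {
    len <- sort(len, decreasing = TRUE)
    perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                  c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))
    for (pm in perms) {
      l <- len[pm]
      val <- try(pracma::integral3(h2, 0, sqrt(l[1]), 0, sqrt(l[2]),
                                   0, sqrt(l[3]), reltol = 1e-6),
                 silent = TRUE)
      if (!inherits(val, "try-error")) return(val)
    }
    stop("quadrature failed for octant ", paste(len, collapse = " x "))
  }
  val <- 0
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
    len <- c(if (sx < 0) -lo[1] else hi[1],
             if (sy < 0) -lo[2] else hi[2],
             if (sz < 0) -lo[3] else hi[3])
    if (any(len <= 0)) next
    val <- val + corner_piece(len)
  }
  val / (4 * pi * sigma)
}

# random (box, point) configurations: 1/3 interior, 1/3 exterior, 1/3 on a
# face of the box
random_box_configs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(t) {
    center <- runif(3, -2, 2)
    dims <- runif(3, 0.1, 2)
    p <- if (t %% 3 == 0) {
      center + (runif(3) - 0.5) * dims * 0.9
    } else if (t %% 3 == 1) {
      center + runif(3, 1, 4) * sample(c(-1, 1), 3, TRUE)
    } else {
      face <- sample(3, 1)
      q <- center + (runif(3) - 0.5) * dims * 0.8
      q[face] <- center[face] + dims[face] / 2
      q
    }
    list(center = center, dims = dims, p = p)
  })
}
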