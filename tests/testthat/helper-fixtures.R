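# Shared fixtures and independent oracles. Everything is generated in code;
# expensive galleries are built once per test run and cached.

.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

# ---- analytic binary masks (no rendering involved) ------------------------

disk_mask <- function(radius_px, pad = 3L) {
  n <- 2L * (as.integer(ceiling(radius_px)) + pad) + 1L
  c0 <- (n + 1) / 2
  ij <- expand.grid(i = 1:n, j = 1:n)
  matrix((ij$i - c0)^2 + (ij$j - c0)^2 <= radius_px^2, n, n)
}

rect_mask <- function(h_px, w_px, pad = 3L) {
  m <- matrix(FALSE, h_px + 2 * pad, w_px + 2 * pad)
  m[pad + seq_len(h_px), pad + seq_len(w_px)] <- TRUE
  m
}

ellipse_mask <- function(a_px, b_px, angle = 0, pad = 3L) {
  n <- 2L * (as.integer(ceiling(a_px)) + pad) + 1L
  c0 <- (n + 1) / 2
  ij <- expand.grid(i = 1:n, j = 1:n)
  x <- ij$j - c0; y <- ij$i - c0
  xr <- cos(angle) * x + sin(angle) * y
  yr <- -sin(angle) * x + cos(angle) * y
  matrix((xr / a_px)^2 + (yr / b_px)^2 <= 1, n, n)
}

# half-annulus opening downward: mid-radius r, limb width w
horseshoe_mask <- function(r_px, w_px, pad = 3L) {
  n <- 2L * (as.integer(ceiling(r_px + w_px / 2)) + pad) + 1L
  c0 <- (n + 1) / 2
  ij <- expand.grid(i = 1:n, j = 1:n)
  x <- ij$j - c0; y <- c0 - ij$i
  rad <- sqrt(x^2 + y^2)
  matrix(rad >= r_px - w_px / 2 & rad <= r_px + w_px / 2 & y >= 0, n, n)
}

# ---- independent oracles --------------------------------------------------

# max Feret diameter over convex-hull vertices of pixel corners
feret_oracle <- function(bits) {
  ij <- which(bits, arr.ind = TRUE)
  pts <- rbind(cbind(ij[, 1] - 0.5, ij[, 2] - 0.5),
               cbind(ij[, 1] - 0.5, ij[, 2] + 0.5),
               cbind(ij[, 1] + 0.5, ij[, 2] - 0.5),
               cbind(ij[, 1] + 0.5, ij[, 2] + 0.5))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  max(dist(hull))
}

# plain-R all-pairs geodesic diameter on the same 16-neighbour metric with
# the straight-segment Euclidean upgrade (independent of the compiled code)
geodesic_oracle <- function(bits) {
  nr <- nrow(bits); nc <- ncol(bits)
  idx <- which(bits)
  pos <- arrayInd(idx, dim(bits))
  key <- setNames(seq_along(idx), idx)
  off <- rbind(expand.grid(dr = -1:1, dc = -1:1)[-5, ],
               data.frame(dr = c(-1, -1, 1, 1, -2, -2, 2, 2),
                          dc = c(-2, 2, -2, 2, -1, 1, -1, 1)))
  mids <- list(c(0, -1, -1, -1), c(0, 1, -1, 1), c(0, -1, 1, -1),
               c(0, 1, 1, 1), c(-1, 0, -1, -1), c(-1, 0, -1, 1),
               c(1, 0, 1, -1), c(1, 0, 1, 1))
  inb <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc
  nbrs <- lapply(seq_along(idx), function(v) {
    r <- pos[v, 1]; c <- pos[v, 2]
    out <- list()
    for (k in seq_len(nrow(off))) {
      r2 <- r + off$dr[k]; c2 <- c + off$dc[k]
      if (!inb(r2, c2) || !bits[r2, c2]) next
      if (k > 8) {
        md <- mids[[k - 8]]
        if (!bits[r + md[1], c + md[2]] || !bits[r + md[3], c + md[4]]) next
      }
      cost <- sqrt(off$dr[k]^2 + off$dc[k]^2)
      out[[length(out) + 1]] <- c(key[[as.character((c2 - 1) * nr + r2)]], cost)
    }
    out
  })
  seg_visible <- function(p, q) {
    d <- sqrt(sum((p - q)^2))
    if (d < 1) return(TRUE)
    f <- seq(0, 1, length.out = ceiling(d / 0.25) + 1)
    rr <- round(p[1] + f * (q[1] - p[1]))
    cc <- round(p[2] + f * (q[2] - p[2]))
    all(bits[cbind(rr, cc)])
  }
  bd <- which(sapply(seq_along(idx), function(v) {
    r <- pos[v, 1]; c <- pos[v, 2]
    r == 1 || r == nr || c == 1 || c == nc ||
      !(bits[r - 1, c] && bits[r + 1, c] && bits[r, c - 1] && bits[r, c + 1])
  }))
  best <- 0
  for (s in bd) {
    dist <- rep(Inf, length(idx)); dist[s] <- 0
    done <- rep(FALSE, length(idx))
    repeat {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (nb in nbrs[[u]]) {
        nd <- dist[u] + nb[2]
        if (nd < dist[nb[1]]) dist[nb[1]] <- nd
      }
      if (all(done | !is.finite(dist))) break
    }
    for (t in bd[bd > s]) {
      d <- if (seg_visible(pos[s, ], pos[t, ]))
        sqrt(sum((pos[s, ] - pos[t, ])^2)) else dist[t]
      if (d > best) best <- d
    }
  }
  best
}

# ---- cached rendered galleries -------------------------------------------

mixed_gallery <- function() cached("mixed", render_gallery(
  250, c(spheroid = 0.55, oblate_polar = 0.05, debris = 0.2,
         doublet = 0.1, cropped = 0.1),
  seed = 101, n_individuals = 3))

mixed_features <- function() cached("mixed_f", extract_gallery(mixed_gallery()))

oblate_gallery <- function() cached("oblate", render_gallery(
  120, c(oblate_polar = 0.5, oblate_equatorial = 0.5), seed = 55))

oblate_features <- function() cached("oblate_f", extract_gallery(oblate_gallery()))
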