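# Independent oracles used across the suite: everything here is plain R,
# written without reference to the package's compute paths.

# central finite-difference gradient of scalar-valued f at x
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# exhaustive double-loop gated axial attention on (N, Z, D, H, W) volumes
attention_oracle <- function(q, k, v, axis, tb, heads, dm) {
  d <- dim(q)
  L <- switch(axis, depth = d[3], height = d[4], width = d[5])
  yo <- array(0, d)
  g <- tb$gates
  for (n in seq_len(d[1])) for (h in seq_len(heads))
    for (z in seq_len(d[3])) for (yy in seq_len(d[4])) for (x in seq_len(d[5])) {
      ch <- (h - 1) * dm + seq_len(dm)
      i <- switch(axis, depth = z, height = yy, width = x)
      s <- numeric(L)
      for (j in seq_len(L)) {
        zz <- z; yj <- yy; xj <- x
        if (axis == "depth") zz <- j else if (axis == "height") yj <- j else xj <- j
        kj <- k[n, ch, zz, yj, xj]
        s[j] <- sum(q[n, ch, z, yy, x] * kj) +
          g[1] * sum(q[n, ch, z, yy, x] * tb$rq[i, j, ]) +
          g[2] * sum(kj * tb$rk[i, j, ])
      }
      a <- exp(s - max(s)); a <- a / sum(a)
      acc <- numeric(dm)
      for (j in seq_len(L)) {
        zz <- z; yj <- yy; xj <- x
        if (axis == "depth") zz <- j else if (axis == "height") yj <- j else xj <- j
        acc <- acc + a[j] * (g[3] * v[n, ch, zz, yj, xj] + g[4] * tb$rv[i, j, ])
      }
      yo[n, ch, z, yy, x] <- acc
    }
  yo
}

# 26-connectivity connected-component count by breadth-first search
count_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  ncomp <- 0L
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    ncomp <- ncomp + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- ncomp
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (o in seq_len(nrow(off))) {
        nb <- cur + off[o, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] != 0 && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- ncomp
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  ncomp
}

# all-pairs min distances from rows of A to rows of B (plain R)
min_dists_oracle <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    sqrt(min(colSums((t(B) - A[i, ])^2)))
  }, numeric(1))
}

# population-variance group normalization (one group) as used on-layer
gn_oracle <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (n in seq_len(d[1])) {
    v <- x[n, , , , ]
    vn <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + eps)
    vn <- array(vn, d[-1])
    for (c0 in seq_len(d[2])) out[n, c0, , , ] <- vn[c0, , , ] * gamma[c0] + beta[c0]
  }
  out
}

tiny_phantom_cases <- function(n, extent = 16L, seed = 500L) {
  spec <- phantom_spec(extent = extent, n_branches = 1L,
                       radius_range = c(1.5, 2), distractor_count = 0L,
                       seed = seed)
  lapply(seq_len(n), function(i) {
    s <- spec; s$seed <- spec$seed + i
    generate_phantom(s)
  })
}
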