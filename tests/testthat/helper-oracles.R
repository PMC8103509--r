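# Naive reference implementations used as independent oracles. These are
# deliberately written with different algorithms / plain nested loops and
# never share code with the package internals.

oracle_dirs <- list(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetric co-occurrence counts by exhaustive pair enumeration.
oracle_glcm <- function(lev, ng) {
  d <- dim(lev)
  out <- array(0, c(ng, ng, 13))
  for (di in seq_along(oracle_dirs)) {
    dd <- oracle_dirs[[di]]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      li <- lev[x, y, z]
      if (is.na(li)) next
      q <- c(x, y, z) + dd
      if (!in_bounds(q, d)) next
      lj <- lev[q[1], q[2], q[3]]
      if (is.na(lj)) next
      out[li, lj, di] <- out[li, lj, di] + 1
      out[lj, li, di] <- out[lj, li, di] + 1
    }
  }
  out
}

# Run lengths via line extraction + rle().
oracle_glrlm <- function(lev, ng) {
  d <- dim(lev)
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, 13))
  for (di in seq_along(oracle_dirs)) {
    dd <- oracle_dirs[[di]]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      p <- c(x, y, z)
      if (in_bounds(p - dd, d)) next     # not a line start
      line <- c()
      while (in_bounds(p, d)) {
        line <- c(line, lev[p[1], p[2], p[3]])
        p <- p + dd
      }
      # NA breaks runs; rle on each non-NA segment
      seg <- split(line, cumsum(is.na(line)))
      for (s in seg) {
        s <- s[!is.na(s)]
        if (length(s) == 0) next
        r <- rle(s)
        for (k in seq_along(r$lengths))
          out[r$values[k], r$lengths[k], di] <-
            out[r$values[k], r$lengths[k], di] + 1
      }
    }
  }
  out
}

# Zones by iterative minimum-label propagation until fixpoint.
oracle_glszm <- function(lev) {
  d <- dim(lev)
  n <- prod(d)
  comp <- array(seq_len(n), d)
  comp[is.na(lev)] <- NA
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  repeat {
    changed <- FALSE
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      if (is.na(lev[x, y, z])) next
      for (o in seq_len(nrow(offs))) {
        q <- c(x + offs$dx[o], y + offs$dy[o], z + offs$dz[o])
        if (!in_bounds(q, d)) next
        if (is.na(lev[q[1], q[2], q[3]])) next
        if (lev[q[1], q[2], q[3]] != lev[x, y, z]) next
        m <- min(comp[x, y, z], comp[q[1], q[2], q[3]])
        if (comp[x, y, z] != m) { comp[x, y, z] <- m; changed <- TRUE }
        if (comp[q[1], q[2], q[3]] != m) {
          comp[q[1], q[2], q[3]] <- m; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ids <- stats::na.omit(unique(as.vector(comp)))
  do.call(rbind, lapply(ids, function(id) {
    vox <- which(comp == id)
    c(level = lev[vox[1]], size = length(vox))
  }))
}

oracle_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  out <- matrix(0, ng, 27)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (is.na(li)) next
    dep <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(q, d)) next
      lj <- lev[q[1], q[2], q[3]]
      if (is.na(lj)) next
      if (abs(lj - li) <= alpha) dep <- dep + 1
    }
    out[li, dep + 1] <- out[li, dep + 1] + 1
  }
  out
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  ncount <- numeric(ng); s <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (is.na(li)) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(q, d)) next
      lj <- lev[q[1], q[2], q[3]]
      if (!is.na(lj)) nb <- c(nb, lj)
    }
    if (length(nb) > 0) {
      ncount[li] <- ncount[li] + 1
      s[li] <- s[li] + abs(li - mean(nb))
    }
  }
  list(n = ncount, s = s)
}

# Random discretized ROI: levels 1..ng with NA holes, guaranteed nonempty.
random_level_array <- function(dims, ng, p_na = 0.3) {
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  lev[stats::runif(prod(dims)) < p_na] <- NA_integer_
  if (all(is.na(lev))) lev[1] <- 1L
  lev
}

# Direct (non-separable) 2-D resampling oracle: joint kernel evaluation
# with edge clamping and joint weight normalization, one slice at a time.
oracle_resample_2d <- function(mat, d_in, d_out, method, m = 3L,
                               sigma_factor = 0.8) {
  n_in <- dim(mat)
  n_out <- pmax(1L, as.integer(round(n_in * d_in / d_out)))
  kfun <- function(u) {
    if (method == "Linear") pmax(0, 1 - abs(u))
    else if (method == "NN") as.numeric(abs(u) <= 0.5)  # handled separately
    else if (method == "Gaussian") {
      sig <- sigma_factor * d_out / d_in
      exp(-0.5 * (u / sig)^2)
    } else radstab::kernel_weight(method, u, m)
  }
  support <- if (method == "Linear") 1 else if (method == "Gaussian")
    max(1, ceiling(3 * sigma_factor * d_out / d_in)) else m
  out <- matrix(0, n_out[1], n_out[2])
  for (j2 in seq_len(n_out[2])) for (j1 in seq_len(n_out[1])) {
    t1 <- (j1 - 1) * d_out / d_in
    t2 <- (j2 - 1) * d_out / d_in
    if (method == "NN") {
      i1 <- min(max(floor(t1 + 0.5), 0), n_in[1] - 1)
      i2 <- min(max(floor(t2 + 0.5), 0), n_in[2] - 1)
      out[j1, j2] <- mat[i1 + 1, i2 + 1]
      next
    }
    i1s <- floor(t1 - support):ceiling(t1 + support)
    i2s <- floor(t2 - support):ceiling(t2 + support)
    acc <- 0; wsum <- 0
    for (i1 in i1s) for (i2 in i2s) {
      w <- kfun(t1 - i1) * kfun(t2 - i2)
      if (w == 0) next
      c1 <- min(max(i1, 0), n_in[1] - 1)
      c2 <- min(max(i2, 0), n_in[2] - 1)
      acc <- acc + w * mat[c1 + 1, c2 + 1]
      wsum <- wsum + w
    }
    out[j1, j2] <- acc / wsum
  }
  out
}

# Direct CCC formula, coded separately from the package.
oracle_ccc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}
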