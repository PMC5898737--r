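# Small-scale reference implementations used as independent oracles, all
# written as explicit index loops so they share no code with the package.

# Trilinear sampling at cell-centred coordinates, one query at a time.
oracleTrilinear <- function(arr, targetShape) {
  d <- dim(arr)
  out <- array(0, targetShape)
  for (k in seq_len(targetShape[3])) for (j in seq_len(targetShape[2]))
    for (i in seq_len(targetShape[1])) {
      g <- (c(i, j, k) - 0.5) * d / targetShape - 0.5  # 0-based input coord
      lo <- floor(g); fr <- g - lo
      acc <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        p <- pmin(pmax(lo + c(dx, dy, dz), 0), d - 1) + 1
        w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
        acc <- acc + w * arr[p[1], p[2], p[3]]
      }
      out[i, j, k] <- acc
    }
  out
}

# Central/one-sided finite-difference gradient magnitude.
oracleGradMag <- function(arr) {
  d <- dim(arr)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    gx <- (arr[min(i + 1, d[1]), j, k] - arr[max(i - 1, 1), j, k]) /
      (min(i + 1, d[1]) - max(i - 1, 1))
    gy <- (arr[i, min(j + 1, d[2]), k] - arr[i, max(j - 1, 1), k]) /
      (min(j + 1, d[2]) - max(j - 1, 1))
    gz <- (arr[i, j, min(k + 1, d[3])] - arr[i, j, max(k - 1, 1)]) /
      (min(k + 1, d[3]) - max(k - 1, 1))
    out[i, j, k] <- sqrt(gx^2 + gy^2 + gz^2)
  }
  out
}

# Dilation by the 3x3x3 cube as an explicit neighbourhood union.
oracleCubeDilate <- function(m) {
  d <- dim(m)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (m[i, j, k] == 0) next
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      p <- c(i + dx, j + dy, k + dz)
      if (all(p >= 1) && all(p <= d)) out[p[1], p[2], p[3]] <- 1
    }
  }
  out
}

# Per-voxel confusion tally.
oracleConfusion <- function(p, t) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0 && t[i] > 0) tp <- tp + 1
    else if (p[i] > 0) fp <- fp + 1
    else if (t[i] > 0) fn <- fn + 1
    else tn <- tn + 1
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Convolution-parameter enumeration: walks the architecture layer by layer
# and sums k^3*cin*cout + cout per convolution.
oracleParamCount <- function(nLevels, base, inCh, outCh) {
  total <- 0
  conv <- function(k, cin, cout) total <<- total + k^3 * cin * cout + cout
  ch <- base * 2^(0:(nLevels - 1))
  prev <- inCh
  for (l in 1:(nLevels - 1)) {
    conv(3, prev, ch[l]); conv(3, ch[l], ch[l]); prev <- ch[l]
  }
  conv(3, prev, ch[nLevels]); conv(3, ch[nLevels], ch[nLevels])
  for (l in (nLevels - 1):1) {
    conv(3, ch[l + 1], ch[l])       # up-convolution
    conv(3, 2 * ch[l], ch[l]); conv(3, ch[l], ch[l])
  }
  conv(1, ch[1], outCh)
  total
}

# Same-padded 3D convolution, direct index loops (single in/out channel
# pair handled per call via weight array w[3,3,3]).
oracleConv3 <- function(arr, w) {
  d <- dim(arr)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      p <- c(i + dx, j + dy, k + dz)
      if (all(p >= 1) && all(p <= d))
        acc <- acc + w[dx + 2, dy + 2, dz + 2] * arr[p[1], p[2], p[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

# 26-connectivity component count via BFS flood fill.
oracleComponentCount <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  nc <- 0L
  idx <- which(m > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    s <- idx[r, ]
    if (lab[s[1], s[2], s[3]] > 0) next
    nc <- nc + 1L
    queue <- list(s)
    lab[s[1], s[2], s[3]] <- nc
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        p <- v + c(dx, dy, dz)
        if (all(p >= 1) && all(p <= d) && m[p[1], p[2], p[3]] > 0 &&
            lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nc
          queue <- c(queue, list(p))
        }
      }
    }
  }
  nc
}

# Voxels within a Euclidean ball, counted one by one.
oracleBallCount <- function(shape, spacing, centre, radiusMm) {
  n <- 0
  for (k in seq_len(shape[3])) for (j in seq_len(shape[2]))
    for (i in seq_len(shape[1])) {
      if (sum(((c(i, j, k) - centre) * spacing)^2) <= radiusMm^2) n <- n + 1
    }
  n
}

# A quick small-grid phantom spec for unit tests (full-size defaults are
# exercised in the acceptance suite).
testSpec <- function(...) {
  phantomSpec(gridShape = c(41, 49, 41), lesionRadiusMm = c(6, 12), ...)
}

# Tiny preprocessed subject pair for training tests: a bright ellipsoidal
# blob in noise, with its support as the target.
tinyTrainingPair <- function(seed, shape = c(16, 16, 8)) {
  set.seed(seed)
  co <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                    z = seq_len(shape[3]))
  cen <- shape / 2 + runif(3, -2, 2)
  r <- c(3.5, 3.5, 2)
  m <- array(((co$x - cen[1]) / r[1])^2 + ((co$y - cen[2]) / r[2])^2 +
               ((co$z - cen[3]) / r[3])^2 <= 1, shape)
  x <- array(rnorm(prod(shape), 0, 0.3), shape) + m * 2
  list(x = x, y = m * 1)
}
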