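# Independent brute-force oracles used to validate the package's compiled
# and vectorized implementations. These are deliberately written with
# different algorithms/data structures from the package code.

# --- connected-component labeling: recursive-free flood fill on a stack ----
oracleFloodFill <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    p0 <- idx[k, ]
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    nxt <- nxt + 1L
    stack <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1L) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Two label arrays describe the same partition of the foreground.
samePartition <- function(a, b) {
  fg <- a != 0L
  if (!identical(fg, b != 0L)) return(FALSE)
  pa <- a[fg]; pb <- b[fg]
  # equal partitions iff labels are in bijection
  all(tapply(pb, pa, function(v) length(unique(v)) == 1L)) &&
    all(tapply(pa, pb, function(v) length(unique(v)) == 1L))
}

# --- Fiji-style circular median filter, plain R loops ----------------------
oracleMedianFilter <- function(vol, radius = 2L) {
  d <- dim(vol)
  out <- vol
  r2 <- radius^2 + 1
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (is.na(vol[x, y, z])) { out[x, y, z] <- NA_real_; next }
    vals <- c()
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dx * dx + dy * dy > r2) next
      xx <- x + dx; yy <- y + dy
      if (xx < 1L || yy < 1L || xx > d[1] || yy > d[2]) next
      v <- vol[xx, yy, z]
      if (!is.na(v)) vals <- c(vals, v)
    }
    out[x, y, z] <- median(vals)
  }
  out
}

# --- exhaustive Otsu: scan every cut, maximize w0*w1*(mu0-mu1)^2 ----------
oracleOtsu <- function(x, nBins = 256L, range = NULL) {
  x <- as.numeric(x)[is.finite(x)]
  if (is.null(range)) range <- base::range(x)
  edges <- seq(range[1], range[2], length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nBins)
  counts <- tabulate(bin, nBins)
  n <- sum(counts)
  vAll <- rep(-Inf, nBins - 1L)
  for (k in seq_len(nBins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * (1:k)) / n0
    mu1 <- sum(counts[(k + 1):nBins] * ((k + 1):nBins)) / n1
    vAll[k] <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
  }
  # plateau midpoint, threshold at the upper edge of the chosen bin
  bestK <- which(vAll >= max(vAll) - 1e-9 * max(abs(vAll[is.finite(vAll)])))
  k <- bestK[ceiling(length(bestK) / 2)]
  edges[k + 1L]
}

# --- exact permutation Pearson p via lexicographic next-permutation -------
oraclePermPearsonP <- function(x, y) {
  n <- length(x)
  perm <- seq_len(n)
  rObs <- cor(x, y)
  hits <- 0L; total <- 0L
  repeat {
    total <- total + 1L
    if (abs(cor(x, y[perm])) >= abs(rObs) - 1e-12) hits <- hits + 1L
    # next lexicographic permutation
    i <- n - 1L
    while (i >= 1L && perm[i] >= perm[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (perm[j] <= perm[i]) j <- j - 1L
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    perm[(i + 1L):n] <- rev(perm[(i + 1L):n])
  }
  hits / total
}

# --- shared fixtures -------------------------------------------------------

# Small, fast simulator config for unit tests (not the calibrated
# acceptance configs).
tinyConfig <- function(seed = 1L, ...) {
  exampleSessionConfig("immature", rngSeed = seed, nInitialPuncta = 8L, ...)
}

randomSparseMask <- function(dim = c(12L, 12L, 6L), pFg = 0.08) {
  array(runif(prod(dim)) < pFg, dim)
}
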