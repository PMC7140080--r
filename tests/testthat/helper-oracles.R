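# Independent oracles used across the suite. Each re-derives a quantity by
# brute force, enumeration or closed form, never by calling the package
# code path it checks.

# exhaustive Otsu: for every candidate threshold, split the data and
# compute the between-class variance from the raw values directly
oracle_otsu_8bit <- function(v) {
  v <- as.numeric(v)
  best_t <- NA_real_; best_var <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var + 1e-12) { best_var <- bc; best_t <- t }
  }
  best_t
}

# brute-force 3D flood fill (26- or 6-connectivity) over an explicit
# neighbour scan; quadratic-ish but fine for <= 20^3 fixtures
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  if (connectivity == 6)
    nb <- nb[abs(nb$dz) + abs(nb$dy) + abs(nb$dx) == 1, ]
  cur <- 0L
  for (i in which(mask != 0)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (j in seq_len(nrow(nb))) {
        z <- co[1] + nb$dz[j]; y <- co[2] + nb$dy[j]; x <- co[3] + nb$dx[j]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3])
          next
        if (mask[z, y, x] != 0 && lab[z, y, x] == 0L) {
          lab[z, y, x] <- cur
          queue <- c(queue, z + (y - 1) * d[1] + (x - 1) * d[1] * d[2])
        }
      }
    }
  }
  lab
}

# exact hypergeometric upper tail by literal subset enumeration (N <= 12)
oracle_hyper_enum <- function(N, K, n, k) {
  hits <- 0; tot <- 0
  for (s in utils::combn(N, n, simplify = FALSE)) {
    tot <- tot + 1
    if (sum(s <= K) >= k) hits <- hits + 1   # genes 1..K form the set
  }
  hits / tot
}

# exact hypergeometric upper tail by the explicit choose() sum
oracle_hyper_choose <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (k > min(n, K)) return(0)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exact two-sided rank-sum p by bitmask enumeration of group assignments
# (independent of the combn-based path in the package); n <= 12
oracle_ranksum_enum <- function(x, y) {
  na <- length(x); n <- na + length(y)
  stopifnot(n <= 12)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  hits <- 0L; tot <- 0L
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s)[1:n])
    if (sum(bits) != na) next
    tot <- tot + 1L
    w <- sum(r[bits == 1L])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / tot
}

# small random 8-bit test volume
random_stack_array <- function(dims, seed) {
  withr::with_seed(seed, array(sample(0:255, prod(dims), replace = TRUE),
                               dims))
}
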