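# Independent oracles used to verify the package implementations.
# These deliberately use naive algorithms (set arithmetic, brute-force
# neighbour scans, O(n^2) pairwise distances, full 2^n enumeration).

# Dice via set arithmetic on coordinate strings
oracle_dice <- function(p, g) {
  ps <- which(p)
  gs <- which(g)
  if (length(ps) + length(gs) == 0L) return(0)
  2 * length(intersect(ps, gs)) / (length(ps) + length(gs))
}

# boundary voxels by exhaustive 6-neighbour scan
oracle_boundary <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in nb) {
      outside <- any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]
      if (outside || !m[q[1], q[2], q[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

# NSD by brute-force pairwise squared distances between boundary centres
oracle_nsd <- function(p, g, spacing, tol) {
  bp <- which(oracle_boundary(p), arr.ind = TRUE)
  bg <- which(oracle_boundary(g), arr.ind = TRUE)
  if (nrow(bp) == 0L || nrow(bg) == 0L) return(0)
  P <- sweep(bp, 2, spacing, `*`)
  G <- sweep(bg, 2, spacing, `*`)
  min_d2 <- function(A, B) {
    o <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2 +
      outer(A[, 3], B[, 3], `-`)^2
    apply(o, 1, min)
  }
  (sum(min_d2(P, G) <= tol^2) + sum(min_d2(G, P) <= tol^2)) /
    (nrow(bp) + nrow(bg))
}

# one-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  mean(ws >= w_obs)
}

# Kendall's tau-b by exhaustive pair counting
oracle_tau_b <- function(a, b) {
  n <- length(a)
  C <- D <- Ta <- Tb <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sa <- sign(a[i] - a[j])
    sb <- sign(b[i] - b[j])
    if (sa == 0) Ta <- Ta + 1L
    if (sb == 0) Tb <- Tb + 1L
    if (sa != 0 && sb != 0) {
      if (sa == sb) C <- C + 1L else D <- D + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - Ta) * (n0 - Tb))
}

# random blobby mask (union of random ellipsoids, optional sparse noise)
random_mask <- function(shape = c(12, 12, 12), n_blobs = sample(0:3, 1),
                        noise = 0.01) {
  m <- array(FALSE, shape)
  for (i in seq_len(n_blobs)) {
    c0 <- runif(3, 2, shape - 1)
    r <- runif(3, 1.2, shape / 3)
    x <- (seq_len(shape[1]) - c0[1]) / r[1]
    y <- (seq_len(shape[2]) - c0[2]) / r[2]
    z <- (seq_len(shape[3]) - c0[3]) / r[3]
    m <- m | (outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1)
  }
  if (noise > 0) m <- xor(m, array(runif(prod(shape)) < noise, shape))
  m
}

# metric table from a per-case value matrix (cases x teams), both metrics
# getting the same values unless nsd_values is supplied
table_from_matrix <- function(m, task = "T1", roi = "organ",
                              nsd_values = m) {
  stopifnot(!is.null(colnames(m)))
  cases <- sprintf("case%02d", seq_len(nrow(m)))
  rows <- list()
  for (t in colnames(m)) {
    rows[[length(rows) + 1L]] <- data.frame(
      team = t, task = task, case = rep(cases, 2), roi = roi,
      metric = rep(c("DSC", "NSD"), each = nrow(m)),
      value = c(m[, t], nsd_values[, t]), stringsAsFactors = FALSE)
  }
  metric_table(do.call(rbind, rows))
}

# dominance cohort: team j's value on every case strictly exceeds team j+1's
dominance_table <- function(n_teams = 3, n_cases = 8, task = "T1",
                            seed = 99) {
  teams <- sprintf("team%02d", seq_len(n_teams))
  set.seed(seed)
  base <- matrix(runif(n_cases, 0.01, 0.1), n_cases, n_teams)
  off <- matrix(rep((n_teams:1) * 0.8 / n_teams, each = n_cases),
                n_cases, n_teams)
  m <- base + off  # values in (0,1), strict ordering per case
  colnames(m) <- teams
  table_from_matrix(m, task = task)
}
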