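# Fixture builders and independent brute-force oracles shared across tests.

# noiseless, blur-free phantom spec (CSF at 50% of cord unless overridden)
noiselessSpec <- function(...) {
  phantomSpec(psfSigma = 0, noiseSd = 0, ...)
}

# points sampled exactly on an ellipse (theta = major-axis angle from x)
ellipsePoints <- function(a, b, theta = 0, cx = 0, cy = 0, n = 36) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(t); y0 <- b * sin(t)
  cbind(cx + x0 * cos(theta) - y0 * sin(theta),
        cy + x0 * sin(theta) + y0 * cos(theta))
}

# support-function width of a point cloud along direction phi
bruteWidth <- function(pts, phi) {
  proj <- pts[, 1] * cos(phi) + pts[, 2] * sin(phi)
  max(proj) - min(proj)
}

# Spearman rho by the rank-difference formula (tie-free inputs)
bruteSpearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exact permutation p-value for Spearman rho (small tie-free n)
bruteSpearmanP <- function(x, y) {
  n <- length(x)
  perms <- gtoolsPerms(n)
  obs <- abs(bruteSpearman(x, y))
  stat <- apply(perms, 1, function(pr) abs(bruteSpearman(x, y[pr])))
  mean(stat >= obs - 1e-12)
}

# all permutations of 1..n (tiny n only)
gtoolsPerms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtoolsPerms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Kruskal-Wallis H with tie correction, from the rank formula
bruteKW <- function(groups) {
  vals <- unlist(groups)
  r <- rank(vals)
  n <- length(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(vals)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Mann-Whitney U of x vs y (number of (x, y) pairs with y < x, ties 1/2)
bruteU <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact two-sided MWU p-value by enumerating all group assignments
# (tie-free pooled data; mirrors the symmetric-distribution doubling rule)
bruteMWUP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u <- apply(idx, 2, function(ii) bruteU(pooled[ii], pooled[-ii]))
  uobs <- bruteU(x, y)
  lo <- min(uobs, n1 * length(y) - uobs)
  min(1, 2 * mean(u <= lo))
}
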