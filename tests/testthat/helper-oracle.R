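# Independent brute-force oracle for the permutation tests.
#
# Everything here is written from the definitions with plain loops and its
# own permutation enumeration, deliberately sharing no code with the
# package's vectorized engine, so the two can be compared exactly on small
# problems.

# all n! orderings of 1..n, by simple recursion
oracle_orderings <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- oracle_orderings(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      rest <- seq_len(n)[-i]
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

# score components by plain summation
oracle_scores <- function(G, y, kind) {
  n <- nrow(G); p <- ncol(G)
  ybar <- mean(y)
  s1 <- 0; u <- numeric(p); tr <- 0
  for (i in seq_len(n)) {
    ci <- 0
    for (j in seq_len(p)) {
      ci <- ci + G[i, j]
      u[j] <- u[j] + G[i, j] * (y[i] - ybar)
      tr <- tr + G[i, j]^2
    }
    s1 <- s1 + ci * (y[i] - ybar)
  }
  if (kind == "continuous") {
    v <- sum((y - ybar)^2) / (n - 1)
    # divide by the (permutation-constant) variance once, after the integer
    # sums, so orderings with mathematically equal statistics stay exactly
    # tied in floating point
    s2 <- 0.5 * sum(u^2) / v^2 - tr / (2 * v)
    s1 <- s1 / v
    u <- u / v
  } else {
    s2 <- 0.5 * sum(u^2) - 0.5 * ybar * (1 - ybar) * tr
  }
  list(s1 = s1, s2 = s2, u = u)
}

# exhaustive-permutation p-values for all tests, from the definitions
oracle_pvalues <- function(G, y, kind) {
  perms <- oracle_orderings(length(y))
  B <- length(perms)
  obs <- oracle_scores(G, y, kind)
  a1 <- numeric(B); s2v <- numeric(B)
  for (b in seq_len(B)) {
    sc <- oracle_scores(G, y[perms[[b]]], kind)
    a1[b] <- abs(sc$s1)
    s2v[b] <- sc$s2
  }
  count_ge <- function(v, x) { k <- 0L; for (w in v) if (w >= x) k <- k + 1L; k }
  count_le <- function(v, x) { k <- 0L; for (w in v) if (w <= x) k <- k + 1L; k }

  p1 <- (count_ge(a1, abs(obs$s1)) + 1) / (B + 1)
  p2 <- (count_ge(s2v, obs$s2) + 1) / (B + 1)

  # pseudo component p-values per permutation: rank within the pool
  p1b <- numeric(B); p2b <- numeric(B)
  for (b in seq_len(B)) {
    p1b[b] <- count_ge(a1, a1[b]) / B
    p2b[b] <- count_ge(s2v, s2v[b]) / B
  }
  fish <- -2 * log(p1b) - 2 * log(p2b)
  fish_obs <- -2 * log(p1) - 2 * log(p2)
  minp <- pmin(p1b, p2b)
  minp_obs <- min(p1, p2)

  m1 <- mean(a1); sd1 <- sqrt(sum((a1 - m1)^2) / (B - 1))
  m2 <- mean(s2v); sd2 <- sqrt(sum((s2v - m2)^2) / (B - 1))
  z <- function(v, m, s) if (s > 0) (v - m) / s else v * 0
  joint <- z(a1, m1, sd1) + z(s2v, m2, sd2)
  joint_obs <- z(abs(obs$s1), m1, sd1) + z(obs$s2, m2, sd2)

  # burden: one-sided upper p of the squared statistic
  burden_stat <- function(yy) {
    ci <- rowSums(G)
    s <- sum(ci * (yy - mean(yy)))^2
    if (kind == "continuous") s / (sum((yy - mean(yy))^2) / (length(yy) - 1)) else s
  }
  bobs <- burden_stat(y)
  bperm <- vapply(perms, function(pm) burden_stat(y[pm]), numeric(1))

  c(
    burden = (count_ge(bperm, bobs) + 1) / (B + 1),
    fisher = (count_ge(fish, fish_obs) + 1) / (B + 1),
    minp = (count_le(minp, minp_obs) + 1) / (B + 1),
    joint = (count_ge(joint, joint_obs) + 1) / (B + 1),
    p1 = p1,
    p2 = p2
  )
}

# small deterministic genotype matrix for fixture use; columns are
# polymorphic and already minor-allele oriented (frequency <= 0.5), so the
# matrix passes through preprocessing unchanged
fixture_genotypes <- function(n, p, seed = 7, maf = 0.2) {
  set.seed(seed)
  repeat {
    G <- matrix(rbinom(n * p, 2, maf), nrow = n)
    cs <- colSums(G)
    if (all(cs > 0) && all(cs <= n)) return(G)
  }
}
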