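# Independent oracles, deliberately coded along different routes than the
# package implementation.

# Minimal RMSD after superposition via Horn's quaternion characteristic
# polynomial: rmsd = sqrt((Gp + Gq - 2 * lambda_max) / N) where lambda_max
# is the top eigenvalue of the 4x4 key matrix. No rotation matrix, no SVD.
quat_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  gp <- sum(p^2)
  gq <- sum(q^2)
  m <- crossprod(p, q)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, gp + gq - 2 * lambda) / nrow(mobile))
}

# H-bond evaluator using the law of cosines on the three pair distances
# (no vectors, no dot products).
brute_hbond <- function(frame, donor, hydrogen, acceptor,
                        angle_cutoff_deg = 30, dist_cutoff = 3.6) {
  d <- frame[donor + 1, ]; h <- frame[hydrogen + 1, ]; a <- frame[acceptor + 1, ]
  dist <- function(u, v) sqrt(sum((u - v)^2))
  dda <- dist(d, a)
  if (dda > dist_cutoff) return(FALSE)
  ddh <- dist(d, h)
  dha <- dist(h, a)
  cosang <- (ddh^2 + dda^2 - dha^2) / (2 * ddh * dda)
  acos(min(1, max(-1, cosang))) * 180 / pi <= angle_cutoff_deg
}

# Exhaustive pairwise-minimum salt-bridge evaluator.
brute_ionic <- function(frame, carbons_a, carbons_b, cutoff = 5) {
  best <- Inf
  for (i in carbons_a) {
    for (j in carbons_b) {
      best <- min(best, sqrt(sum((frame[i + 1, ] - frame[j + 1, ])^2)))
    }
  }
  best < cutoff
}

# Exhaustive steepest-ascent basin assignment on a network given node
# populations and an undirected adjacency matrix: from each node walk to
# the highest-population closed-neighbourhood member (ties: self first,
# then lexicographically smallest name) until stationary.
brute_basins <- function(pop, adj) {
  codes <- names(pop)
  dest <- function(u) {
    repeat {
      nb <- codes[adj[u, ] > 0]
      if (length(nb) == 0) return(u)
      best_pop <- max(pop[nb])
      if (pop[u] >= best_pop) return(u)
      cand <- sort(nb[pop[nb] == best_pop])
      u <- cand[1]
    }
  }
  vapply(codes, dest, character(1))
}

# One-sided (over-representation) hypergeometric tail by direct enumeration
# with choose(); a = class-in-loop count, margins (r1 = class total,
# r2 = other total, c1 = loop total).
hyper_tail <- function(a, r1, r2, c1) {
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pmf <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  sum(pmf[ks >= a])
}

# Random rigid transform applied to an N x 3 coordinate block.
random_rigid <- function(xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  t_vec <- stats::rnorm(3, sd = 5)
  sweep(xyz %*% t(r), 2, t_vec, `+`)
}
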