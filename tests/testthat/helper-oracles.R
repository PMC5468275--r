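# Independent oracles used across the suite.  These deliberately take the
# slow, transparent route (exhaustive enumeration, dense weighted least
# squares, rotation grid search) so they share no code with the
# implementations they check.

# Minimax barrier by exhaustive enumeration of simple grid paths, with the
# sound pruning that a running maximum >= the incumbent cannot improve.
enumMinimaxOptimum <- function(val, s, e, connectivity = 4L) {
  nr <- nrow(val); nc <- ncol(val)
  off <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  rec <- function(i, j, cur) {
    cur <- max(cur, val[i, j])
    if (i == e[1] && j == e[2]) { best <<- min(best, cur); return(invisible()) }
    if (cur >= best) return(invisible())
    visited[i, j] <<- TRUE
    for (o in off) {
      ni <- i + o[1]; nj <- j + o[2]
      if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
          !visited[ni, nj] && is.finite(val[ni, nj]))
        rec(ni, nj, cur)
    }
    visited[i, j] <<- FALSE
  }
  rec(s[1], s[2], -Inf)
  best
}

# Dense local weighted least squares with tri-cube weights over the
# span-nearest neighbours (Cleveland's definition), 1D or 2D predictors.
bruteLocalRegression <- function(x, y, span, degree) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(x)
  q <- floor(n * span)
  vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
    dq <- sort(d)[q]
    w <- (1 - pmin(d / dq, 1)^3)^3
    dx <- sweep(x, 2, x[i, ])
    X <- matrix(1, n, 1)
    for (p in seq_len(degree)) {
      X <- cbind(X, dx^p)
      if (ncol(x) == 2L && p == 2L) X <- cbind(X, dx[, 1] * dx[, 2])
    }
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    beta[1]
  }, numeric(1))
}

# RMSD after best rigid superposition, by brute-force search over rotation
# space (Euler-angle grid + Nelder-Mead refinement); no reflections.
bruteSuperposeRmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((mc %*% t(rotmat(ang)) - rc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; bestAng <- c(0, 0, 0)
  for (a in grid) for (b in seq(0, pi, length.out = 7)) for (g in grid) {
    v <- obj(c(a, b, g))
    if (v < best) { best <- v; bestAng <- c(a, b, g) }
  }
  opt <- optim(bestAng, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Mueller-Brown global minimum by dense grid search + local refinement,
# straight from the analytic four-Gaussian form (no package code).
bruteMuellerBrownMinimum <- function() {
  A <- c(-200, -100, -170, 15); a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6); cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1); y0 <- c(0, 0.5, 1.5, 1)
  U <- function(p) sum(A * exp(a * (p[1] - x0)^2 + b * (p[1] - x0) * (p[2] - y0) +
                                 cc * (p[2] - y0)^2))
  g <- expand.grid(x = seq(-2, 1.5, by = 0.02), y = seq(-0.5, 2.5, by = 0.02))
  e <- apply(g, 1, U)
  opt <- optim(as.numeric(g[which.min(e), ]), U, method = "BFGS",
               control = list(reltol = 1e-14))
  list(x = opt$par, energy = opt$value)
}

# random rigid motion (rotation with det +1, plus translation)
randomRigidMotion <- function(pts, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(pts %*% q, 2, rnorm(3, sd = 5), "+")
}
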