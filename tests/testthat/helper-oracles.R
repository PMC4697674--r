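# Independent brute-force oracles: plain nested loops, no shared code with
# the package internals.  Deliberately slow and literal.

# replicate-padded pixel fetch
.oget <- function(x, i, j) {
  x[min(max(i, 1L), nrow(x)), min(max(j, 1L), ncol(x))]
}

# Per-pixel loop evaluation of the regularizer chain on a 2-D matrix:
# local mean, LVC, zeta/omega, phi, and the weighted image.
oracle_regularizer <- function(x, w = 3L) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  n_r <- w * w
  xbar <- lvc <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -h:h) for (dj in -h:h) vals <- c(vals, .oget(x, i + di, j + dj))
    xbar[i, j] <- mean(vals)
    lvc[i, j] <- if (xbar[i, j] == 0) 0 else
      sum((vals - xbar[i, j])^2) / (n_r * xbar[i, j]^2)
  }
  zeta <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -h:h) for (dj in -h:h)
      if (!(di == 0 && dj == 0)) s <- s + .oget(lvc, i + di, j + dj)
    zeta[i, j] <- exp(s)
  }
  omega <- phi <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    denom <- 0
    for (di in -h:h) for (dj in -h:h)
      denom <- denom + .oget(zeta, i + di, j + dj)
    omega[i, j] <- zeta[i, j] / denom
    phi[i, j] <- if (xbar[i, j] < x[i, j]) 2 + omega[i, j] else
      if (xbar[i, j] > x[i, j]) 2 - omega[i, j] else 0
  }
  phi_max <- max(phi)
  xi <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -h:h) for (dj in -h:h)
      if (!(di == 0 && dj == 0)) s <- s + .oget(x, i + di, j + dj)
    xi[i, j] <- (x[i, j] + (1 + phi_max) / (n_r - 1) * s) / (2 + phi_max)
  }
  list(xbar = xbar, lvc = lvc, omega = omega, phi = phi, xi = xi,
       phi_max = phi_max)
}

# Nested-loop Gaussian-kernel fuzzy C-means on a grayscale vector, using the
# same initialization and stopping conventions as the package but coded
# independently with explicit loops.
oracle_kfcm <- function(x, c_, m = 2, sigma, eps = 0.001, max_iter = 100L) {
  n <- length(x)
  v <- numeric(c_)
  for (j in seq_len(c_))
    v[j] <- min(x) + (2 * j - 1) / (2 * c_) * (max(x) - min(x))
  kern <- function(a, b) exp(-(a - b)^2 / (2 * sigma^2))
  memb <- function(v) {
    u <- matrix(0, n, c_)
    for (i in seq_len(n)) {
      d <- numeric(c_)
      for (j in seq_len(c_)) d[j] <- 1 - kern(x[i], v[j])
      if (any(d == 0)) {
        for (j in seq_len(c_)) u[i, j] <- (d[j] == 0) / sum(d == 0)
      } else {
        for (j in seq_len(c_)) {
          s <- 0
          for (k in seq_len(c_)) s <- s + (d[j] / d[k])^(1 / (m - 1))
          u[i, j] <- 1 / s
        }
      }
    }
    u
  }
  u <- memb(v)
  for (t in seq_len(max_iter)) {
    v_new <- numeric(c_)
    for (j in seq_len(c_)) {
      num <- 0; den <- 0
      for (i in seq_len(n)) {
        kij <- kern(x[i], v[j])
        num <- num + u[i, j]^m * kij * x[i]
        den <- den + u[i, j]^m * kij
      }
      v_new[j] <- num / den
    }
    v <- v_new
    u_new <- memb(v)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < eps) break
  }
  list(u = u, v = v)
}

# Literal double-loop evaluation of the regularized kernel objective.
oracle_objective <- function(x, xb, phi, u, v, m, sigma) {
  j_total <- 0
  for (i in seq_along(x)) for (j in seq_along(v)) {
    k1 <- exp(-(x[i] - v[j])^2 / (2 * sigma^2))
    k2 <- exp(-(xb[i] - v[j])^2 / (2 * sigma^2))
    j_total <- j_total + 2 * u[i, j]^m * (1 - k1) +
      phi[i] * u[i, j]^m * (1 - k2)
  }
  j_total
}

# Literal center update of the regularized kernel method.
oracle_centers <- function(x, xb, phi, u, v, m, sigma) {
  v_new <- numeric(length(v))
  for (j in seq_along(v)) {
    num <- 0; den <- 0
    for (i in seq_along(x)) {
      k1 <- exp(-(x[i] - v[j])^2 / (2 * sigma^2))
      k2 <- exp(-(xb[i] - v[j])^2 / (2 * sigma^2))
      num <- num + u[i, j]^m * (k1 * x[i] + phi[i] * k2 * xb[i])
      den <- den + u[i, j]^m * (k1 + phi[i] * k2)
    }
    v_new[j] <- num / den
  }
  v_new
}

# Histogram-based entropy measure computed with explicit loops over regions
# and grayscale values (integer-valued images).
oracle_entropy <- function(x, labels, background = 0L) {
  keep <- labels != background
  vals <- x[keep]; regs <- labels[keep]
  s_i <- sum(keep)
  e_region <- 0; e_layout <- 0
  for (j in unique(regs)) {
    vj <- vals[regs == j]
    s_j <- length(vj)
    h <- 0
    for (g in unique(vj)) {
      p <- sum(vj == g) / s_j
      h <- h - p * log(p)
    }
    e_region <- e_region + (s_j / s_i) * h
    e_layout <- e_layout - (s_j / s_i) * log(s_j / s_i)
  }
  e_region + e_layout
}

# Small random test image (non-negative, irregular values).
random_image <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc, 0, 200), nr, nc)
}
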