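# Independent oracles used across the suite. These deliberately avoid the
# package's own differentiation/integration code paths.

# Menger curvature: curvature of the circle through three consecutive points,
# kappa = 4 * area(triangle) / (|ab| |bc| |ca|). Derivative-free.
menger_kappa <- function(m) {
  n <- nrow(m)
  vapply(2:(n - 1), function(i) {
    a <- m[i - 1, ]; b <- m[i, ]; c <- m[i + 1, ]
    ab <- b - a; bc <- c - b; ca <- a - c
    cr <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    area2 <- sqrt(sum(cr^2))  # 2 * triangle area
    2 * area2 / (sqrt(sum(ab^2)) * sqrt(sum(bc^2)) * sqrt(sum(ca^2)))
  }, numeric(1))
}

# Closed-form OLS via the normal equations (solve(t(X) %*% X), not lm).
ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  n <- nrow(X); p <- ncol(X); k <- p - 1
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  f <- ((tss - rss) / k) / (rss / (n - k - 1))
  list(beta = as.numeric(beta), r2 = r2, adj_r2 = adj,
       p = stats::pf(f, k, n - k - 1, lower.tail = FALSE))
}

# Direct-moment skewness/kurtosis with the adjusted (bias-corrected)
# factors, written from the textbook formulas.
skew_oracle <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

kurt_oracle <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

# A semicircle of radius r continued tangentially by a straight tail,
# sampled at exactly uniform arc-length spacing across the junction.
semicircle_with_tail <- function(r = 1, tail = pi, spacing = 0.01) {
  L <- pi * r + tail
  s <- seq(0, L, by = spacing)
  on_arc <- s <= pi * r
  th <- s[on_arc] / r
  m_arc <- cbind(r * sin(th), r * (1 - cos(th)), 0)
  st <- s[!on_arc] - pi * r
  # tangent at the arc end (theta = pi) is (-1, 0, 0)
  m_tail <- cbind(0 - st, 2 * r, 0)
  cl <- centerline(rbind(m_arc, m_tail))
  attr(cl, "spacing") <- spacing
  cl
}

# Inject a synthetic curvature profile (bypasses geometry entirely).
fake_profile <- function(s, kappa) {
  p <- tibble::tibble(s = s, kappa = kappa)
  attr(p, "spacing") <- s[2] - s[1]
  class(p) <- c("tortuometry_curvature_profile", class(p))
  p
}

# independent central-difference derivative on an arbitrary grid
fd_first_oracle <- function(y, s) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (s[2] - s[1])
  d[n] <- (y[n] - y[n - 1]) / (s[n] - s[n - 1])
  d
}

scale_centerline <- function(cl, lambda) {
  out <- centerline(as_matrix_xyz(cl) * lambda, label = branch_label(cl))
  attr(out, "spacing") <- NULL
  out
}

as_matrix_xyz <- function(cl) cbind(cl$x, cl$y, cl$z)

rotate_translate <- function(cl, axis = c(1, 2, 2), angle = 0.7,
                             shift = c(5, -3, 2)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  m <- as_matrix_xyz(cl) %*% t(R)
  out <- centerline(sweep(m, 2, shift, "+"), label = branch_label(cl))
  attr(out, "spacing") <- attr(cl, "spacing", exact = TRUE)
  out
}

# 1-to-4 uniform triangle subdivision; each child keeps its parent's
# per-triangle field value and mask.
subdivide_surface <- function(s) {
  stopifnot(s$tawss_on == "triangle")
  v <- s$vertices
  tris <- s$triangles
  new_v <- list(v)
  new_t <- list()
  new_val <- numeric(0)
  new_mask <- logical(0)
  off <- nrow(v)
  for (i in seq_len(nrow(tris))) {
    a <- v[tris[i, 1], ]; b <- v[tris[i, 2], ]; c <- v[tris[i, 3], ]
    mids <- rbind((a + b) / 2, (b + c) / 2, (c + a) / 2)
    new_v[[i + 1]] <- mids
    ab <- off + 1L; bc <- off + 2L; ca <- off + 3L
    off <- off + 3L
    new_t[[i]] <- rbind(c(tris[i, 1], ab, ca), c(ab, tris[i, 2], bc),
                        c(ca, bc, tris[i, 3]), c(ab, bc, ca))
    new_val <- c(new_val, rep(s$tawss[i], 4))
    new_mask <- c(new_mask, rep(s$region_mask[i], 4))
  }
  suppressWarnings(surface_field(do.call(rbind, new_v), do.call(rbind, new_t),
                                 new_val, region_mask = new_mask))
}
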