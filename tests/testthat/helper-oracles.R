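# Independent numerical oracles used by the tests. These deliberately avoid
# the package's analytic formulas.

# Brute-force finite-difference solve of the depth-averaged stream function
# around the disk: Laplace's equation on a square [-L, L]^2 (L in obstacle
# radii), psi = U*x (uniform stream along -y) on the outer boundary, psi = 0
# on the disk. Five-point stencil, sparse direct solve. Returns grid
# coordinates and central-difference velocities.
laplace_streamfunction_oracle <- function(model, L_radii = 12, n = 161) {
  a <- model$radius
  U <- model$U
  L <- L_radii * a
  xs <- seq(-L, L, length.out = n)
  h <- xs[2] - xs[1]
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  idx <- matrix(seq_len(n * n), n, n)
  fixed <- R <= a | X == -L | X == L | Y == -L | Y == L
  psi <- U * X
  psi[R <= a] <- 0
  free <- which(!fixed)
  nf <- length(free)
  pos <- integer(n * n)
  pos[free] <- seq_len(nf)
  neigh <- cbind(free - 1, free + 1, free - n, free + n)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  b <- numeric(nf)
  for (k in 1:4) {
    nb <- neigh[, k]
    is_free <- !fixed[nb]
    rows <- c(rows, seq_len(nf)[is_free])
    cols <- c(cols, pos[nb[is_free]])
    vals <- c(vals, rep(1, sum(is_free)))
    b <- b - ifelse(is_free, 0, psi[nb])
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(nf), rows),
                            j = c(seq_len(nf), cols),
                            x = c(rep(-4, nf), vals), dims = c(nf, nf))
  sol <- Matrix::solve(A, b)
  psi[free] <- as.numeric(sol)
  # central differences: u = dpsi/dy, v = -dpsi/dx
  interior <- 2:(n - 1)
  u <- (psi[interior, interior + 1] - psi[interior, interior - 1]) / (2 * h)
  v <- -(psi[interior + 1, interior] - psi[interior - 1, interior]) / (2 * h)
  list(x = X[interior, interior], y = Y[interior, interior],
       r = R[interior, interior], u = u, v = v, h = h)
}

# finite-difference velocity gradient of the model's velocity field
fd_velocity_gradient <- function(point, model, h = 0.5) {
  cols <- lapply(1:2, function(i) {
    d <- c(0, 0); d[i] <- h
    va <- flow_velocity(tibble::tibble(x = point[1] + d[1],
                                       y = point[2] + d[2]), model)
    vb <- flow_velocity(tibble::tibble(x = point[1] - d[1],
                                       y = point[2] - d[2]), model)
    c((va$vx - vb$vx) / (2 * h), (va$vy - vb$vy) / (2 * h))
  })
  cbind(cols[[1]], cols[[2]])
}
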