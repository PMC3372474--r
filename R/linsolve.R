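# Preconditioned Krylov solvers for the two sparse systems the scheme
# produces: CG for the symmetric positive-definite pressure-correction
# matrix (preconditioned by a cached CHOLMOD supernodal Cholesky factor)
# and BiCGSTAB for the upwind advection-diffusion energy matrix
# (preconditioned by a wavefront-vectorised DILU factorisation, which
# respects the one-way character of upwind advection).

chol_factor <- function(Msym) {
  Cholesky(Msym, LDL = FALSE, perm = TRUE, super = TRUE)
}

# dense numeric vector from a Matrix result (dgeMatrix or plain numeric)
dvec <- function(m) if (is.numeric(m)) m else m@x

chol_psolve <- function(fac) function(r) dvec(solve(fac, r))

# Conjugate gradients for SPD M; `psolve` applies the preconditioner.
pcg_solve <- function(M, b, psolve, x0 = NULL, rtol = 1e-12,
                      atol = 1e-300, maxit = 60L) {
  nb <- sqrt(sum(b^2))
  if (nb < atol) return(list(x = numeric(length(b)), its = 0L, rel = 0))
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - dvec(M %*% x)
  z <- psolve(r)
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- dvec(M %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / nb
    if (rel < rtol) return(list(x = x, its = it, rel = rel))
    z <- psolve(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, its = maxit, rel = sqrt(sum(r^2)) / nb)
}

# Preconditioned BiCGSTAB.
bicgstab_solve <- function(M, b, psolve, x0 = NULL, rtol = 1e-11,
                           atol = 1e-300, maxit = 500L) {
  nb <- sqrt(sum(b^2))
  if (nb < atol) return(list(x = numeric(length(b)), its = 0L, rel = 0))
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - dvec(M %*% x)
  rel <- sqrt(sum(r^2)) / nb
  if (rel < rtol) return(list(x = x, its = 0L, rel = rel))
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(length(b))
  for (it in seq_len(maxit)) {
    rho_new <- sum(r0 * r)
    if (abs(rho_new) < 1e-290) { r0 <- r; rho_new <- sum(r0 * r) }
    beta <- (rho_new / rho) * (alpha / omega)
    rho <- rho_new
    p <- r + beta * (p - omega * v)
    phat <- psolve(p)
    v <- dvec(M %*% phat)
    alpha <- rho / sum(r0 * v)
    s <- r - alpha * v
    if (sqrt(sum(s^2)) / nb < rtol) {
      x <- x + alpha * phat
      return(list(x = x, its = it, rel = sqrt(sum(s^2)) / nb))
    }
    shat <- psolve(s)
    t <- dvec(M %*% shat)
    omega <- sum(t * s) / sum(t * t)
    x <- x + alpha * phat + omega * shat
    r <- s - omega * t
    rel <- sqrt(sum(r^2)) / nb
    if (rel < rtol) return(list(x = x, its = it, rel = rel))
  }
  warning(sprintf("BiCGSTAB stopped at %d iterations, residual %.2e",
                  maxit, rel))
  list(x = x, its = maxit, rel = rel)
}

# ---------------------------------------------------------------------------
# DILU preconditioner for the 7-point stencil, vectorised over the
# i+j+k wavefront hyperplanes of the structured grid (every lower
# neighbour of a plane lies in an earlier plane, so each plane updates
# as one vector operation).

# Static structure: lower-neighbour index maps and the plane partition.
dilu_structure <- function(nx, ny, nz) {
  ncell <- nx * ny * nz
  ijk <- arrayInd(seq_len(ncell), c(nx, ny, nz))
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  idx <- function(ii, jj, kk, ok) ifelse(ok, ii + nx * (jj - 1L) +
                                           nx * ny * (kk - 1L), 0L)
  h <- i + j + k
  str <- list(
    idxW = idx(i - 1L, j, k, i > 1L),
    idxS = idx(i, j - 1L, k, j > 1L),
    idxB = idx(i, j, k - 1L, k > 1L),
    planes = split(seq_len(ncell), h)
  )
  attr(str, "nx") <- nx
  attr(str, "nxny") <- nx * ny
  str
}

# Stencil: list with diag and the six off-diagonal coefficient vectors
# (uE, uN, uT: upper neighbours; lW, lS, lB: lower neighbours), 0 where
# the neighbour does not exist.
dilu_factor <- function(stencil, str) {
  d <- stencil$diag
  uE <- stencil$uE; uN <- stencil$uN; uT <- stencil$uT
  lW <- stencil$lW; lS <- stencil$lS; lB <- stencil$lB
  idxW <- str$idxW; idxS <- str$idxS; idxB <- str$idxB
  for (cells in str$planes) {
    acc <- numeric(length(cells))
    w <- idxW[cells]; ok <- w > 0L
    acc[ok] <- acc[ok] + lW[cells[ok]] * uE[w[ok]] / d[w[ok]]
    s <- idxS[cells]; ok <- s > 0L
    acc[ok] <- acc[ok] + lS[cells[ok]] * uN[s[ok]] / d[s[ok]]
    b <- idxB[cells]; ok <- b > 0L
    acc[ok] <- acc[ok] + lB[cells[ok]] * uT[b[ok]] / d[b[ok]]
    d[cells] <- d[cells] - acc
  }
  d
}

# Apply z = M_DILU^{-1} r with M = (D~ + L) D~^{-1} (D~ + U).
dilu_psolve <- function(stencil, d, str) {
  uE <- stencil$uE; uN <- stencil$uN; uT <- stencil$uT
  lW <- stencil$lW; lS <- stencil$lS; lB <- stencil$lB
  idxW <- str$idxW; idxS <- str$idxS; idxB <- str$idxB
  planes <- str$planes
  np <- length(planes)
  function(r) {
    y <- numeric(length(r))
    for (pi in seq_len(np)) {
      cells <- planes[[pi]]
      acc <- r[cells]
      w <- idxW[cells]; ok <- w > 0L
      acc[ok] <- acc[ok] - lW[cells[ok]] * y[w[ok]]
      s <- idxS[cells]; ok <- s > 0L
      acc[ok] <- acc[ok] - lS[cells[ok]] * y[s[ok]]
      b <- idxB[cells]; ok <- b > 0L
      acc[ok] <- acc[ok] - lB[cells[ok]] * y[b[ok]]
      y[cells] <- acc / d[cells]
    }
    z <- y
    for (pi in rev(seq_len(np))) {
      cells <- planes[[pi]]
      # upper neighbours live in later planes; gather their z values
      acc <- numeric(length(cells))
      ii <- cells + 1L           # East neighbour index when uE != 0
      ok <- stencil$uE[cells] != 0
      acc[ok] <- acc[ok] + uE[cells[ok]] * z[ii[ok]]
      jj <- cells + attr(str, "nx")
      ok <- stencil$uN[cells] != 0
      acc[ok] <- acc[ok] + uN[cells[ok]] * z[jj[ok]]
      kk <- cells + attr(str, "nxny")
      ok <- stencil$uT[cells] != 0
      acc[ok] <- acc[ok] + uT[cells[ok]] * z[kk[ok]]
      z[cells] <- y[cells] - acc / d[cells]
    }
    z
  }
}
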