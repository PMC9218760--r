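# Finite-volume machinery shared by the device-physics solvers.
#
# Both solvers discretize an operator of the form
#     -div(k grad u) + c u = q
# on a tensor-product grid with graded (geometrically growing) cell widths:
# steady diffusion of light fluence (k = D, c = mu_a) and steady bioheat
# (k = thermal conductivity, c = perfusion coefficient). Face conductances
# use harmonic averaging so high-contrast inclusions (silicon in tissue) are
# handled conservatively. Dirichlet-0 boundaries are folded into the
# diagonal; Neumann boundaries contribute nothing. Systems are symmetric
# positive definite and solved with a sparse Cholesky factorization.

# Geometrically graded cell widths summing exactly to `total`.
grow_widths <- function(total, h0, growth = 1.3, hmax = Inf) {
  stopifnot(total > 0, h0 > 0, growth >= 1)
  w <- numeric(0); h <- h0; s <- 0
  while (s + h < total) {
    w <- c(w, h); s <- s + h
    h <- min(h * growth, hmax)
  }
  rem <- total - s
  if (length(w) && rem < 0.3 * w[length(w)]) {
    w[length(w)] <- w[length(w)] + rem
  } else {
    w <- c(w, rem)
  }
  w
}

# Assemble and solve -div(k grad u) + c u = q on a 3-D tensor grid.
# xe, ye, ze: cell edge coordinates (m). karr: conductivity (nx,ny,nz).
# carr: volumetric sink coefficient (W m^-3 K^-1 or m^-1 scale). qarr: source
# per cell (W). neumann: subset of c("xlo","xhi","ylo","yhi","zlo","zhi");
# all other boundaries are Dirichlet u = 0. face_res_y: optional
# (nx, ny-1, nz) array of extra series area-resistance (m^2 K W^-1) on
# y-faces (used for the thin oxide cap).
fv_solve_3d <- function(xe, ye, ze, karr, carr, qarr,
                        neumann = character(), face_res_y = NULL) {
  nx <- length(xe) - 1L; ny <- length(ye) - 1L; nz <- length(ze) - 1L
  stopifnot(all(dim(karr) == c(nx, ny, nz)))
  dx <- diff(xe); dy <- diff(ye); dz <- diff(ze)
  n <- nx * ny * nz
  lin <- function(ix, iy, iz) ix + (iy - 1L) * nx + (iz - 1L) * (nx * ny)

  diagv <- as.vector(carr) *
    as.vector(outer(dx, outer(dy, dz))) # c * cell volume
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)

  add_faces <- function(axis) {
    if (axis == 1L) {
      m <- c(nx - 1L, ny, nz)
      if (m[1L] < 1L) return(NULL)
      k1 <- karr[seq_len(nx - 1L), , , drop = FALSE]
      k2 <- karr[1L + seq_len(nx - 1L), , , drop = FALSE]
      rf <- dx[seq_len(nx - 1L)] / (2 * k1) + dx[1L + seq_len(nx - 1L)] / (2 * k2)
      A <- array(rep(outer(dy, dz), each = nx - 1L), dim = m)
      idx <- arrayInd(seq_len(prod(m)), m)
      i <- lin(idx[, 1L], idx[, 2L], idx[, 3L])
      j <- lin(idx[, 1L] + 1L, idx[, 2L], idx[, 3L])
    } else if (axis == 2L) {
      m <- c(nx, ny - 1L, nz)
      if (m[2L] < 1L) return(NULL)
      k1 <- karr[, seq_len(ny - 1L), , drop = FALSE]
      k2 <- karr[, 1L + seq_len(ny - 1L), , drop = FALSE]
      rf <- array(rep(dy[seq_len(ny - 1L)], each = nx), dim = m) / (2 * k1) +
        array(rep(dy[1L + seq_len(ny - 1L)], each = nx), dim = m) / (2 * k2)
      if (!is.null(face_res_y)) rf <- rf + face_res_y
      A <- array(outer(dx, rep(1, ny - 1L)), dim = m) *
        array(rep(dz, each = nx * (ny - 1L)), dim = m)
      idx <- arrayInd(seq_len(prod(m)), m)
      i <- lin(idx[, 1L], idx[, 2L], idx[, 3L])
      j <- lin(idx[, 1L], idx[, 2L] + 1L, idx[, 3L])
    } else {
      m <- c(nx, ny, nz - 1L)
      if (m[3L] < 1L) return(NULL)
      k1 <- karr[, , seq_len(nz - 1L), drop = FALSE]
      k2 <- karr[, , 1L + seq_len(nz - 1L), drop = FALSE]
      rf <- array(rep(dz[seq_len(nz - 1L)], each = nx * ny), dim = m) / (2 * k1) +
        array(rep(dz[1L + seq_len(nz - 1L)], each = nx * ny), dim = m) / (2 * k2)
      A <- array(outer(dx, dy), dim = m)
      idx <- arrayInd(seq_len(prod(m)), m)
      i <- lin(idx[, 1L], idx[, 2L], idx[, 3L])
      j <- lin(idx[, 1L], idx[, 2L], idx[, 3L] + 1L)
    }
    G <- as.vector(A / rf)
    list(i = i, j = j, G = G)
  }

  for (ax in 1:3) {
    f <- add_faces(ax)
    if (is.null(f)) next
    ii <- c(ii, f$i); jj <- c(jj, f$j); gg <- c(gg, f$G)
    diagv[f$i] <- diagv[f$i] + f$G
    diagv[f$j] <- diagv[f$j] + f$G
  }

  add_dirichlet <- function(face) {
    if (face %in% neumann) return(NULL)
    if (face == "xlo") { ix <- 1L; d <- dx[1L] }
    if (face == "xhi") { ix <- nx; d <- dx[nx] }
    if (face %in% c("xlo", "xhi")) {
      idx <- arrayInd(seq_len(ny * nz), c(ny, nz))
      cells <- lin(ix, idx[, 1L], idx[, 2L])
      Gb <- as.vector(outer(dy, dz)) / (d / (2 * karr[ix, , ]))
    } else if (face %in% c("ylo", "yhi")) {
      iy <- if (face == "ylo") 1L else ny; d <- if (face == "ylo") dy[1L] else dy[ny]
      idx <- arrayInd(seq_len(nx * nz), c(nx, nz))
      cells <- lin(idx[, 1L], iy, idx[, 2L])
      Gb <- as.vector(outer(dx, dz)) / (d / (2 * karr[, iy, ]))
    } else {
      iz <- if (face == "zlo") 1L else nz; d <- if (face == "zlo") dz[1L] else dz[nz]
      idx <- arrayInd(seq_len(nx * ny), c(nx, ny))
      cells <- lin(idx[, 1L], idx[, 2L], iz)
      Gb <- as.vector(outer(dx, dy)) / (d / (2 * karr[, , iz]))
    }
    diagv[cells] <<- diagv[cells] + as.vector(Gb)
    NULL
  }
  for (f in c("xlo", "xhi", "ylo", "yhi", "zlo", "zhi")) add_dirichlet(f)

  A <- Matrix::sparseMatrix(
    i = c(ii, jj, seq_len(n)), j = c(jj, ii, seq_len(n)),
    x = c(-gg, -gg, diagv), dims = c(n, n)
  )
  u <- chol_solve(A, as.vector(qarr))
  array(u, dim = c(nx, ny, nz))
}

# SPD sparse solve via supernodal Cholesky (much faster than the generic
# sparse-LU dispatch for these 3-D stencil systems).
chol_solve <- function(A, b) {
  As <- Matrix::forceSymmetric(A)
  ch <- Matrix::Cholesky(As, LDL = FALSE, super = TRUE)
  as.numeric(Matrix::solve(ch, b))
}

# Axisymmetric (r, z) variant used by the fluence solver's fast path.
# re: radial edges from 0 (m); ze: axial edges (m). k scalar, c scalar,
# qarr: (nr, nz) source per cell (W). neumann: subset of c("zlo","zhi");
# the outer radial boundary and non-Neumann axial boundaries are
# Dirichlet 0; the axis r = 0 is a natural symmetry boundary.
fv_solve_axisym <- function(re, ze, k, cc, qarr, neumann = character()) {
  nr <- length(re) - 1L; nz <- length(ze) - 1L
  stopifnot(re[1L] == 0, all(dim(qarr) == c(nr, nz)))
  dr <- diff(re); dz <- diff(ze)
  rc <- (re[-1L] + re[-length(re)]) / 2
  area_ann <- pi * (re[-1L]^2 - re[-length(re)]^2)   # annulus cross-section
  vol <- outer(area_ann, dz)
  n <- nr * nz
  lin <- function(ir, iz) ir + (iz - 1L) * nr

  diagv <- as.vector(cc * vol)
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)

  # radial faces
  if (nr >= 2L) {
    idx <- arrayInd(seq_len((nr - 1L) * nz), c(nr - 1L, nz))
    i <- lin(idx[, 1L], idx[, 2L]); j <- lin(idx[, 1L] + 1L, idx[, 2L])
    rfac <- re[1L + seq_len(nr - 1L)] # face radius
    A <- outer(2 * pi * rfac, dz)
    R <- (rc[1L + seq_len(nr - 1L)] - rc[seq_len(nr - 1L)]) / k
    G <- as.vector(A / R)
    ii <- c(ii, i); jj <- c(jj, j); gg <- c(gg, G)
    diagv[i] <- diagv[i] + G; diagv[j] <- diagv[j] + G
  }
  # axial faces
  if (nz >= 2L) {
    idx <- arrayInd(seq_len(nr * (nz - 1L)), c(nr, nz - 1L))
    i <- lin(idx[, 1L], idx[, 2L]); j <- lin(idx[, 1L], idx[, 2L] + 1L)
    A <- outer(area_ann, rep(1, nz - 1L))
    R <- rep((dz[seq_len(nz - 1L)] + dz[1L + seq_len(nz - 1L)]) / (2 * k),
             each = nr)
    G <- as.vector(A) / R
    ii <- c(ii, i); jj <- c(jj, j); gg <- c(gg, G)
    diagv[i] <- diagv[i] + G; diagv[j] <- diagv[j] + G
  }
  # outer radial Dirichlet
  cells <- lin(nr, seq_len(nz))
  diagv[cells] <- diagv[cells] + 2 * pi * re[nr + 1L] * dz / (dr[nr] / (2 * k))
  # axial boundaries
  if (!("zlo" %in% neumann)) {
    cells <- lin(seq_len(nr), 1L)
    diagv[cells] <- diagv[cells] + area_ann / (dz[1L] / (2 * k))
  }
  if (!("zhi" %in% neumann)) {
    cells <- lin(seq_len(nr), nz)
    diagv[cells] <- diagv[cells] + area_ann / (dz[nz] / (2 * k))
  }

  A <- Matrix::sparseMatrix(
    i = c(ii, jj, seq_len(n)), j = c(jj, ii, seq_len(n)),
    x = c(-gg, -gg, diagv), dims = c(n, n)
  )
  u <- chol_solve(A, as.vector(qarr))
  array(u, dim = c(nr, nz))
}

# Fractional overlap of grid cells with an axis-aligned box, per dimension.
# Returns a vector of per-cell overlap lengths for edges `e` against [a, b].
edge_overlap <- function(e, a, b) {
  pmax(0, pmin(e[-1L], b) - pmax(e[-length(e)], a))
}
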