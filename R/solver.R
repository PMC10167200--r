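#' Blood properties
#'
#' Standard values for whole blood at body temperature; both configurable.
#'
#' @param rho Density, kg/m^3 (default 1060).
#' @param mu Dynamic viscosity, Pa s (default 3.5e-3).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1060, mu = 3.5e-3) {
  if (rho <= 0 || mu <= 0) stop("fluid_properties: rho and mu must be > 0")
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Inflow specification
#'
#' The systolic inflow is a parabolic (Poiseuille-shaped) axial profile with
#' a temporal envelope. The default envelope is a half sine over the systolic
#' interval `T`, peaking exactly at `T/2 = T_end`, so simulations run from
#' rest to peak systole. The peak axial velocity is set from the target peak
#' inlet Reynolds number: `U_peak = Re_max * mu / (rho * 2R)` with `R` the
#' cylinder radius (the Reynolds number is based on the diameter and the
#' spatio-temporal maximum of the profile).
#'
#' @param T Systolic interval, s (default 0.4).
#' @param T_end Simulation end time, s (default 0.2, peak systole).
#' @param Re_max Target peak inlet Reynolds number (default 1200).
#' @param envelope `"halfsine"` (`sin(pi t / T)`) or `"constant"` (steady).
#' @param type `"velocity"` (strong Dirichlet profile, default) or
#'   `"pressure"` (natural traction inflow with prescribed pressure `p_in`,
#'   used e.g. for blocked-domain penalization tests).
#' @param p_in Driving pressure (Pa) when `type = "pressure"`.
#' @return An object of class `inflow_spec`.
#' @export
inflow_spec <- function(T = 0.4, T_end = 0.2, Re_max = 1200,
                        envelope = c("halfsine", "constant"),
                        type = c("velocity", "pressure"), p_in = 0) {
  envelope <- match.arg(envelope)
  type <- match.arg(type)
  if (!(T_end > 0 && T_end <= T)) stop("inflow_spec: need 0 < T_end <= T")
  if (Re_max <= 0) stop("inflow_spec: Re_max must be > 0")
  structure(list(T = T, T_end = T_end, Re_max = Re_max, envelope = envelope,
                 type = type, p_in = p_in),
            class = "inflow_spec")
}

#' Solver configuration
#'
#' @param dt Time step, s (default 2.5e-3; the desk-scale preset uses 1e-2).
#' @param backflow_coeff Outlet backflow-stabilization coefficient
#'   (default 0.5).
#' @param picard_iter Nonlinear (Picard) sweeps per step; 1 is the
#'   semi-implicit scheme with the previous-step advecting velocity.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 2.5e-3, backflow_coeff = 0.5,
                          picard_iter = 1L) {
  if (dt <= 0) stop("solver_config: dt must be > 0")
  structure(list(dt = dt, backflow_coeff = backflow_coeff,
                 picard_iter = as.integer(picard_iter)),
            class = "solver_config")
}

#' Inlet velocity profile
#'
#' @param position `n x 3` coordinates on the inlet plane (mm).
#' @param t Time (s).
#' @param spec An [inflow_spec()].
#' @param props A [fluid_properties()].
#' @param radius Cylinder radius (mm).
#' @return `n x 3` velocity matrix (m/s); only the axial (+z) component is
#'   nonzero, vanishing at `r = R`.
#' @export
inlet_profile <- function(position, t, spec, props, radius) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  R <- radius * 1e-3
  U <- spec$Re_max * props$mu / (props$rho * 2 * R)
  env <- switch(spec$envelope,
                halfsine = sin(pi * t / spec$T),
                constant = 1)
  r2 <- (position[, 1]^2 + position[, 2]^2) * 1e-6 / R^2
  r2[abs(r2 - 1) < 1e-12] <- 1  # exact no-slip on the rim
  uz <- U * pmax(0, 1 - r2) * env
  cbind(0, 0, uz, deparse.level = 0)
}

# peak inlet axial velocity (m/s) implied by the Reynolds target
inlet_peak_velocity <- function(spec, props, radius) {
  spec$Re_max * props$mu / (props$rho * 2 * radius * 1e-3)
}

# ---------------------------------------------------------------------------
# Finite element machinery (P1bubble/P1, statically condensed bubble)

# Per-element P1 data in SI units: volumes (m^3) and basis gradients (1/m)
fem_element_data <- function(mesh) {
  X <- mesh$nodes * 1e-3
  tt <- mesh$cells
  p1 <- X[tt[, 1], , drop = FALSE]
  a <- X[tt[, 2], , drop = FALSE] - p1
  b <- X[tt[, 3], , drop = FALSE] - p1
  cc <- X[tt[, 4], , drop = FALSE] - p1
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cr(b, cc); cxa <- cr(cc, a); axb <- cr(a, b)
  six_v <- rowSums(a * bxc)
  g2 <- bxc / six_v; g3 <- cxa / six_v; g4 <- axb / six_v
  g1 <- -(g2 + g3 + g4)
  list(vol = six_v / 6,
       gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
       gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
       gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3]),
       cells = tt, n_nodes = nrow(X), nodes_m = X)
}

# 16 (i,j) local pairs expanded to global triplet index vectors
fem_pair_index <- function(cells) {
  li <- rep(1:4, each = 4); lj <- rep(1:4, times = 4)
  list(I = as.vector(cells[, li]), J = as.vector(cells[, lj]),
       li = li, lj = lj)
}

# scalar consistent-mass triplet values: V/20 (1 + delta_ij)
fem_mass_values <- function(ed, px) {
  vapply(seq_len(16), function(k) {
    ed$vol / 20 * (1 + (px$li[k] == px$lj[k]))
  }, ed$vol) |> as.vector()
}

# scalar stiffness values: V g_i . g_j
fem_stiffness_values <- function(ed, px) {
  vapply(seq_len(16), function(k) {
    i <- px$li[k]; j <- px$lj[k]
    ed$vol * (ed$gx[, i] * ed$gx[, j] + ed$gy[, i] * ed$gy[, j] +
                ed$gz[, i] * ed$gz[, j])
  }, ed$vol) |> as.vector()
}

# reaction values for a P1 nodal coefficient field gamma (exact integrals)
fem_gamma_values <- function(ed, px, gamma_nodal) {
  gtet <- matrix(gamma_nodal[ed$cells], ncol = 4)
  gsum <- rowSums(gtet)
  vapply(seq_len(16), function(k) {
    i <- px$li[k]; j <- px$lj[k]
    if (i == j) ed$vol / 60 * (gsum + 2 * gtet[, i])
    else ed$vol / 120 * (gsum + gtet[, i] + gtet[, j])
  }, ed$vol) |> as.vector()
}

# convection values rho * phi_i (w . grad phi_j), w the P1 advecting field,
# plus the Temam term (rho/2)(div w) phi_i phi_j and a streamline-upwind
# diffusion rho tau (w.grad phi_i)(w.grad phi_j) with tau = h_e / (2|w|),
# which damps the node-to-node oscillations of Galerkin convection at the
# high cell Peclet numbers of coarse meshes
fem_convection_values <- function(ed, px, w, rho, supg = TRUE) {
  wx <- matrix(w[ed$cells, 1], ncol = 4)
  wy <- matrix(w[ed$cells, 2], ncol = 4)
  wz <- matrix(w[ed$cells, 3], ncol = 4)
  sx <- rowSums(wx); sy <- rowSums(wy); sz <- rowSums(wz)
  divw <- rowSums(wx * ed$gx + wy * ed$gy + wz * ed$gz)
  bx <- sx / 4; by <- sy / 4; bz <- sz / 4
  if (supg) {
    nb <- sqrt(bx^2 + by^2 + bz^2)
    h_e <- (6 * sqrt(2) * ed$vol)^(1 / 3)
    tau <- rho * ed$vol * h_e / (2 * nb + 1e-12)
  } else tau <- 0
  vapply(seq_len(16), function(k) {
    i <- px$li[k]; j <- px$lj[k]
    conv <- rho * ed$vol / 20 *
      ((sx + wx[, i]) * ed$gx[, j] + (sy + wy[, i]) * ed$gy[, j] +
         (sz + wz[, i]) * ed$gz[, j])
    temam <- rho / 2 * divw * ed$vol / 20 * (1 + (i == j))
    su <- tau * (bx * ed$gx[, i] + by * ed$gy[, i] + bz * ed$gz[, i]) *
      (bx * ed$gx[, j] + by * ed$gy[, j] + bz * ed$gz[, j])
    conv + temam + su
  }, ed$vol) |> as.vector()
}

# pressure-gradient coupling blocks: momentum(i, comp k) x pressure(j)
# value -(V/4) g_{i,k}; returns one triplet set per component
fem_pressure_blocks <- function(ed, px) {
  lapply(list(ed$gx, ed$gy, ed$gz), function(G) {
    as.vector(vapply(seq_len(16), function(k) {
      -(ed$vol / 4) * G[, px$li[k]]
    }, ed$vol))
  })
}

# condensed-bubble pressure stabilization: tau_e * g_i . g_j with
# tau_e = (int b)^2 / [ (rho/dt + mean gamma) int b^2 + mu int |grad b|^2 ]
fem_bubble_tau <- function(ed, gamma_nodal, rho, mu, dt) {
  ib <- (32 / 105) * ed$vol
  ib2 <- (6291456 / 39916800) * ed$vol
  sumg2 <- (ed$gx^2 + ed$gy^2 + ed$gz^2) |> rowSums()
  kb <- (65536 / 15120) * ed$vol * sumg2
  gbar <- rowMeans(matrix(gamma_nodal[ed$cells], ncol = 4))
  ib^2 / ((rho / dt + gbar) * ib2 + mu * kb)
}

fem_bubble_values <- function(ed, px, tau) {
  vapply(seq_len(16), function(k) {
    i <- px$li[k]; j <- px$lj[k]
    tau * (ed$gx[, i] * ed$gx[, j] + ed$gy[, i] * ed$gy[, j] +
             ed$gz[, i] * ed$gz[, j])
  }, ed$vol) |> as.vector()
}

# ---------------------------------------------------------------------------

#' Precompute the time-invariant finite element operators
#'
#' Assembles everything that does not change between time steps: scalar mass,
#' viscous and penalization operators, the pressure coupling and the
#' condensed-bubble pressure stabilization, boundary facet data and the
#' Dirichlet dof bookkeeping. Geometry is converted from mm to SI metres
#' here; all assembled operators are in SI units.
#'
#' @param mesh A `volume_mesh`.
#' @param gamma A `gamma_field` (or `NULL` for a plain Navier-Stokes run).
#' @param inflow An [inflow_spec()].
#' @param config A [solver_config()].
#' @param props A [fluid_properties()].
#' @return An opaque list consumed by [advance()] / [run_simulation()].
#' @export
fem_setup <- function(mesh, gamma, inflow, config, props) {
  ed <- fem_element_data(mesh)
  px <- fem_pair_index(ed$cells)
  N <- ed$n_nodes
  gam <- if (is.null(gamma)) numeric(N) else gamma$values

  mvals <- fem_mass_values(ed, px)
  Msc <- Matrix::sparseMatrix(i = px$I, j = px$J, x = mvals, dims = c(N, N))
  Ksc <- Matrix::sparseMatrix(i = px$I, j = px$J,
                              x = fem_stiffness_values(ed, px),
                              dims = c(N, N))
  Gsc <- Matrix::sparseMatrix(i = px$I, j = px$J,
                              x = fem_gamma_values(ed, px, gam),
                              dims = c(N, N))
  Asc_const <- (props$rho / config$dt) * Msc + props$mu * Ksc + Gsc

  pb <- fem_pressure_blocks(ed, px)
  Gx <- Matrix::sparseMatrix(i = px$I, j = px$J, x = pb[[1]], dims = c(N, N))
  Gy <- Matrix::sparseMatrix(i = px$I, j = px$J, x = pb[[2]], dims = c(N, N))
  Gz <- Matrix::sparseMatrix(i = px$I, j = px$J, x = pb[[3]], dims = c(N, N))

  tau <- fem_bubble_tau(ed, gam, props$rho, props$mu, config$dt)
  Cpp <- Matrix::sparseMatrix(i = px$I, j = px$J,
                              x = fem_bubble_values(ed, px, tau),
                              dims = c(N, N))

  # boundary bookkeeping
  inlet_nodes <- sort(unique(as.vector(mesh$boundary$inlet)))
  wall_nodes <- sort(unique(as.vector(mesh$boundary$wall)))
  if (inflow$type == "velocity") {
    # profile vanishes on the rim, so wall-precedence is consistent
    dir_nodes <- sort(unique(c(inlet_nodes, wall_nodes)))
  } else {
    dir_nodes <- wall_nodes
  }
  cdofs <- c(dir_nodes, dir_nodes + N, dir_nodes + 2L * N)
  is_c <- rep(FALSE, 4L * N); is_c[cdofs] <- TRUE

  out_faces <- mesh$boundary$outlet
  out_areas <- facet_areas(mesh$nodes, out_faces) * 1e-6  # m^2
  in_faces <- mesh$boundary$inlet
  in_areas <- facet_areas(mesh$nodes, in_faces) * 1e-6
  # nodal inlet areas for traction inflow
  a_in_nodal <- numeric(N)
  for (cidx in 1:3) {
    acc <- tapply(in_areas / 3, in_faces[, cidx], sum)
    ii <- as.integer(names(acc))
    a_in_nodal[ii] <- a_in_nodal[ii] + acc
  }

  mask <- rep(1, N); mask[dir_nodes] <- 0
  Dm <- Matrix::Diagonal(N, mask)
  Gxb <- Dm %*% Gx; Gyb <- Dm %*% Gy; Gzb <- Dm %*% Gz
  GxT <- Matrix::t(Gx); GyT <- Matrix::t(Gy); GzT <- Matrix::t(Gz)

  list(ed = ed, px = px, N = N, Msc = Msc, Asc_const = Asc_const,
       Gx = Gx, Gy = Gy, Gz = Gz, Gxb = Gxb, Gyb = Gyb, Gzb = Gzb,
       GxT = GxT, GyT = GyT, GzT = GzT, Cpp = Cpp,
       mask = mask, Dm = Dm,
       inlet_nodes = inlet_nodes, wall_nodes = wall_nodes,
       dir_nodes = dir_nodes, is_c = is_c, cdofs = cdofs,
       out_faces = out_faces, out_areas = out_areas,
       in_faces = in_faces, in_areas = in_areas, a_in_nodal = a_in_nodal,
       mesh = mesh, gamma = gam, inflow = inflow, config = config,
       props = props, cache = new.env(parent = emptyenv()))
}

# outlet backflow stabilization triplets: -(rho*beta/2)(w.n)_- face mass
backflow_triplets <- function(fem, w) {
  f <- fem$out_faces
  if (!nrow(f)) return(list(I = integer(0), J = integer(0), X = numeric(0)))
  wzm <- (w[f[, 1], 3] + w[f[, 2], 3] + w[f[, 3], 3]) / 3  # n = +e_z
  coefs <- fem$props$rho * fem$config$backflow_coeff / 2 * pmax(0, -wzm)
  act <- coefs > 0
  if (!any(act)) return(list(I = integer(0), J = integer(0), X = numeric(0)))
  f <- f[act, , drop = FALSE]
  cf <- (coefs * fem$out_areas)[act]
  li <- rep(1:3, each = 3); lj <- rep(1:3, times = 3)
  I <- as.vector(f[, li]); J <- as.vector(f[, lj])
  X <- as.vector(vapply(seq_len(9), function(k) {
    cf / 12 * (1 + (li[k] == lj[k]))
  }, cf))
  list(I = I, J = J, X = X)
}

# assemble the full velocity-block scalar operator at advecting field w,
# with Dirichlet rows/columns folded (identity on constrained dofs)
velocity_operator <- function(fem, w) {
  N <- fem$N
  Ac <- Matrix::sparseMatrix(
    i = fem$px$I, j = fem$px$J,
    x = fem_convection_values(fem$ed, fem$px, w, fem$props$rho),
    dims = c(N, N))
  bt <- backflow_triplets(fem, w)
  if (length(bt$I))
    Ac <- Ac + Matrix::sparseMatrix(i = bt$I, j = bt$J, x = bt$X,
                                    dims = c(N, N))
  As <- fem$Asc_const + Ac
  Abc <- fem$Dm %*% As %*% fem$Dm +
    Matrix::Diagonal(N, 1 - fem$mask)
  list(As = As, Abc = Abc)
}

# frozen block preconditioner: LU of the velocity operator and a Cholesky of
# the approximate pressure Schur complement Cpp + B' diag(A)^{-1} B
build_preconditioner <- function(fem, Abc) {
  N <- fem$N
  dA <- fem$mask / Matrix::diag(Abc)
  D <- Matrix::Diagonal(N, dA)
  P0 <- fem$Cpp + fem$GxT %*% D %*% fem$Gx + fem$GyT %*% D %*% fem$Gy +
    fem$GzT %*% D %*% fem$Gz
  # guard the Cholesky against roundoff on the badly scaled (but PSD)
  # Schur approximation when gamma spans many orders of magnitude
  P0 <- P0 + Matrix::Diagonal(N, 1e-10 * max(Matrix::diag(P0)))
  list(Alu = Matrix::lu(Abc),
       Pch = Matrix::Cholesky(Matrix::forceSymmetric(P0), LDL = FALSE))
}

# right-preconditioned BiCGSTAB on the monolithic system
bicgstab <- function(matvec, precond, b, x0, rtol = 1e-8, atol = 1e-300,
                     maxit = 400L) {
  bnrm <- sqrt(sum(b^2))
  if (bnrm == 0) return(list(x = 0 * b, iters = 0L, converged = TRUE))
  x <- x0
  r <- b - matvec(x)
  tol <- max(rtol * bnrm, atol)
  if (sqrt(sum(r^2)) <= tol)
    return(list(x = x, iters = 0L, converged = TRUE))
  r0 <- r
  rho_old <- 1; alpha <- 1; omega <- 1
  v <- p <- 0 * b
  for (it in seq_len(maxit)) {
    rho <- sum(r0 * r)
    if (abs(rho) < 1e-300) break
    beta <- (rho / rho_old) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    ph <- precond(p)
    v <- matvec(ph)
    alpha <- rho / sum(r0 * v)
    s <- r - alpha * v
    x <- x + alpha * ph
    if (sqrt(sum(s^2)) <= tol)
      return(list(x = x, iters = it, converged = TRUE))
    sh <- precond(s)
    t <- matvec(sh)
    omega <- sum(t * s) / sum(t * t)
    x <- x + omega * sh
    r <- s - omega * t
    if (sqrt(sum(r^2)) <= tol)
      return(list(x = x, iters = it, converged = TRUE))
    rho_old <- rho
  }
  list(x = x, iters = maxit, converged = FALSE)
}

#' Advance the flow state by one backward-Euler step
#'
#' Solves the monolithic penalized system at `t + dt`: implicit mass,
#' viscous, penalization and pressure coupling; convection and the Temam
#' stabilization linearized with the previous-step advecting velocity
#' (optionally Picard-updated); backflow stabilization on the outlet;
#' strong Dirichlet data on inlet (velocity inflow) and wall. The linear
#' saddle system is solved with BiCGSTAB under a block-triangular
#' preconditioner (sparse LU of the velocity operator, Cholesky of the
#' bubble-stabilized approximate pressure Schur complement); the
#' preconditioner is refreshed adaptively when convection has drifted enough
#' to slow convergence.
#'
#' @param state A `flow_state` (list with `u` `n x 3` m/s, `p` Pa, `t` s).
#' @param fem Output of [fem_setup()].
#' @return The updated `flow_state`.
#' @export
advance <- function(state, fem) {
  N <- fem$N
  cfg <- fem$config
  props <- fem$props
  cache <- fem$cache
  tn1 <- state$t + cfg$dt
  u <- state$u
  w <- u
  iu <- 1:(3 * N); ip <- 3 * N + 1:N
  for (sweep in seq_len(max(1L, cfg$picard_iter))) {
    op <- velocity_operator(fem, w)

    # momentum rhs: time term (+ traction inflow if pressure-driven)
    fmat <- (props$rho / cfg$dt) * as.matrix(fem$Msc %*% u)
    if (fem$inflow$type == "pressure") {
      env <- switch(fem$inflow$envelope,
                    halfsine = sin(pi * tn1 / fem$inflow$T), constant = 1)
      fmat[, 3] <- fmat[, 3] + fem$inflow$p_in * env * fem$a_in_nodal
    }

    # Dirichlet values per component (axial inflow profile; walls at rest)
    val <- matrix(0, N, 3)
    if (fem$inflow$type == "velocity" && length(fem$inlet_nodes)) {
      uin <- inlet_profile(fem$mesh$nodes[fem$inlet_nodes, , drop = FALSE],
                           tn1, fem$inflow, props, fem$mesh$spec$radius)
      val[fem$inlet_nodes, 3] <- uin[, 3]
      val[fem$wall_nodes, ] <- 0
    }
    fbc <- fem$mask * (fmat - as.matrix(op$As %*% val)) + (1 - fem$mask) * val

    b <- c(as.vector(fbc), rep(0, N))
    matvec <- function(x) {
      um <- matrix(x[iu], N, 3)
      pv <- x[ip]
      yu <- as.matrix(op$Abc %*% um)
      yu[, 1] <- yu[, 1] + as.vector(fem$Gxb %*% pv)
      yu[, 2] <- yu[, 2] + as.vector(fem$Gyb %*% pv)
      yu[, 3] <- yu[, 3] + as.vector(fem$Gzb %*% pv)
      yp <- as.vector(fem$GxT %*% um[, 1] + fem$GyT %*% um[, 2] +
                        fem$GzT %*% um[, 3] - fem$Cpp %*% pv)
      c(as.vector(yu), yp)
    }
    precond <- function(r) {
      rp <- r[ip]
      zp <- -as.vector(Matrix::solve(cache$pc$Pch, rp))
      ru <- matrix(r[iu], N, 3)
      ru[, 1] <- ru[, 1] - as.vector(fem$Gxb %*% zp)
      ru[, 2] <- ru[, 2] - as.vector(fem$Gyb %*% zp)
      ru[, 3] <- ru[, 3] - as.vector(fem$Gzb %*% zp)
      zu <- as.matrix(Matrix::solve(cache$pc$Alu, ru))
      c(as.vector(zu), zp)
    }

    if (is.null(cache$pc) || isTRUE(cache$refresh)) {
      cache$pc <- build_preconditioner(fem, op$Abc)
      cache$refresh <- FALSE
    }
    x0 <- c(as.vector(state$u), state$p)
    res <- bicgstab(matvec, precond, b, x0)
    if (!res$converged) {
      # stale preconditioner: rebuild at the current operator and retry
      cache$pc <- build_preconditioner(fem, op$Abc)
      res <- bicgstab(matvec, precond, b, x0)
      if (!res$converged)
        stop(sprintf(
          "advance: linear solver failed to converge at t=%.4f s", tn1))
    }
    if (res$iters > 40L) cache$refresh <- TRUE
    sol <- res$x
    if (any(!is.finite(sol)))
      stop(sprintf("advance: non-finite solution at t=%.4f s", tn1))
    w <- matrix(sol[iu], N, 3)
  }
  list(u = w, p = sol[ip], t = tn1)
}

# discrete boundary fluxes (m^3/s): exact for P1 velocity on planar facets
boundary_flux <- function(fem, u) {
  fin <- fem$in_faces; fout <- fem$out_faces
  qi <- -sum(fem$in_areas *
               (u[fin[, 1], 3] + u[fin[, 2], 3] + u[fin[, 3], 3]) / 3)
  qo <- sum(fem$out_areas *
              (u[fout[, 1], 3] + u[fout[, 2], 3] + u[fout[, 3], 3]) / 3)
  c(inflow = -qi, outflow = qo)  # inflow reported positive into the domain
}

#' Run a transient penalized flow simulation
#'
#' Integrates from rest (`u = 0`) to `T_end` with backward Euler, recording
#' per-step diagnostics: the peak nodal velocity magnitude `v_max` (the
#' CW-Doppler-style whole-domain peak), the transvalvular pressure drop
#' between two axial planes, and the discrete inlet/outlet fluxes.
#'
#' @param mesh A `volume_mesh`.
#' @param gamma A `gamma_field`, or `NULL` for an empty domain.
#' @param inflow An [inflow_spec()].
#' @param config A [solver_config()].
#' @param props A [fluid_properties()].
#' @param z_up,z_down Axial stations (mm) for the pressure drop; defaults are
#'   one leaflet-height upstream and three downstream of the annulus when a
#'   refinement band is present, else the quarter points of the domain.
#' @param verbose Print a line per step.
#' @return A `flow_state`: final `u` (m/s), `p` (Pa), `t`, and `series`, a
#'   data frame with columns `t`, `v_max` (m/s), `dP` (mmHg), `flux_in`,
#'   `flux_out` (m^3/s).
#' @export
run_simulation <- function(mesh, gamma, inflow, config, props,
                           z_up = NULL, z_down = NULL, verbose = FALSE) {
  sp <- mesh$spec
  lh <- sp$refine_zmax - 2 * sp$h_coarse
  if (is.null(z_up)) z_up <- max(sp$z_min * 0.75, -lh)
  if (is.null(z_down)) z_down <- min(sp$z_max * 0.75, 3 * lh)
  fem <- fem_setup(mesh, gamma, inflow, config, props)
  nstep <- max(1L, round(inflow$T_end / config$dt))
  state <- list(u = matrix(0, fem$N, 3), p = numeric(fem$N), t = 0)
  series <- data.frame(t = numeric(nstep), v_max = numeric(nstep),
                       dP = numeric(nstep), flux_in = numeric(nstep),
                       flux_out = numeric(nstep))
  for (k in seq_len(nstep)) {
    state <- advance(state, fem)
    fl <- boundary_flux(fem, state$u)
    series$t[k] <- state$t
    series$v_max[k] <- sqrt(max(rowSums(state$u^2)))
    series$dP[k] <- compute_pressure_drop(state, mesh, z_up, z_down)
    series$flux_in[k] <- fl["inflow"]
    series$flux_out[k] <- fl["outflow"]
    if (verbose)
      message(sprintf(
        "  t=%.4f s  v_max=%.3f m/s  dP=%.2f mmHg  Qin=%.2e Qout=%.2e",
        state$t, series$v_max[k], series$dP[k], fl["inflow"], fl["outflow"]))
  }
  state$series <- series
  state$z_up <- z_up
  state$z_down <- z_down
  class(state) <- "flow_state"
  state
}

#' Transvalvular pressure drop between two axial planes
#'
#' Area-averaged pressure on the plane `z = z_up` minus `z = z_down`,
#' converted to mmHg. The structured extruded mesh is exploited: pressure is
#' interpolated linearly along each vertical node column to the requested
#' plane (exact for fields linear in z) and averaged with the nodal disk
#' areas.
#'
#' @param state A `flow_state` (pressures in Pa).
#' @param mesh The `volume_mesh` of the simulation.
#' @param z_up,z_down Plane stations (mm), inside the domain.
#' @return Pressure drop in mmHg.
#' @export
compute_pressure_drop <- function(state, mesh, z_up, z_down) {
  plane_average <- function(z) {
    zs <- mesh$meta$z_levels
    if (z < min(zs) - 1e-9 || z > max(zs) + 1e-9)
      stop("compute_pressure_drop: plane z=", z, " outside the domain")
    z <- min(max(z, min(zs)), max(zs))
    l0 <- max(1L, findInterval(z, zs, rightmost.closed = TRUE))
    l1 <- min(length(zs), l0 + 1L)
    th <- if (l1 == l0) 0 else (z - zs[l0]) / (zs[l1] - zs[l0])
    nd <- mesh$meta$n_disk
    p0 <- state$p[(l0 - 1L) * nd + seq_len(nd)]
    p1 <- state$p[(l1 - 1L) * nd + seq_len(nd)]
    w <- mesh$meta$node_area
    sum(((1 - th) * p0 + th * p1) * w) / sum(w)
  }
  (plane_average(z_up) - plane_average(z_down)) / .PA_PER_MMHG
}

#' Compare simulated gradients with the simplified Bernoulli relation
#'
#' Clinically, the transvalvular gradient is estimated from the Doppler peak
#' velocity as `dP = 4 v_max^2` (dP in mmHg, v in m/s). Given simulated
#' `(v_max, dP)` pairs this fits the least-squares quadratic
#' `dP = a v^2 + b v + c` and reports each point's ratio `dP / v_max^2`
#' against the Bernoulli constant 4.
#'
#' @param v_max Peak velocities (m/s).
#' @param dP Peak pressure drops (mmHg).
#' @return A list with `coefficients` (`a`, `b`, `c`; `NA` with fewer than 3
#'   points), `ratio` (`dP / v^2` per point), and `bernoulli_constant` (4).
#' @export
bernoulli_compare <- function(v_max, dP) {
  stopifnot(length(v_max) == length(dP), length(v_max) >= 1)
  ratio <- dP / v_max^2
  coefs <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  if (length(v_max) >= 3) {
    if (max(v_max) - min(v_max) < 1e-12)
      stop("bernoulli_compare: degenerate fit (all velocities equal)")
    fit <- lm(dP ~ I(v_max^2) + v_max)
    coefs <- c(a = unname(coef(fit)[2]), b = unname(coef(fit)[3]),
               c = unname(coef(fit)[1]))
  }
  list(coefficients = coefs, ratio = ratio, bernoulli_constant = 4)
}

#' @export
print.flow_state <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("Flow state at t=%.4f s (%d steps recorded)\n", x$t, n))
  if (n)
    cat(sprintf("  peak v_max=%.3f m/s, peak dP=%.2f mmHg (planes z=%.1f/%.1f mm)\n",
                max(x$series$v_max), max(x$series$dP), x$z_up, x$z_down))
  invisible(x)
}
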