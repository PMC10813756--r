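#' Radial return onto the von Mises yield surface
#'
#' Closed-form return mapping for J2 perfect plasticity: if the trial von
#' Mises stress exceeds the yield stress, the stress deviator is scaled
#' back onto the yield surface (the hydrostatic part is untouched) and the
#' increment of equivalent plastic strain is
#' \eqn{\Delta\bar\varepsilon^p = (q_{tr} - \sigma_y) / (3G)}.
#' Uniaxial stress states reproduce the elastic-perfectly-plastic
#' uniaxial law exactly.
#'
#' @param trial_stress symmetric 3x3 trial (elastic predictor) Cauchy
#'   stress, MPa.
#' @param sigma_y yield stress, MPa (> 0).
#' @param shear_modulus elastic shear modulus G, MPa (> 0).
#' @return list with `stress` (updated 3x3), `dpeeq` (equivalent plastic
#'   strain increment), `q_trial` and `q` (trial/updated von Mises
#'   stress).
#' @export
radial_return <- function(trial_stress, sigma_y, shear_modulus) {
  s <- as.matrix(trial_stress)
  if (!all(dim(s) == c(3L, 3L))) stop("'trial_stress' must be 3x3")
  if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s))))
    stop("'trial_stress' must be symmetric")
  if (sigma_y <= 0) stop("'sigma_y' must be > 0")
  if (shear_modulus <= 0) stop("'shear_modulus' must be > 0")
  p <- sum(diag(s)) / 3
  dev <- s - diag(p, 3)
  q_tr <- sqrt(1.5 * sum(dev * dev))
  if (q_tr <= sigma_y) {
    return(list(stress = s, dpeeq = 0, q_trial = q_tr, q = q_tr))
  }
  beta <- sigma_y / q_tr
  list(stress = diag(p, 3) + beta * dev,
       dpeeq = (q_tr - sigma_y) / (3 * shear_modulus),
       q_trial = q_tr, q = sigma_y)
}

new_plastic_state <- function(n_elements) {
  list(epsp = matrix(0, n_elements, 6L), peeq = numeric(n_elements))
}

cards_vectors <- function(mesh, cards) {
  m <- nrow(mesh$tets)
  if (nrow(cards) != m)
    stop("need one material card per element")
  list(E = cards$E, nu = rep_len(cards$nu, m), sigy = cards$sigma_y)
}

#' Assemble tangent stiffness and internal force
#'
#' Standard constant-strain T4 assembly: given nodal displacements and the
#' committed plastic state, performs the elastic-predictor/radial-return
#' stress update in every element and returns the (symmetric) consistent
#' tangent and the internal force vector.
#'
#' @param mesh a `tet_mesh`.
#' @param cards `material_cards` (one row per element).
#' @param u nodal displacement vector, length `3 * n_nodes` (mm); defaults
#'   to zero.
#' @param state plastic state as returned in a previous assembly
#'   (`list(epsp, peeq)`), or `NULL` for virgin material.
#' @return list with `K` (sparse symmetric tangent, N/mm), `fint` (N),
#'   `stress` (m x 6 Voigt, MPa), `vm` (von Mises, MPa), `state` (updated
#'   plastic state), `dpeeq`.
#' @export
assemble_system <- function(mesh, cards, u = NULL, state = NULL) {
  m <- nrow(mesh$tets)
  ndof <- 3L * nrow(mesh$nodes)
  if (is.null(u)) u <- numeric(ndof)
  if (length(u) != ndof) stop("'u' has wrong length")
  if (is.null(state)) state <- new_plastic_state(m)
  cv <- cards_vectors(mesh, cards)
  pre <- tet_precompute_cpp(mesh$nodes, mesh$tets)
  upd <- fem_state_update_cpp(pre$grad, pre$vol, mesh$tets, u,
                              cv$E, cv$nu, cv$sigy, state$epsp, TRUE)
  dofmat <- dof_matrix(mesh$tets)
  ii <- as.vector(t(dofmat[, rep(1:12, times = 12), drop = FALSE]))
  jj <- as.vector(t(dofmat[, rep(1:12, each = 12), drop = FALSE]))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = upd$Kvals,
                            dims = c(ndof, ndof))
  list(K = Matrix::forceSymmetric(K), fint = upd$fint, stress = upd$stress,
       vm = upd$vm,
       state = list(epsp = upd$epsp, peeq = state$peeq + upd$dpeeq),
       dpeeq = upd$dpeeq)
}

dof_matrix <- function(tets) {
  m <- nrow(tets)
  dofmat <- matrix(0L, m, 12L)
  for (a in 1:4) {
    base <- 3L * (tets[, a] - 1L)
    dofmat[, 3L * a - 2L] <- base + 1L
    dofmat[, 3L * a - 1L] <- base + 2L
    dofmat[, 3L * a] <- base + 3L
  }
  dofmat
}

# Build the constraint transformation for a load case:
#   u_full = T u_free + d * g
# where d is the prescribed compression magnitude (applied along -axial)
# and g the prescribed unit mode.  For rigid coupling the last three free
# DOFs are the control-point rotations.
build_constraints <- function(mesh, loadcase) {
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  cranial <- loadcase$coupled_set
  caudal <- loadcase$fixed_set
  if (length(intersect(cranial, caudal)))
    stop("coupled and fixed sets must be disjoint")

  g <- numeric(ndof)
  g[3L * cranial] <- -1  # unit compression: cranial surface moves -z

  if (loadcase$coupling == "rigid") {
    other <- setdiff(seq_len(n), c(cranial, caudal))
    nfree <- 3L * length(other)
    ncol_T <- nfree + 3L
    ti <- 3L * rep(other, each = 3L) - c(2L, 1L, 0L)
    tj <- seq_len(nfree)
    tx <- rep(1, nfree)
    r <- sweep(mesh$nodes[cranial, , drop = FALSE], 2L,
               loadcase$control_point)
    # u_slave = theta x r (linearized rotation), columns nfree + (1,2,3)
    si <- c(3L * cranial - 2L, 3L * cranial - 2L,   # u_x: th2*r3 - th3*r2
            3L * cranial - 1L, 3L * cranial - 1L,   # u_y: th3*r1 - th1*r3
            3L * cranial,      3L * cranial)        # u_z: th1*r2 - th2*r1
    sj <- rep(c(nfree + 2L, nfree + 3L,
                nfree + 3L, nfree + 1L,
                nfree + 1L, nfree + 2L), each = length(cranial))
    sx <- c(r[, 3], -r[, 2], r[, 1], -r[, 3], r[, 2], -r[, 1])
    Tm <- Matrix::sparseMatrix(i = c(ti, si), j = c(tj, sj), x = c(tx, sx),
                               dims = c(ndof, ncol_T))
    list(T = Tm, g = g, n_rot = 3L,
         rot_cols = nfree + 1:3)
  } else {
    fixed <- c(3L * caudal,                       # caudal z
               anchor_dofs(mesh, caudal))
    prescribed <- 3L * cranial
    free <- setdiff(seq_len(ndof), c(fixed, prescribed))
    Tm <- Matrix::sparseMatrix(i = free, j = seq_along(free),
                               x = rep(1, length(free)),
                               dims = c(ndof, length(free)))
    list(T = Tm, g = g, n_rot = 0L, rot_cols = integer(0))
  }
}

# Minimal in-plane anchors for the uniform-axial (frictionless plate)
# setup: they block lateral rigid-body motion and carry no force in a
# homogeneous uniaxial state.
anchor_dofs <- function(mesh, caudal) {
  pts <- mesh$nodes[caudal, , drop = FALSE]
  ctr <- colMeans(pts)
  a <- caudal[which.min((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)]
  pa <- mesh$nodes[a, ]
  b <- caudal[which.max(abs(mesh$nodes[caudal, 1] - pa[1]))]
  c(3L * a - 2L, 3L * a - 1L, 3L * b - 1L)
}

#' Prepare a reusable FE model
#'
#' Precomputes element geometry, the global sparsity pattern, and the
#' constraint transformation so that repeated solves (mesh refinement
#' studies, yield-scale calibration) avoid redundant setup.
#'
#' @param mesh a labelled `tet_mesh`.
#' @param loadcase a `load_case`.
#' @return An object of class `fem_model`.
#' @export
prepare_fem_model <- function(mesh, loadcase) {
  if (length(loadcase$coupled_set) == 0L || length(loadcase$fixed_set) == 0L)
    stop("load case needs non-empty coupled and fixed sets")
  ndof <- 3L * nrow(mesh$nodes)
  pre <- tet_precompute_cpp(mesh$nodes, mesh$tets)
  dofmat <- dof_matrix(mesh$tets)
  ii <- as.vector(t(dofmat[, rep(1:12, times = 12), drop = FALSE]))
  jj <- as.vector(t(dofmat[, rep(1:12, each = 12), drop = FALSE]))
  Kpat <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                               dims = c(ndof, ndof))
  colj <- rep(seq_len(ndof), diff(Kpat@p))
  keyK <- (colj - 1) * ndof + (Kpat@i + 1)
  key <- (jj - 1) * ndof + ii
  map <- match(key, keyK)
  con <- build_constraints(mesh, loadcase)
  structure(list(mesh = mesh, loadcase = loadcase, grad = pre$grad,
                 vol = pre$vol, Kpat = Kpat, map = map,
                 nnz = length(Kpat@x), T = con$T, g = con$g,
                 rot_cols = con$rot_cols, ndof = ndof),
            class = "fem_model")
}

#' Displacement-controlled quasi-static elastoplastic solve
#'
#' Prescribes the control point's axial compression in equal increments;
#' the rigid coupling transmits it to the cranial surface (control-point
#' rotations free, transverse translations locked) while the caudal
#' surface is fully fixed.  Each increment is equilibrated by full Newton
#' iteration with consistent tangents and radial-return state updates.
#'
#' @param mesh a labelled `tet_mesh` (ignored if `model` is given).
#' @param cards `material_cards`, one row per element.
#' @param loadcase a `load_case` (ignored if `model` is given).
#' @param model optional pre-built [prepare_fem_model()] result.
#' @param tol_rel relative residual tolerance per increment.
#' @param tol_abs absolute residual tolerance, N.
#' @param max_iter maximum Newton iterations per increment.
#' @param store_history keep the per-increment PEEQ history matrix.
#' @return An object of class `solution_record`: list with `curve` (a
#'   [load_displacement_curve()], kN vs mm), `displacement`, `load_kN`,
#'   `rotation` (n_inc x 3, rad; zero cols for the uniform-axial setup),
#'   `peeq` (final, per element), `peeq_history` (optional), `u` (final
#'   nodal displacements), `converged`, `n_completed`, `iterations`.
#' @export
solve_quasistatic <- function(mesh, cards, loadcase, model = NULL,
                              tol_rel = 1e-6, tol_abs = 1e-8,
                              max_iter = 25L, store_history = TRUE) {
  if (is.null(model)) model <- prepare_fem_model(mesh, loadcase)
  mesh <- model$mesh
  loadcase <- model$loadcase
  cv <- cards_vectors(mesh, cards)
  m <- nrow(mesh$tets)
  ndof <- model$ndof
  Tm <- model$T
  K <- model$Kpat
  ninc <- loadcase$n_increments
  dtot <- loadcase$prescribed_axial_displacement
  dinc <- dtot / ninc

  u <- numeric(ndof)
  epsp <- matrix(0, m, 6L)
  peeq <- numeric(m)
  disp <- numeric(0)
  load_kN <- numeric(0)
  rot <- matrix(0, 0, 3L)
  peeq_hist <- if (store_history) matrix(0, m, 0) else NULL
  iters <- integer(0)
  converged <- TRUE
  u_free_rot <- numeric(length(model$rot_cols))

  try_chol <- function(A, r) {
    tryCatch({
      ch <- suppressWarnings(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE))
      as.vector(Matrix::solve(ch, r, system = "A"))
    }, error = function(e) NULL)
  }
  solve_reduced <- function(Kred, r) {
    out <- try_chol(Kred, r)
    if (!is.null(out)) return(out)
    # At the plastic limit load the consistent tangent of a perfectly
    # plastic model is positive semi-definite only.  A small diagonal
    # shift restores definiteness; the shifted matrix is used purely as
    # the Newton iteration operator, so the converged equilibrium is
    # unaffected (convergence is judged on the residual alone).
    dscale <- mean(Matrix::diag(Kred))
    for (shift in c(1e-8, 1e-5, 1e-2)) {
      A <- Kred + shift * dscale *
        Matrix::Diagonal(nrow(Kred))
      out <- try_chol(A, r)
      if (!is.null(out)) return(out)
    }
    as.vector(Matrix::solve(methods::as(Kred, "generalMatrix"), r))
  }

  residual_of <- function(u, epsp, tangent) {
    upd <- fem_state_update_cpp(model$grad, model$vol, mesh$tets, u,
                                cv$E, cv$nu, cv$sigy, epsp, tangent)
    upd$r <- -as.vector(Matrix::crossprod(Tm, upd$fint))
    upd$rn <- sqrt(sum(upd$r^2))
    upd
  }

  reduced_tangent <- function(upd) {
    K@x <- accumulate_slots_cpp(model$map, upd$Kvals, model$nnz)
    K
  }

  # Equilibrate one displacement sub-step: a displacement-control
  # predictor using the committed-state tangent, then Newton corrections
  # with consistent tangents and a backtracking line search on the
  # residual norm.  Returns the converged state or NULL.
  newton_step <- function(u, epsp, d_step) {
    drot <- numeric(3L)
    upd <- residual_of(u, epsp, TRUE)
    Kc <- reduced_tangent(upd)
    finc <- as.vector(Matrix::crossprod(Tm, Kc %*% (d_step * model$g)))
    ref <- max(sqrt(sum(finc^2)), upd$rn, tol_abs)
    Kred <- Matrix::forceSymmetric(Matrix::crossprod(Tm, Kc %*% Tm))
    du <- solve_reduced(Kred, upd$r - finc)
    u <- u + d_step * model$g + as.vector(Tm %*% du)
    if (length(model$rot_cols)) drot <- drot + du[model$rot_cols]
    upd <- residual_of(u, epsp, TRUE)
    for (it in seq_len(max_iter)) {
      if (upd$rn <= max(tol_rel * ref, tol_abs))
        return(list(u = u, upd = upd, iterations = it, drot = drot))
      Kc <- reduced_tangent(upd)
      Kred <- Matrix::forceSymmetric(Matrix::crossprod(Tm, Kc %*% Tm))
      du <- solve_reduced(Kred, upd$r)
      step <- as.vector(Tm %*% du)
      alpha <- 1
      for (ls in 1:8) {
        upd_try <- residual_of(u + alpha * step, epsp, ls == 1L)
        if (upd_try$rn < (1 - 1e-4 * alpha) * upd$rn) break
        alpha <- alpha / 2
      }
      u <- u + alpha * step
      if (length(model$rot_cols))
        drot <- drot + alpha * du[model$rot_cols]
      upd <- if (alpha == 1 && !is.null(upd_try$Kvals)) upd_try
             else residual_of(u, epsp, TRUE)
    }
    if (upd$rn <= max(tol_rel * ref, tol_abs))
      return(list(u = u, upd = upd, iterations = max_iter, drot = drot))
    NULL
  }

  # advance by d_step, bisecting the sub-step on non-convergence
  advance <- function(env, d_step, depth) {
    res <- newton_step(env$u, env$epsp, d_step)
    if (!is.null(res)) {
      env$u <- res$u
      env$epsp <- res$upd$epsp
      env$peeq <- env$peeq + res$upd$dpeeq
      env$fint <- res$upd$fint
      env$rot3 <- env$rot3 + res$drot
      env$nit <- env$nit + res$iterations
      return(TRUE)
    }
    if (depth >= 4L) return(FALSE)
    advance(env, d_step / 2, depth + 1L) &&
      advance(env, d_step / 2, depth + 1L)
  }

  st <- new.env(parent = emptyenv())
  st$u <- u
  st$epsp <- epsp
  st$peeq <- peeq
  st$rot3 <- numeric(3L)
  st$fint <- NULL
  for (inc in seq_len(ninc)) {
    st$nit <- 0L
    if (!advance(st, dinc, 0L)) { converged <- FALSE; break }
    disp <- c(disp, inc * dinc)
    load_kN <- c(load_kN, sum(model$g * st$fint) / 1000)
    rot <- rbind(rot, st$rot3)
    if (store_history) peeq_hist <- cbind(peeq_hist, st$peeq)
    iters <- c(iters, st$nit)
  }
  u <- st$u
  peeq <- st$peeq

  curve <- if (length(disp) >= 2L)
    load_displacement_curve(c(0, disp), c(0, load_kN)) else NULL
  structure(list(curve = curve, displacement = disp, load_kN = load_kN,
                 rotation = rot, peeq = peeq, peeq_history = peeq_hist,
                 u = u, converged = converged,
                 n_completed = length(disp), iterations = iters),
            class = "solution_record")
}

#' @export
print.solution_record <- function(x, ...) {
  cat(sprintf(
    "solution_record: %d increments%s, peak load %.3f kN, %d yielded elements\n",
    x$n_completed,
    if (x$converged) "" else " (NOT converged)",
    if (length(x$load_kN)) max(x$load_kN) else NA_real_,
    sum(x$peeq > 1e-8)))
  invisible(x)
}
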