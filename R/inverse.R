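#' Optimizer settings for the stiffness inversion
#'
#' The inversion minimizes the worst-case weighted displacement mismatch
#' (a min–max objective). Because the max is non-smooth, gradients are taken
#' on a p-norm aggregation of the per-node mismatches (exponent
#' `aggregation_exponent`); the true maximum is reported alongside. Element
#' sensitivities are cone-filtered within `filter_radius` to regularize the
#' problem and keep the reconstruction mesh-independent; densities move at
#' most `move_limit` per iteration.
#'
#' @param max_iterations iteration budget (default 100).
#' @param objective_tolerance relative surrogate-objective change below
#'   which an iteration counts as converged; convergence is declared after 5
#'   consecutive such iterations (default 1e-4).
#' @param aggregation_exponent p-norm exponent of the smooth max surrogate
#'   (default 12).
#' @param filter_radius sensitivity-filter radius in mm; `NULL` (default)
#'   means 2x the element size. The larger-filter edge-artifact remedy
#'   multiplies this via `filter_radius_factor`.
#' @param filter_radius_factor multiplier applied to the (default or given)
#'   radius (default 1).
#' @param move_limit per-iteration density change cap in `(0, 1)`
#'   (default 0.1).
#' @param optimizer `"mma"` (default): method-of-moving-asymptotes update,
#'   the standard in density-based topology optimization — each iteration
#'   minimizes a separable convex approximation whose per-element asymptotes
#'   adapt to the iteration history; with box constraints only, the
#'   subproblem solves in closed form. `"pg"`: projected spectral-gradient
#'   fallback.
#' @param smoothness_weight weight of the density-smoothness penalty
#'   `mean((rho - H rho)^2)` added to the surrogate (H is the cone-filter
#'   operator). Elements next to fully prescribed boundaries are nearly
#'   unobservable from internal mismatches; the penalty ties them to their
#'   neighbourhood instead of leaving them at whatever value the descent
#'   path last gave them. Default 1 (mm of surrogate per unit mean-square
#'   density roughness); 0 disables.
#' @param seed integer seed for any stochastic restart (the default
#'   optimizer is deterministic).
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(max_iterations = 100L,
                               objective_tolerance = 1e-4,
                               aggregation_exponent = 12,
                               filter_radius = NULL,
                               filter_radius_factor = 1,
                               move_limit = 0.1,
                               optimizer = c("mma", "pg"),
                               smoothness_weight = 0,
                               seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (max_iterations < 1) stop("`max_iterations` must be positive")
  if (objective_tolerance <= 0) stop("`objective_tolerance` must be positive")
  if (aggregation_exponent < 2) stop("`aggregation_exponent` must be >= 2")
  if (move_limit <= 0 || move_limit >= 1) stop("`move_limit` must be in (0,1)")
  if (smoothness_weight < 0) stop("`smoothness_weight` must be >= 0")
  structure(list(max_iterations = as.integer(max_iterations),
                 objective_tolerance = objective_tolerance,
                 aggregation_exponent = aggregation_exponent,
                 filter_radius = filter_radius,
                 filter_radius_factor = filter_radius_factor,
                 move_limit = move_limit, optimizer = optimizer,
                 smoothness_weight = smoothness_weight,
                 seed = as.integer(seed)),
            class = "optimizer_settings")
}

#' Assemble an inverse stiffness-reconstruction problem
#'
#' Packages everything the inversion needs: the mesh, the measured nodal
#' displacements (used as mismatch targets at internal nodes and as
#' Dirichlet data at every boundary node), per-node weights, the design
#' material (initial densities and material constants), and optimizer
#' settings.
#'
#' @param mesh an [fe_mesh()].
#' @param measured numeric matrix (n_nodes x dim) of measured displacements
#'   at every mesh node (mm).
#' @param weights per-node non-negative weights (default 1); use
#'   [weight_outliers()] upstream to down-vote suspect pixels.
#' @param material a [material_field()] holding the initial densities;
#'   default: uniform 0.5, E0 = 500 Pa, nu = 0.49, p = 1.
#' @param settings an [optimizer_settings()].
#' @return An object of class `inverse_problem`.
#' @export
inverse_problem <- function(mesh, measured, weights = NULL, material = NULL,
                            settings = optimizer_settings()) {
  stopifnot(inherits(mesh, "fe_mesh"))
  measured <- as.matrix(measured)
  if (nrow(measured) != nrow(mesh$nodes) || ncol(measured) != mesh$dim)
    stop("`measured` must be n_nodes x dim")
  if (any(!is.finite(measured))) stop("measured displacements must be finite")
  if (is.null(weights)) weights <- rep(1, nrow(mesh$nodes))
  if (length(weights) != nrow(mesh$nodes) || any(weights < 0))
    stop("`weights` must be one non-negative value per node")
  if (is.null(material))
    material <- material_field(rho = rep(0.5, nrow(mesh$elements)))
  if (length(material$rho) != nrow(mesh$elements))
    stop("material densities must be one per element")
  internal <- setdiff(seq_len(nrow(mesh$nodes)), mesh$boundary_nodes)
  if (length(internal) == 0) stop("no internal target nodes")
  bc <- dirichlet_bc(nodes = mesh$boundary_nodes,
                     values = measured[mesh$boundary_nodes, , drop = FALSE])
  structure(list(mesh = mesh, measured = measured, weights = weights,
                 bc = bc, internal_nodes = internal, material = material,
                 settings = settings),
            class = "inverse_problem")
}

#' Displacement-mismatch objective
#'
#' The design objective of the inversion: the maximum over internal nodes
#' and components of the weighted absolute difference between measured and
#' simulated displacement. Also returns the smooth p-norm surrogate that the
#' optimizer differentiates (always an upper bound on the true max,
#' converging to it as the exponent grows).
#'
#' @param measured,simulated numeric matrices (targets x dim) or vectors of
#'   identical shape (mm).
#' @param weights per-row weights (default 1).
#' @param exponent surrogate p-norm exponent (default 12).
#' @return list with `value` (the true max, mm) and `surrogate` (p-norm
#'   aggregation, mm).
#' @export
objective <- function(measured, simulated, weights = NULL, exponent = 12) {
  measured <- as.matrix(measured)
  simulated <- as.matrix(simulated)
  if (!all(dim(measured) == dim(simulated)))
    stop("measured and simulated shapes differ")
  if (nrow(measured) == 0) stop("empty target node set")
  if (is.null(weights)) weights <- rep(1, nrow(measured))
  a <- abs(measured - simulated) * weights
  M <- max(a)
  if (M == 0) return(list(value = 0, surrogate = 0))
  s <- (a / M)^exponent
  list(value = M, surrogate = M * sum(s)^(1 / exponent))
}

# gradient of the surrogate wrt the residual vector r (same shape as r)
surrogate_gradient_r <- function(r, weights, exponent) {
  a <- abs(r) * weights
  M <- max(a)
  if (M == 0) return(r * 0)
  s <- a / M
  S <- sum(s^exponent)
  S^(1 / exponent - 1) * s^(exponent - 1) * weights * sign(r)
}

# cone-weighted (linear decay) sensitivity filter as a sparse row-stochastic
# matrix over element centroids; bucketed neighbour search
build_filter_matrix <- function(mesh, radius) {
  ne <- nrow(mesh$elements)
  cen <- element_centroids(mesh)
  lo <- apply(cen, 2L, min)
  key <- floor(sweep(cen, 2L, lo, `-`) / radius)
  kstr <- apply(key, 1L, paste, collapse = ",")
  buckets <- split(seq_len(ne), kstr)
  nd <- ncol(cen)
  offs <- as.matrix(expand.grid(rep(list(-1L:1L), nd)))
  ii <- list(); jj <- list(); xx <- list()
  for (b in seq_along(buckets)) {
    els <- buckets[[b]]
    k0 <- key[els[1], ]
    cand <- integer(0)
    for (r in seq_len(nrow(offs))) {
      nb <- buckets[[paste(k0 + offs[r, ], collapse = ",")]]
      if (!is.null(nb)) cand <- c(cand, nb)
    }
    d2 <- matrix(0, length(els), length(cand))
    for (a in seq_len(nd))
      d2 <- d2 + outer(cen[els, a], cen[cand, a], `-`)^2
    w <- 1 - sqrt(d2) / radius
    w[w < 0] <- 0
    nzro <- which(w > 0, arr.ind = TRUE)
    ii[[b]] <- els[nzro[, 1]]
    jj[[b]] <- cand[nzro[, 2]]
    xx[[b]] <- w[nzro]
  }
  H <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ne, ne))
  rs <- Matrix::rowSums(H)
  Matrix::Diagonal(x = 1 / rs) %*% H
}

#' Cone-filter element sensitivities
#'
#' Replaces each element's sensitivity by the linear-decay (cone) weighted
#' average of sensitivities within `radius` of its centroid, weights
#' normalized to sum to one per element. Filtering regularizes the inverse
#' problem, decouples the reconstruction from the mesh resolution and speeds
#' convergence; a radius below the inter-element distance reduces to the
#' identity.
#'
#' @param gradient per-element sensitivity vector.
#' @param mesh an [fe_mesh()].
#' @param radius filter radius (mm).
#' @return filtered sensitivity vector.
#' @export
filter_sensitivities <- function(gradient, mesh, radius) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (radius <= 0) stop("`radius` must be positive")
  H <- build_filter_matrix(mesh, radius)
  as.numeric(H %*% gradient)
}

#' Density update step
#'
#' Projected steepest-descent update of the per-element densities: the
#' (filtered) gradient is scaled so that the largest element change equals
#' `step_scale * move_limit`, subtracted, and the result clipped to the
#' per-iteration move limit and to the box `[rho_min, 1]`. The surrounding
#' optimization loop adapts `step_scale` by backtracking so that accepted
#' steps always reduce the surrogate objective (a convex-separable
#' subproblem solver in the moving-asymptotes family could be substituted
#' here; the projected-gradient rule is the package default).
#'
#' @param rho current density vector.
#' @param gradient (filtered) sensitivity vector, same length.
#' @param settings an [optimizer_settings()].
#' @param rho_min lower density bound.
#' @param step_size explicit step length multiplying the gradient; `NULL`
#'   (default) scales the step so the largest element change equals the
#'   move limit. The optimization loop passes spectral (Barzilai-Borwein)
#'   step lengths here.
#' @return updated density vector.
#' @export
update_densities <- function(rho, gradient, settings, rho_min = 0.01,
                             step_size = NULL) {
  gmax <- max(abs(gradient))
  if (gmax == 0) return(rho)
  if (is.null(step_size)) step_size <- settings$move_limit / gmax
  new <- rho - step_size * gradient
  new <- pmin(pmax(new, rho - settings$move_limit), rho + settings$move_limit)
  pmin(pmax(new, rho_min), 1)
}

# closed-form solution of the box-constrained MMA subproblem (no coupling
# constraints): minimize sum_k p_k/(U_k - x) + q_k/(x - L_k) elementwise
mma_candidate <- function(rho, g, L, U, move, rho_min, rng, eps = 1e-7) {
  gp <- pmax(g, 0); gm <- pmax(-g, 0)
  p <- (U - rho)^2 * (1.001 * gp + 0.001 * gm + eps / rng)
  q <- (rho - L)^2 * (1.001 * gm + 0.001 * gp + eps / rng)
  sp <- sqrt(p); sq <- sqrt(q)
  x <- (L * sp + U * sq) / (sp + sq)
  lo <- pmax(pmax(rho_min, rho - move), L + 0.1 * (rho - L))
  hi <- pmin(pmin(1, rho + move), U - 0.1 * (U - rho))
  pmin(pmax(x, lo), hi)
}

# internal solver context shared across iterations (and replicates): fem
# assembly tables restricted to the free/prescribed blocks, the filter
# matrix, and target bookkeeping
inversion_context <- function(mesh, nu, bc, settings) {
  ctx <- fem_context(mesh, nu)
  dofs <- bc_dofs(bc, ctx$dim, ctx$ndof)
  nf <- length(dofs$free)
  rank <- integer(ctx$ndof)
  rank[dofs$free] <- seq_len(nf)
  rank[dofs$prescribed] <- nf + seq_along(dofs$prescribed)
  II2 <- rank[ctx$II]
  JJ2 <- rank[ctx$JJ]
  in_ff <- II2 <= nf & JJ2 <= nf
  in_fp <- II2 <= nf & JJ2 > nf
  nv <- ctx$nde * ctx$nde
  tri_elem <- rep(seq_len(ctx$ne), each = nv)
  KeFlat <- if (!is.null(ctx$Ke1)) rep(as.vector(ctx$Ke1), ctx$ne) else
    as.vector(ctx$KeAll)
  esize <- max(sqrt(rowSums((mesh$nodes[mesh$elements[, 1], , drop = FALSE] -
                             mesh$nodes[mesh$elements[, 2], , drop = FALSE])^2)))
  radius <- settings$filter_radius
  if (is.null(radius)) radius <- 2 * esize
  radius <- radius * settings$filter_radius_factor
  H <- build_filter_matrix(mesh, max(radius, 1e-9))
  # K is linear in the element moduli, so each condensed block is cached as
  # a fixed sparsity pattern plus an aggregation operator A with
  # block@x = A %*% E; re-assembly then costs one sparse matvec
  np <- length(dofs$prescribed)
  ff_u <- in_ff & II2 <= JJ2  # upper triangle of the symmetric free block
  pos_map <- function(sel, i, j, nrow_) {
    key <- (as.numeric(j[sel]) - 1) * nrow_ + as.numeric(i[sel])
    uk <- sort(unique(key))
    list(pos = match(key, uk), n = length(uk))
  }
  pm_ff <- pos_map(ff_u, II2, JJ2, nf)
  A_ff <- Matrix::sparseMatrix(i = pm_ff$pos, j = tri_elem[ff_u],
                               x = KeFlat[ff_u],
                               dims = c(pm_ff$n, ctx$ne))
  Kff_t <- Matrix::sparseMatrix(i = II2[ff_u], j = JJ2[ff_u],
                                x = rep(1, sum(ff_u)), dims = c(nf, nf),
                                symmetric = TRUE)
  pm_fp <- pos_map(in_fp, II2, JJ2 - nf, nf)
  A_fp <- Matrix::sparseMatrix(i = pm_fp$pos, j = tri_elem[in_fp],
                               x = KeFlat[in_fp],
                               dims = c(pm_fp$n, ctx$ne))
  Kfp_t <- Matrix::sparseMatrix(i = II2[in_fp], j = JJ2[in_fp] - nf,
                                x = rep(1, sum(in_fp)), dims = c(nf, np))
  list(fem = ctx, dofs = dofs, nf = nf,
       A_ff = A_ff, Kff_t = Kff_t, A_fp = A_fp, Kfp_t = Kfp_t,
       H = H, radius = radius, esize = esize)
}

# condensed blocks for per-element moduli E (pattern reused, values swapped)
assemble_blocks <- function(ictx, E) {
  Kff <- ictx$Kff_t
  Kff@x <- as.numeric(ictx$A_ff %*% E)
  Kfp <- ictx$Kfp_t
  Kfp@x <- as.numeric(ictx$A_fp %*% E)
  list(Kff = Kff, Kfp = Kfp)
}

# forward solve within the inversion loop; chol is reused/updated in place
inversion_forward <- function(ictx, material, chol = NULL) {
  E <- material$rho^material$penal * material$E0
  blocks <- assemble_blocks(ictx, E)
  rhs <- -as.numeric(blocks$Kfp %*% ictx$dofs$values)
  chol <- if (is.null(chol))
    Matrix::Cholesky(blocks$Kff, LDL = FALSE, super = TRUE) else
    Matrix::update(chol, blocks$Kff)
  uf <- as.numeric(Matrix::solve(chol, rhs))
  u <- numeric(ictx$fem$ndof)
  u[ictx$dofs$free] <- uf
  u[ictx$dofs$prescribed] <- ictx$dofs$values
  list(u = u, uf = uf, chol = chol)
}

#' Adjoint sensitivity of the mismatch surrogate
#'
#' Computes the derivative of the smooth (p-norm) mismatch surrogate with
#' respect to every element density through one adjoint solve: with
#' `K lambda = dF/du` on the free degrees of freedom (zero at prescribed
#' ones), the sensitivity is `dF/drho_k = -lambda' (dK/drho_k) u`, where for
#' the linear density law `dK/drho_k` is the element's unit-modulus
#' stiffness scaled by `p rho^(p-1) E0`.
#'
#' @param problem an [inverse_problem()].
#' @param rho density vector at which to differentiate; defaults to the
#'   problem's material densities.
#' @return per-element sensitivity vector.
#' @export
objective_gradient <- function(problem, rho = NULL) {
  stopifnot(inherits(problem, "inverse_problem"))
  material <- problem$material
  if (!is.null(rho)) material <- material_field(rho, E0 = material$E0,
                                                nu = material$nu,
                                                penal = material$penal,
                                                rho_min = material$rho_min)
  ictx <- inversion_context(problem$mesh, material$nu, problem$bc,
                            problem$settings)
  fwd <- inversion_forward(ictx, material)
  adjoint_gradient(problem, ictx, material, fwd)
}

# shared adjoint computation given a forward solution
adjoint_gradient <- function(problem, ictx, material, fwd) {
  dim <- ictx$fem$dim
  wdof <- rep(problem$weights, each = dim)
  uexp <- as.vector(t(problem$measured))
  r_f <- fwd$uf - uexp[ictx$dofs$free]
  g_f <- surrogate_gradient_r(r_f, wdof[ictx$dofs$free],
                              problem$settings$aggregation_exponent)
  lam <- numeric(ictx$fem$ndof)
  lam[ictx$dofs$free] <- as.numeric(Matrix::solve(fwd$chol, g_f))
  edof <- ictx$fem$edof
  Ue <- matrix(fwd$u[edof], nrow = nrow(edof))
  Le <- matrix(lam[edof], nrow = nrow(edof))
  scale <- material$penal * material$rho^(material$penal - 1) * material$E0
  if (!is.null(ictx$fem$Ke1)) {
    g <- -rowSums((Le %*% ictx$fem$Ke1) * Ue) * scale
  } else {
    nde <- ictx$fem$nde
    M <- Le[, rep(seq_len(nde), times = nde), drop = FALSE] *
      Ue[, rep(seq_len(nde), each = nde), drop = FALSE]
    g <- -rowSums(M * t(ictx$fem$KeAll)) * scale
  }
  g
}

#' Run the stiffness inversion
#'
#' Iterates forward solve, mismatch evaluation, adjoint sensitivity, cone
#' filtering and a move-limited density update until the relative change of
#' the surrogate objective stays below the tolerance for 5 consecutive
#' iterations or the iteration budget is exhausted. Each update is accepted
#' only if it reduces the surrogate (backtracking on the step size), so the
#' accepted-objective trace is non-increasing. Returns the best density map
#' found, with `converged = FALSE` if the loop stalls or runs out of
#' iterations.
#'
#' @param problem an [inverse_problem()].
#' @param verbose print a one-line progress summary every 10 iterations.
#' @return list with `material` (final [material_field()]) and `state`
#'   (class `optimization_state`: final densities, objective values, full
#'   history data frame, `converged` flag).
#' @export
run_inversion <- function(problem, verbose = FALSE) {
  stopifnot(inherits(problem, "inverse_problem"))
  st <- problem$settings
  material <- problem$material
  ictx <- inversion_context(problem$mesh, material$nu, problem$bc, st)
  dim <- ictx$fem$dim
  wdof <- rep(problem$weights, each = dim)
  uexp_f <- as.vector(t(problem$measured))[ictx$dofs$free]
  w_f <- wdof[ictx$dofs$free]
  eval_obj <- function(uf) {
    a <- abs(uf - uexp_f) * w_f
    M <- max(a)
    if (M == 0) return(c(0, 0))
    c(M, M * sum((a / M)^st$aggregation_exponent)^(1 / st$aggregation_exponent))
  }
  rho <- material$rho
  ne <- length(rho)
  beta <- st$smoothness_weight
  reg_val <- function(rho) {
    if (beta == 0) return(0)
    d <- rho - as.numeric(ictx$H %*% rho)
    beta * mean(d * d)
  }
  reg_grad <- function(rho) {
    if (beta == 0) return(numeric(ne))
    d <- rho - as.numeric(ictx$H %*% rho)
    as.numeric(beta * (2 / ne) * (d - Matrix::crossprod(ictx$H, d)))
  }
  fwd <- inversion_forward(ictx, material)
  ob <- eval_obj(fwd$uf)
  total <- ob[2] + reg_val(rho)
  history <- data.frame(iteration = 0L, objective = ob[1], surrogate = ob[2],
                        total = total, step = 0)
  best_rho <- rho; best_total <- total; best_obj <- ob[1]
  calm <- 0L
  converged <- FALSE
  alpha <- NULL
  rho_prev <- NULL; rho_prev2 <- NULL; gf_prev <- NULL
  rng <- 1 - material$rho_min
  L <- rho - 0.5 * rng; U <- rho + 0.5 * rng  # MMA asymptotes
  for (it in seq_len(st$max_iterations)) {
    if (total <= .Machine$double.eps) { converged <- TRUE; break }
    g <- adjoint_gradient(problem, ictx, material, fwd)
    gf <- as.numeric(ictx$H %*% g) + reg_grad(rho)
    gmax <- max(abs(gf))
    if (gmax == 0) { converged <- TRUE; break }
    if (st$optimizer == "mma") {
      if (!is.null(rho_prev2)) {
        osc <- (rho - rho_prev) * (rho_prev - rho_prev2)
        gam <- ifelse(osc > 0, 1.2, ifelse(osc < 0, 0.7, 1))
        L <- rho - gam * (rho_prev - L)
        U <- rho + gam * (U - rho_prev)
        L <- pmin(pmax(L, rho - 10 * rng), rho - 0.01 * rng)
        U <- pmax(pmin(U, rho + 10 * rng), rho + 0.01 * rng)
      }
    } else {
      # spectral (Barzilai-Borwein) step length for the fallback rule
      alpha_ml <- st$move_limit / gmax
      if (is.null(rho_prev)) alpha <- alpha_ml
      else {
        s <- rho - rho_prev
        yv <- gf - gf_prev
        den <- sum(s * yv)
        alpha <- if (den > 1e-300) sum(s * s) / den else 2 * alpha
        alpha <- min(max(alpha, 1e-3 * alpha_ml), 50 * alpha_ml)
      }
    }
    rho_prev2 <- rho_prev; rho_prev <- rho; gf_prev <- gf
    accepted <- FALSE
    move_scale <- 1
    for (try in seq_len(15L)) {
      rho_new <- if (st$optimizer == "mma")
        mma_candidate(rho, gf, L, U, st$move_limit * move_scale,
                      material$rho_min, rng) else
        update_densities(rho, gf, st, rho_min = material$rho_min,
                         step_size = alpha)
      if (max(abs(rho_new - rho)) == 0) break
      mat_new <- material_field(rho_new, E0 = material$E0, nu = material$nu,
                                penal = material$penal,
                                rho_min = material$rho_min)
      fwd_new <- inversion_forward(ictx, mat_new, fwd$chol)
      ob_new <- eval_obj(fwd_new$uf)
      total_new <- ob_new[2] + reg_val(rho_new)
      if (total_new < total) {
        accepted <- TRUE
        rel <- (total - total_new) / max(total, .Machine$double.eps)
        rho <- rho_new; material <- mat_new; fwd <- fwd_new
        ob <- ob_new; total <- total_new
        calm <- if (rel < st$objective_tolerance) calm + 1L else 0L
        break
      }
      move_scale <- move_scale / 2
      if (st$optimizer == "mma") {  # pull asymptotes in as well
        L <- (L + rho) / 2; U <- (U + rho) / 2
      } else alpha <- alpha / 2
    }
    history <- rbind(history,
                     data.frame(iteration = it, objective = ob[1],
                                surrogate = ob[2], total = total,
                                step = move_scale))
    if (total < best_total) {
      best_total <- total; best_rho <- rho; best_obj <- ob[1]
    }
    if (verbose && it %% 10L == 0L)
      message(sprintf("iter %3d  max|mismatch| %.3e mm  surrogate %.3e",
                      it, ob[1], ob[2]))
    if (!accepted) {
      # no admissible step descends: first-order stationary within the
      # line-search resolution
      converged <- TRUE
      break
    }
    if (calm >= 5L) { converged <- TRUE; break }
  }
  final <- material_field(best_rho, E0 = material$E0, nu = material$nu,
                          penal = material$penal, rho_min = material$rho_min)
  state <- structure(list(iteration = max(history$iteration),
                          rho = best_rho, objective = best_obj,
                          surrogate = best_total, history = history,
                          converged = converged),
                     class = "optimization_state")
  list(material = final, state = state)
}

#' @export
print.optimization_state <- function(x, ...) {
  cat("<optimization_state> ", x$iteration, " iterations, max|mismatch| ",
      format(x$objective, digits = 4), " mm, ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  invisible(x)
}

#' Normalize a density map to mean relative stiffness 0.5
#'
#' Under pure-displacement boundary data the stiffness scale is
#' unidentifiable, so maps are compared after rescaling to a common mean
#' relative stiffness of 0.5: `rho * 0.5 / mean(rho)`, clipped to `(0, 1]`.
#' Region-mean ratios are unchanged by the rescaling (up to clipping).
#'
#' @param rho density/relative-stiffness vector (or array).
#' @param target_mean mean after rescaling (default 0.5).
#' @return rescaled vector of the same shape.
#' @export
normalize_relative_stiffness <- function(rho, target_mean = 0.5) {
  m <- mean(rho)
  if (!is.finite(m) || m <= 0) stop("density map must have a positive mean")
  pmin(rho * (target_mean / m), 1)
}

#' Region-mean stiffness and pairwise ratios
#'
#' @param stiffness per-element stiffness (or density) vector.
#' @param labels per-element region labels (factor/character/integer); at
#'   least two nonempty regions.
#' @return list with `means` (named region means) and `ratios` (matrix of
#'   `means[i] / means[j]`).
#' @export
region_ratio <- function(stiffness, labels) {
  if (length(stiffness) != length(labels))
    stop("one label per element required")
  labels <- as.character(labels)
  means <- tapply(stiffness, labels, mean)
  if (length(means) < 2) stop("need at least two nonempty regions")
  ratios <- outer(means, means, `/`)
  list(means = means, ratios = ratios)
}
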