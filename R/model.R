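# ---------------------------------------------------------------------------
# Linear ODE transcription model.
#
# Each gene i follows dy_i/dt = alpha_i + sum_j beta_ij y_j
#                               + sum_k gamma_ik dv_k - delta_i y_i,
# where (alpha, beta, gamma) of gene i is the effective regulation of the
# operon containing i, and dv_k = v_k - v_k^opt. In matrix form
#   dy/dt = a + (B - D) y + G dv,  D = diag(delta),
# so the steady state solves (D - B) y = a + G dv.
# ---------------------------------------------------------------------------

# Build the dense model matrices for a genome: delta, alpha, B (gene x gene),
# G (gene x factor), plus index bookkeeping. Internal work-horse shared by
# steady_state, simulate_dynamics and the annealer (which maintains an
# incrementally updated copy).
model_matrices <- function(g, factors = NULL) {
  gene_ids <- names(g$genes)
  n <- length(gene_ids)
  delta <- vapply(g$genes, `[[`, 0, "delta")
  alpha <- stats::setNames(numeric(n), gene_ids)
  B <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  gam_list <- vector("list", length(g$operons))
  names(gam_list) <- names(g$operons)
  for (op in g$operons) {
    rf <- effective_regulation(g, op)
    alpha[op$genes] <- rf$alpha
    if (length(rf$beta)) {
      bad <- setdiff(names(rf$beta), gene_ids)
      if (length(bad))
        stop("operon '", op$id, "': beta regulator(s) not in genome: ",
             paste(bad, collapse = ", "))
      B[op$genes, names(rf$beta)] <-
        matrix(rf$beta, nrow = length(op$genes), ncol = length(rf$beta),
               byrow = TRUE)
    }
    gam_list[[op$id]] <- rf$gamma
  }
  if (is.null(factors))
    factors <- sort(unique(unlist(lapply(gam_list, names))))
  G <- matrix(0, n, length(factors), dimnames = list(gene_ids, factors))
  if (length(factors)) {
    for (op in g$operons) {
      gm <- gam_list[[op$id]]
      if (length(gm))
        G[op$genes, names(gm)] <-
          matrix(gm, nrow = length(op$genes), ncol = length(gm), byrow = TRUE)
    }
  }
  list(gene_ids = gene_ids, delta = delta, alpha = alpha, B = B, G = G)
}

# dv vector aligned to the model's factor columns; factors the model never
# senses (all-zero gamma column cannot occur here since columns come from
# nonempty gammas) are fine to omit from env only if their gamma is absent.
.model_dv <- function(mm, env) {
  factors <- colnames(mm$G)
  if (!length(factors)) return(numeric(0))
  dv <- stats::setNames(numeric(length(factors)), factors)
  known <- intersect(factors, names(env$dv))
  dv[known] <- env$dv[known]
  missing <- setdiff(factors, names(env$dv))
  if (length(missing))
    stop("environment lacks factor(s) with nonzero gamma: ",
         paste(missing, collapse = ", "))
  dv
}

# steady-state solve on prebuilt matrices; rhs may have several columns
# (one per environment). Returns the raw (unclipped) solution matrix.
.steady_solve <- function(mm, rhs, cond_threshold = 1e12) {
  A <- diag(mm$delta, nrow = length(mm$delta)) - mm$B
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / cond_threshold) {
    rs <- rowSums(abs(mm$B)) - mm$delta
    worst <- order(rs, decreasing = TRUE)[seq_len(min(5L, length(rs)))]
    stop("singular or ill-conditioned transcription system (rcond = ",
         signif(rc, 3), "); most implicated genes: ",
         paste(mm$gene_ids[worst], collapse = ", "))
  }
  solve(A, rhs)
}

#' Steady-state expression under an environment
#'
#' Solves the transcription model at equilibrium, `(D - B) y = a + G dv`,
#' where every gene's regulatory row comes from the effective regulation of
#' its operon. Negative components (possible in a linear model) are clipped
#' to zero after solving; the genes affected are reported in the
#' `"clipped"` attribute of the result.
#'
#' @param g A [gtrn()] object.
#' @param env A [environment_state()].
#' @param clip Clip negative components to 0 (default `TRUE`).
#' @param cond_threshold Reciprocal-condition threshold above which the
#'   system is declared ill-conditioned (default `1e12`).
#' @return Named numeric vector of steady-state expression, one entry per
#'   gene, with attribute `clipped` (character vector of clipped gene ids).
#' @export
steady_state <- function(g, env, clip = TRUE, cond_threshold = 1e12) {
  mm <- model_matrices(g)
  dv <- .model_dv(mm, env)
  rhs <- mm$alpha + if (length(dv)) drop(mm$G %*% dv) else 0
  y <- drop(.steady_solve(mm, rhs, cond_threshold))
  names(y) <- mm$gene_ids
  clipped <- character()
  if (clip && any(y < 0)) {
    clipped <- mm$gene_ids[y < 0]
    y[y < 0] <- 0
  }
  attr(y, "clipped") <- clipped
  y
}

#' Steady-state expression profile across environments
#'
#' @param g A [gtrn()] object.
#' @param envs List of [environment_state()] objects.
#' @param clip Clip negative components to 0 (default `TRUE`).
#' @return A gene x environment matrix of class `expression_profile`;
#'   column names are environment ids (or `env1..envN`).
#' @export
expression_profile <- function(g, envs, clip = TRUE) {
  if (inherits(envs, "gtrn_environment")) envs <- list(envs)
  mm <- model_matrices(g)
  nE <- length(envs)
  rhs <- matrix(mm$alpha, nrow = length(mm$gene_ids), ncol = nE)
  for (j in seq_len(nE)) {
    dv <- .model_dv(mm, envs[[j]])
    if (length(dv)) rhs[, j] <- rhs[, j] + drop(mm$G %*% dv)
  }
  Y <- .steady_solve(mm, rhs)
  Y <- matrix(Y, nrow = length(mm$gene_ids))
  if (clip) Y[Y < 0] <- 0
  ids <- vapply(seq_len(nE), function(j) {
    id <- envs[[j]]$id
    if (is.na(id)) paste0("env", j) else id
  }, "")
  dimnames(Y) <- list(mm$gene_ids, make.unique(ids))
  class(Y) <- c("expression_profile", class(Y))
  Y
}

#' Stability of the transcription dynamics
#'
#' @param g A [gtrn()] object.
#' @return The spectral abscissa (largest real part of the eigenvalues) of
#'   `B - D`; negative means the linear dynamics are stable.
#' @export
spectral_abscissa <- function(g) {
  mm <- model_matrices(g)
  M <- mm$B - diag(mm$delta, nrow = length(mm$delta))
  max(Re(eigen(M, only.values = TRUE)$values))
}

#' Simulate transcription dynamics
#'
#' Integrates the linear mRNA ODE from an initial state over a time grid.
#' If the system is unstable (an eigenvalue of `B - D` with nonnegative real
#' part) a warning is issued and the result carries attribute
#' `unstable = TRUE`; the trajectory is still returned.
#'
#' @param g A [gtrn()] object.
#' @param env A [environment_state()].
#' @param y0 Named (or positionally ordered) initial expression vector.
#' @param t_grid Strictly increasing numeric vector of times starting at 0
#'   (hours).
#' @return A `length(t_grid) x n_genes` matrix of expression values with
#'   `time` attribute `t_grid`; rows follow `t_grid`.
#' @export
simulate_dynamics <- function(g, env, y0, t_grid) {
  if (length(t_grid) < 2L || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing and start at 0")
  mm <- model_matrices(g)
  n <- length(mm$gene_ids)
  if (length(y0) != n) stop("y0 must have one entry per gene")
  if (!is.null(names(y0))) {
    if (!setequal(names(y0), mm$gene_ids)) stop("y0 names do not match genes")
    y0 <- y0[mm$gene_ids]
  }
  dv <- .model_dv(mm, env)
  drive <- mm$alpha + if (length(dv)) drop(mm$G %*% dv) else 0
  M <- mm$B - diag(mm$delta, nrow = n)
  unstable <- max(Re(eigen(M, only.values = TRUE)$values)) >= 0
  if (unstable)
    warning("transcription dynamics are unstable ",
            "(eigenvalue of B - D with nonnegative real part)")
  rhs <- function(t, y, parms) list(drive + drop(M %*% y))
  sol <- deSolve::lsoda(y = as.numeric(y0), times = t_grid, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  traj <- unname(sol[, -1, drop = FALSE])
  dimnames(traj) <- list(NULL, mm$gene_ids)
  attr(traj, "time") <- t_grid
  attr(traj, "unstable") <- unstable
  traj
}

#' Response time to an environmental shift
#'
#' Time for the transcriptome, starting at the steady state of `env_from`,
#' to first remain within `epsilon` of the new steady state after switching
#' to `env_to`: the last time the max-norm deviation from the new steady
#' state exceeds `epsilon * ||y_to - y_from||_inf`. Returns 0 when the two
#' steady states coincide.
#'
#' @param g A [gtrn()] object.
#' @param env_from,env_to [environment_state()] objects.
#' @param epsilon Convergence fraction in (0, 1); default `0.05`.
#' @return Response time in hours.
#' @export
response_time <- function(g, env_from, env_to, epsilon = 0.05) {
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must be in (0, 1)")
  mm <- model_matrices(g)
  n <- length(mm$gene_ids)
  M <- mm$B - diag(mm$delta, nrow = n)
  ev <- eigen(M)
  if (max(Re(ev$values)) >= 0)
    stop("dynamics do not converge: unstable transcription system")
  y_from <- steady_state(g, env_from, clip = FALSE)
  y_to <- steady_state(g, env_to, clip = FALSE)
  d0 <- max(abs(y_to - y_from))
  if (d0 == 0) return(0)
  Vinv_d <- solve(ev$vectors, as.complex(y_from - y_to))
  dev <- function(t) {
    # ||y(t) - y_to||_inf with y(t) - y_to = V exp(L t) V^-1 (y_from - y_to)
    max(abs(Re(ev$vectors %*% (exp(ev$values * t) * Vinv_d))))
  }
  thr <- epsilon * d0
  t_max <- log(1 / (epsilon * 1e-3)) / min(-Re(ev$values))
  grid <- seq(0, t_max, length.out = 4000L)
  above <- vapply(grid, dev, 0) > thr
  if (!any(above)) return(0)
  k <- max(which(above))
  if (k == length(grid))
    stop("trajectory did not settle within the search horizon")
  stats::uniroot(function(t) dev(t) - thr, c(grid[k], grid[k + 1L]),
                 tol = 1e-10)$root
}
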