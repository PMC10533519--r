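# Laplace marginal-likelihood machinery: the random effects are
# profiled out by an inner Newton solver (exact analytic block
# Hessians per group level), and the fixed effects plus variance
# components are optimized on the marginal objective
#   F = -ll(b-hat) + b-hat' D^-1 b-hat / 2 + sum(log sigma_b)
#       + 0.5 * sum(log det A_level) + fixed-effect penalty,
# with A_level the curvature block of one group level's random
# effects. The outer problem is low-dimensional, so finite-difference
# gradients are affordable; inner solves are warm-started and the
# envelope property (dF/db = 0 at the profiled optimum) keeps F
# insensitive to inner tolerance.

# flat list of random effects of one grouping factor
ranef_effects <- function(design, layout, g) {
  effs <- list()
  for (tg in names(layout$ranef[[g]])) {
    for (cn in names(layout$ranef[[g]][[tg]])) {
      info <- layout$ranef[[g]][[tg]][[cn]]
      effs[[length(effs) + 1L]] <- list(
        target = tg, key = info$key, par = info$par, col = info$col,
        x = design$targets[[tg]]$X[, info$col])
    }
  }
  effs
}

# per-level curvature blocks A (n_groups x m x m), prior included
level_blocks <- function(design, layout, pieces, g, sigma_b,
                         effs = NULL) {
  if (is.null(effs)) effs <- ranef_effects(design, layout, g)
  ridx <- design$random[[g]]$index
  n_groups <- design$random[[g]]$n_groups
  m <- length(effs)
  pairs <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  M <- matrix(0, design$n, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    j <- pairs[i, 1]; k <- pairs[i, 2]
    q <- cross_d2(pieces, effs[[j]]$target, effs[[k]]$target,
                  design$n)
    M[, i] <- -q * effs[[j]]$x * effs[[k]]$x
  }
  S <- rowsum(M, ridx)
  blocks <- array(0, dim = c(n_groups, m, m))
  for (i in seq_len(nrow(pairs))) {
    j <- pairs[i, 1]; k <- pairs[i, 2]
    blocks[, j, k] <- S[, i]
    blocks[, k, j] <- S[, i]
  }
  prior <- 1 / vapply(effs, function(e) sigma_b[[e$key]],
                      numeric(1))^2
  for (j in seq_len(m)) blocks[, j, j] <- blocks[, j, j] + prior[j]
  list(blocks = blocks, effs = effs, prior = prior)
}

# joint penalized objective restricted to the random-effect part
ranef_penalty <- function(theta, sigma_b, effs_all) {
  val <- 0
  for (effs in effs_all) {
    for (e in effs) {
      val <- val + 0.5 * sum(theta[e$par]^2) / sigma_b[[e$key]]^2
    }
  }
  val
}

# Damped Newton profiling of the random effects; block Hessians are
# refreshed once per sweep. Returns theta with updated b, plus the
# pieces and blocks at the solution (for reuse by the caller).
inner_newton <- function(design, layout, theta, sigma_b, effs_all,
                         max_sweeps = 25, tol = 1e-6, quick = FALSE,
                         polish = TRUE) {
  pieces <- ll_pieces(design, layout, theta, grad = TRUE, hess = TRUE)
  lbs <- NULL
  if (length(layout$ranef) == 0) {
    return(list(theta = theta, pieces = pieces, lbs = NULL))
  }
  # quick: one undamped Newton step from a warm start, used inside
  # finite-difference gradient evaluations where the perturbation is
  # tiny and the step error is second order
  if (quick) max_sweeps <- 1L
  f_cur <- if (quick) Inf else {
    -sum(pieces$ll) + ranef_penalty(theta, sigma_b, effs_all)
  }
  refresh <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    if (refresh) {
      pieces <- ll_pieces(design, layout, theta, grad = TRUE,
                          hess = TRUE)
    }
    refresh <- TRUE
    lbs <- list()
    max_step <- 0
    for (gi in seq_along(layout$ranef)) {
      g <- names(layout$ranef)[gi]
      effs <- effs_all[[gi]]
      lb <- level_blocks(design, layout, pieces, g, sigma_b, effs)
      lbs[[g]] <- lb
      m <- length(effs)
      ridx <- design$random[[g]]$index
      gr <- matrix(0, design$random[[g]]$n_groups, m)
      for (j in seq_len(m)) {
        contrib <- rowsum(pieces$deta[[effs[[j]]$target]] *
                          effs[[j]]$x, ridx)[, 1]
        gr[, j] <- -contrib +
          theta[effs[[j]]$par] / sigma_b[[effs[[j]]$key]]^2
      }
      # saddle-free modified Newton: negative curvature directions are
      # flipped (|eigenvalue| with a floor), so the step is always a
      # descent direction and the profiler escapes indefinite regions
      delta <- matrix(0, nrow(gr), m)
      for (lev in seq_len(nrow(gr))) {
        A <- lb$blocks[lev, , , drop = TRUE]
        if (m == 1) A <- matrix(A, 1, 1)
        ev <- eigen(A, symmetric = TRUE)
        lam <- pmax(abs(ev$values), 1e-2)
        delta[lev, ] <- ev$vectors %*%
          ((crossprod(ev$vectors, gr[lev, ]))[, 1] / lam)
      }
      if (quick) {
        for (j in seq_len(m)) {
          theta[effs[[j]]$par] <- theta[effs[[j]]$par] - delta[, j]
        }
        next
      }
      step <- 1
      repeat {
        th_new <- theta
        for (j in seq_len(m)) {
          th_new[effs[[j]]$par] <- theta[effs[[j]]$par] -
            step * delta[, j]
        }
        f_new <- -sum(ll_pieces(design, layout, th_new)$ll) +
          ranef_penalty(th_new, sigma_b, effs_all)
        if (is.finite(f_new) && f_new <= f_cur + 1e-10) {
          theta <- th_new
          f_cur <- f_new
          max_step <- max(max_step, max(abs(step * delta)))
          break
        }
        step <- step / 2
        if (step < 1e-4) break
      }
    }
    if (max_step < tol) break
  }
  # final refresh so the returned pieces/blocks match theta exactly
  pieces <- ll_pieces(design, layout, theta, grad = TRUE, hess = TRUE)
  lbs <- list()
  for (gi in seq_along(layout$ranef)) {
    g <- names(layout$ranef)[gi]
    lbs[[g]] <- level_blocks(design, layout, pieces, g, sigma_b,
                             effs_all[[gi]])
  }

  # mode resolution: the per-level inner problems can be multimodal on
  # the rate-asymptote ridge. Levels whose curvature block has a
  # near-zero or negative eigenvalue are restarted from zero and the
  # better branch is kept per level (the inner objective separates by
  # level, so branches may be mixed).
  if (polish && !quick) {
    for (gi in seq_along(layout$ranef)) {
      g <- names(layout$ranef)[gi]
      effs <- effs_all[[gi]]
      m <- length(effs)
      lb <- lbs[[g]]
      mineig <- apply(lb$blocks, 1, function(A) {
        if (m == 1) A <- matrix(A, 1, 1)
        min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
      })
      flagged <- which(mineig < 0.5)
      if (length(flagged) == 0) next
      ridx <- design$random[[g]]$index
      level_obj <- function(th, pc) {
        pen <- matrix(0, design$random[[g]]$n_groups, 1)
        for (j in seq_len(m)) {
          pen <- pen + 0.5 * th[effs[[j]]$par]^2 /
            sigma_b[[effs[[j]]$key]]^2
        }
        -rowsum(pc$ll, ridx)[, 1] + pen[, 1]
      }
      obj_cur <- level_obj(theta, pieces)
      th_try <- theta
      for (j in seq_len(m)) {
        th_try[effs[[j]]$par[flagged]] <- 0
      }
      alt <- inner_newton(design, layout, th_try, sigma_b, effs_all,
                          max_sweeps = 8, tol = tol, polish = FALSE)
      obj_alt <- level_obj(alt$theta, alt$pieces)
      better <- which(obj_alt < obj_cur - 1e-8)
      take <- intersect(better, flagged)
      if (length(take) > 0) {
        for (j in seq_len(m)) {
          theta[effs[[j]]$par[take]] <- alt$theta[effs[[j]]$par[take]]
        }
        settle <- inner_newton(design, layout, theta, sigma_b,
                               effs_all, max_sweeps = 4, tol = tol,
                               polish = FALSE)
        theta <- settle$theta
        pieces <- settle$pieces
        lbs <- settle$lbs
      }
    }
  }
  list(theta = theta, pieces = pieces, lbs = lbs)
}


# One undamped Newton step from a warm, mode-resolved base, reusing
# the base curvature blocks (stale by O(h), giving an O(h^2) step
# error), then one refresh for the log-determinant blocks. Used only
# inside finite-difference gradient loops.
inner_quick <- function(design, layout, theta, sigma_b, effs_all,
                        base_lbs) {
  pieces <- ll_pieces(design, layout, theta, grad = TRUE, hess = TRUE)
  for (gi in seq_along(layout$ranef)) {
    g <- names(layout$ranef)[gi]
    effs <- effs_all[[gi]]
    lb <- base_lbs[[g]]
    m <- length(effs)
    ridx <- design$random[[g]]$index
    gr <- matrix(0, design$random[[g]]$n_groups, m)
    for (j in seq_len(m)) {
      contrib <- rowsum(pieces$deta[[effs[[j]]$target]] *
                        effs[[j]]$x, ridx)[, 1]
      gr[, j] <- -contrib +
        theta[effs[[j]]$par] / sigma_b[[effs[[j]]$key]]^2
    }
    for (lev in seq_len(nrow(gr))) {
      A <- lb$blocks[lev, , , drop = TRUE]
      if (m == 1) A <- matrix(A, 1, 1)
      d <- tryCatch(
        backsolve(chol(A), forwardsolve(t(chol(A)), gr[lev, ])),
        error = function(e) {
          ev <- eigen(A, symmetric = TRUE)
          lam <- pmax(abs(ev$values), 1e-2)
          as.vector(ev$vectors %*%
                    (crossprod(ev$vectors, gr[lev, ])[, 1] / lam))
        })
      for (j in seq_len(m)) {
        theta[effs[[j]]$par[lev]] <- theta[effs[[j]]$par[lev]] - d[j]
      }
    }
  }
  pieces <- ll_pieces(design, layout, theta, grad = TRUE, hess = TRUE)
  lbs <- list()
  for (gi in seq_along(layout$ranef)) {
    g <- names(layout$ranef)[gi]
    lbs[[g]] <- level_blocks(design, layout, pieces, g, sigma_b,
                             effs_all[[gi]])
  }
  list(theta = theta, pieces = pieces, lbs = lbs)
}

# marginal negative log-likelihood at a fixed-parameter vector phi
# (beta blocks + log_sigma + log sigma_b), profiling b via the warm
# state kept in `state`
marginal_nll <- function(phi, design, layout, prior, state, phi_map,
                         quick = FALSE) {
  theta <- state$theta
  theta[phi_map$fixed_idx] <- phi[seq_along(phi_map$fixed_idx)]
  sigma_b <- state$sigma_b
  if (length(phi_map$keys) > 0) {
    sigma_b[phi_map$keys] <-
      exp(phi[length(phi_map$fixed_idx) + seq_along(phi_map$keys)])
    sigma_b <- pmin(pmax(sigma_b, 1e-3), 10)
  }
  sol <- if (quick && !is.null(state$lbs)) {
    inner_quick(design, layout, theta, sigma_b, state$effs_all,
                state$lbs)
  } else {
    inner_newton(design, layout, theta, sigma_b, state$effs_all,
                 quick = quick)
  }
  theta <- sol$theta
  state$theta <- theta
  if (!quick) state$lbs <- sol$lbs
  val <- -sum(sol$pieces$ll)
  psd <- prior_sds(design, layout, prior)
  fx <- phi_map$fixed_idx
  center <- rep(0, layout$n_par)
  center[layout$log_sigma] <- prior$log_sigma_center
  val <- val + 0.5 * sum(((theta[fx] - center[fx]) / psd[fx])^2)
  val <- val + ranef_penalty(theta, sigma_b, state$effs_all)
  for (gi in seq_along(layout$ranef)) {
    g <- names(layout$ranef)[gi]
    lb <- sol$lbs[[g]]
    if (is.null(lb)) {
      pieces <- sol$pieces
      lb <- level_blocks(design, layout, pieces, g, sigma_b,
                         state$effs_all[[gi]])
    }
    m <- length(lb$effs)
    n_groups <- design$random[[g]]$n_groups
    for (j in seq_len(m)) {
      val <- val + n_groups * log(sigma_b[[lb$effs[[j]]$key]])
    }
    for (lev in seq_len(n_groups)) {
      A <- lb$blocks[lev, , , drop = TRUE]
      if (m == 1) A <- matrix(A, 1, 1)
      # smooth handling of non-concave stalls of the inner profiler:
      # eigenvalues are floored for the log-determinant and the
      # violation is penalized, keeping the objective continuous so
      # finite-difference gradients steer away rather than cliff
      ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
      floor_ev <- 1e-4
      low <- ev < floor_ev
      if (any(low)) {
        val <- val + 1e3 * sum(floor_ev - ev[low])
        ev[low] <- floor_ev
      }
      val <- val + 0.5 * sum(log(ev))
    }
  }
  val
}

# forward-difference gradient; the envelope property makes F smooth in
# phi, and the induced optimum shift is O(h), far below the standard
# errors
marginal_grad <- function(phi, design, layout, prior, state, phi_map,
                          f0 = NULL, h = 1e-6, active = NULL) {
  if (is.null(active)) active <- seq_along(phi)
  base_theta <- state$theta
  if (is.null(f0)) {
    f0 <- marginal_nll(phi, design, layout, prior, state, phi_map)
    base_theta <- state$theta
  }
  g <- numeric(length(active))
  for (jj in seq_along(active)) {
    j <- active[jj]
    hp <- h * (1 + abs(phi[j]))
    pp <- phi; pp[j] <- pp[j] + hp
    state$theta <- base_theta
    g[jj] <- (marginal_nll(pp, design, layout, prior, state,
                           phi_map, quick = TRUE) - f0) / hp
  }
  state$theta <- base_theta
  g
}

# Full Laplace-marginal fit, starting from a joint penalized optimum.
laplace_fit <- function(design, layout, prior, theta0, sigma_b0,
                        control = list()) {
  fixed_idx <- c(unlist(layout$beta, use.names = FALSE),
                 layout$log_sigma)
  keys <- ranef_keys(layout)
  phi_map <- list(fixed_idx = fixed_idx, keys = keys)
  state <- new.env(parent = emptyenv())
  state$theta <- theta0
  state$sigma_b <- sigma_b0
  state$effs_all <- lapply(names(layout$ranef), function(g) {
    ranef_effects(design, layout, g)
  })
  phi0 <- c(theta0[fixed_idx], log(pmax(sigma_b0[keys], 1e-3)))

  # SDs below 0.02 on the log scale are practically zero; bounding
  # there keeps the optimizer off the flat tail of the profile
  lower <- c(rep(-30, length(fixed_idx)), rep(log(0.02), length(keys)))
  upper <- c(rep(30, length(fixed_idx)), rep(log(10), length(keys)))

  nll <- function(p, quick = FALSE) {
    marginal_nll(p, design, layout, prior, state, phi_map,
                 quick = quick)
  }
  ngrad <- function(p, f0 = NULL) {
    marginal_grad(p, design, layout, prior, state, phi_map, f0 = f0)
  }
  fd_hess <- function(p, g0) {
    np <- length(p)
    H <- matrix(0, np, np)
    for (j in seq_len(np)) {
      h <- 1e-4 * (1 + abs(p[j]))
      pp <- p; pp[j] <- pp[j] + h
      H[, j] <- (ngrad(pp) - g0) / h
    }
    (H + t(H)) / 2
  }
  clamp <- function(p) pmin(pmax(p, lower), upper)

  # damped saddle-free Newton on the marginal objective: the
  # finite-difference Hessian is refreshed every few steps, negative
  # curvature is flipped so every step is a descent direction, and
  # the final Hessian doubles as the Wald covariance
  max_iter <- control$outer_iter %||% 30L
  tol_step <- control$outer_tol %||% 1e-4
  phi <- clamp(phi0)
  f_cur <- nll(phi)
  base_theta <- state$theta
  base_lbs <- state$lbs
  g <- ngrad(phi, f0 = f_cur)
  H <- NULL
  ev <- NULL
  stale <- 0L
  n_outer <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_outer <- n_outer + 1L
    if (is.null(H) || stale >= 40L) {
      state$theta <- base_theta
      state$lbs <- base_lbs
      H <- fd_hess(phi, g)
      ev <- eigen(H, symmetric = TRUE)
      stale <- 0L
    }
    lam <- pmax(abs(ev$values), 1e-3)
    step <- as.vector(ev$vectors %*%
                      (crossprod(ev$vectors, g)[, 1] / lam))
    t_ls <- 1
    improved <- FALSE
    repeat {
      cand <- clamp(phi - t_ls * step)
      state$theta <- base_theta
      state$lbs <- base_lbs
      f_new <- nll(cand)
      if (is.finite(f_new) && f_new < f_cur - 1e-10) {
        phi <- cand
        f_cur <- f_new
        base_theta <- state$theta
        base_lbs <- state$lbs
        improved <- TRUE
        break
      }
      t_ls <- t_ls / 2
      if (t_ls < 1e-2) break
    }
    state$theta <- base_theta
    state$lbs <- base_lbs
    if (!improved) {
      if (stale > 0L) {
        # retry from a fresh Hessian before giving up
        stale <- 40L
        next
      }
      converged <- TRUE  # no descent found at a fresh Hessian
      break
    }
    stale <- stale + 1L
    if (max(abs(t_ls * step)) < tol_step) {
      converged <- TRUE
      break
    }
    state$theta <- base_theta
    state$lbs <- base_lbs
    g <- ngrad(phi, f0 = f_cur)
  }
  state$theta <- base_theta
  state$lbs <- base_lbs
  nll(phi)  # leave the inner state at the optimum
  opt <- list(convergence = if (converged) 0L else 1L,
              message = if (converged) "relative convergence"
                        else "outer iteration limit reached",
              iterations = n_outer, objective = f_cur)
  theta <- state$theta
  sigma_b <- state$sigma_b
  if (length(keys) > 0) {
    sigma_b[keys] <- exp(pmin(pmax(
      phi[length(fixed_idx) + seq_along(keys)],
      log(0.02)), log(10)))
  }

  # curvature of the marginal objective at the optimum; the quick
  # profiling path is mode-stable around a mode-resolved optimum, and
  # residual pathologies are caught downstream by the joint-curvature
  # cross-check. Variance components on their bounds are excluded
  # from the inversion, and the saddle-free inverse yields usable
  # variances if a flat direction remains.
  state$theta <- theta
  g_fin <- ngrad(phi)
  state$theta <- theta
  H <- fd_hess(phi, g_fin)
  free <- which(phi > lower + 1e-6 & phi < upper - 1e-6)
  evH <- eigen(H[free, free, drop = FALSE], symmetric = TRUE)
  lamH <- pmax(abs(evH$values), 1e-6)
  covf <- evH$vectors %*% (t(evH$vectors) / lamH)
  covm <- matrix(0, length(phi), length(phi))
  covm[free, free] <- covf
  state$theta <- theta

  list(theta = theta, sigma_b = sigma_b, cov_phi = covm,
       phi = phi, fixed_idx = fixed_idx, keys = keys,
       convergence = opt$convergence, message = opt$message,
       iterations = opt$iterations, objective = opt$objective)
}
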