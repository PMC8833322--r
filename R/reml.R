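# Average-information REML for the multi-trait animal model, with an EM-REML
# fallback for proposals that leave the parameter space or decrease the
# restricted likelihood. Parameters are the (co)variance components of G0 and
# R0 directly; the AI matrix is computed analytically from working variates,
# and the score by central finite differences of the exact sparse restricted
# log-likelihood (one sparse Cholesky per evaluation).

vech_index <- function(t) {
  idx <- which(upper.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]   # (1,1),(1,2),(2,2),(1,3)...
}

pack_theta <- function(G0, R0) {
  t <- nrow(G0)
  ix <- vech_index(t)
  th <- c(G0[ix], R0[ix])
  names(th) <- c(paste0("G[", ix[, 1L], ",", ix[, 2L], "]"),
                 paste0("R[", ix[, 1L], ",", ix[, 2L], "]"))
  th
}

unpack_theta <- function(theta, t) {
  ix <- vech_index(t)
  np <- nrow(ix)
  G0 <- matrix(0, t, t); R0 <- matrix(0, t, t)
  G0[ix] <- theta[seq_len(np)];        G0[ix[, c(2L, 1L)]] <- theta[seq_len(np)]
  R0[ix] <- theta[np + seq_len(np)];   R0[ix[, c(2L, 1L)]] <- theta[np + seq_len(np)]
  list(G0 = G0, R0 = R0)
}

is_pd <- function(M, eps = 0) {
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) -Inf)
  min(ev) > eps
}

#' Restricted log-likelihood of the multi-trait animal model
#'
#' Evaluates the REML log-likelihood at the given variance components via the
#' mixed-model equations:
#' `-0.5 * (log|R| + log|G| + log|C| + y' P y)`, where `C` is the MME
#' coefficient matrix under the package's corner-point fixed-effect
#' constraints. The additive constant (the `-0.5 (N - p) log 2pi` term) is
#' omitted; values are comparable across variance components for a fixed
#' design, which is all REML iteration and model comparison need.
#'
#' @param design an [build_design()] object.
#' @param ainv sparse A-inverse from [a_inverse()] (its `logdet_A` attribute
#'   is used when present).
#' @param vc a [variance_components()] object.
#' @return scalar log-likelihood (up to the stated constant).
#' @export
restricted_loglik <- function(design, ainv, vc) {
  ev <- reml_eval(design, ainv_prep(ainv), vc$G0, vc$R0)
  if (!is.finite(ev$ll)) stop("restricted log-likelihood is not finite at these components")
  ev$ll
}

ainv_prep <- function(ainv) {
  ld <- attr(ainv, "logdet_A")
  AF <- Matrix::Cholesky(Matrix::forceSymmetric(ainv), LDL = FALSE)
  if (is.null(ld)) ld <- -chol_logdet(AF)
  list(ainv = ainv, AF = AF, logdetA = ld)
}

reml_eval <- function(design, ap, G0, R0, want_sol = FALSE) {
  q <- design$q; t <- design$t
  parts <- mme_parts(design, G0, R0)
  C <- mme_coefmat(parts, ap$ainv, G0, q, t)
  CF <- tryCatch(Matrix::Cholesky(C, LDL = FALSE), error = function(e) NULL)
  if (is.null(CF)) return(list(ll = -Inf))
  sol <- as.numeric(Matrix::solve(CF, parts$rhs))
  yPy <- parts$yRy - sum(sol * parts$rhs)
  logG <- t * ap$logdetA + q * as.numeric(determinant(G0, logarithm = TRUE)$modulus)
  ll <- -0.5 * (parts$logR + logG + chol_logdet(CF) + yPy)
  if (!want_sol) return(list(ll = ll))
  list(ll = ll, sol = sol, parts = parts, CF = CF)
}

# Average-information matrix and score-by-finite-differences at (G0, R0).
# Working variates: f_j = dV/dtheta_j %*% P y; AI_ij = 0.5 f_i' P f_j.
reml_ai_matrix <- function(design, ap, G0, R0, ev) {
  q <- design$q; t <- design$t
  ix <- vech_index(t)
  np <- nrow(ix)
  parts <- ev$parts
  fit <- parts$fitted_for(ev$sol)
  e <- (design$Y - fit) * design$O
  eta <- parts$Rinv_apply(e) * design$O          # P y in record space

  basis_times <- function(M, k, l) {             # M %*% (E_kl + E_lk [k!=l])
    out <- matrix(0, q, t)
    out[, k] <- out[, k] + M[, l]
    if (k != l) out[, l] <- out[, l] + M[, k]
    out
  }
  A_eta <- as.matrix(Matrix::solve(ap$AF, eta, system = "A"))  # A %*% eta

  fs <- vector("list", 2L * np)
  for (j in seq_len(np)) {
    k <- ix[j, 1L]; l <- ix[j, 2L]
    fG <- basis_times(A_eta, k, l); fG[!design$O] <- 0
    fR <- basis_times(eta,  k, l); fR[!design$O] <- 0
    fs[[j]] <- fG
    fs[[np + j]] <- fR
  }
  RHS <- vapply(fs, parts$rhs_for, numeric(parts$dim))
  SOLS <- as.matrix(Matrix::solve(ev$CF, RHS))
  AI <- matrix(0, 2L * np, 2L * np)
  Pf <- vector("list", 2L * np)
  for (j in seq_len(2L * np)) {
    fitj <- parts$fitted_for(SOLS[, j])
    Pf[[j]] <- parts$Rinv_apply((fs[[j]] - fitj) * design$O) * design$O
  }
  for (i in seq_len(2L * np)) for (j in i:(2L * np)) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(fs[[i]] * Pf[[j]])
  }
  AI
}

# natural size of each (co)variance parameter: geometric mean of the two
# traits' phenotypic variances, so ill-scaled trait pairs get sane FD steps
param_scales <- function(theta, t) {
  par <- unpack_theta(theta, t)
  ph <- pmax(diag(par$G0) + diag(par$R0), .Machine$double.eps)
  ix <- vech_index(t)
  sc <- sqrt(ph[ix[, 1L]] * ph[ix[, 2L]])
  c(sc, sc)
}

reml_score_fd <- function(design, ap, theta, t, ll0, scales, step = 1e-3) {
  np <- length(theta)
  s <- numeric(np)
  for (j in seq_len(np)) {
    h <- step * max(abs(theta[j]), 0.1 * scales[j])
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    mu <- unpack_theta(up, t); md <- unpack_theta(dn, t)
    llu <- if (is_pd(mu$G0) && is_pd(mu$R0)) reml_eval(design, ap, mu$G0, mu$R0)$ll else NA_real_
    lld <- if (is_pd(md$G0) && is_pd(md$R0)) reml_eval(design, ap, md$G0, md$R0)$ll else NA_real_
    s[j] <- if (is.finite(llu) && is.finite(lld)) (llu - lld) / (2 * h)
            else if (is.finite(llu)) (llu - ll0) / h
            else if (is.finite(lld)) (ll0 - lld) / h
            else 0
  }
  s
}

# EM-REML step expressed through the score: for the additive components,
# G0+ = G0 + (2/q) G0 S_G G0 reproduces the classical EM update
# G0+ = (u'A^-1u + tr(A^-1 C^aa)) / q; the residual side uses the record
# count analogously. Guaranteed uphill for small enough damping.
em_step <- function(theta, score, t, q, nrec) {
  ix <- vech_index(t)
  np <- nrow(ix)
  mk_S <- function(sv) {
    S <- matrix(0, t, t)
    for (j in seq_len(np)) {
      k <- ix[j, 1L]; l <- ix[j, 2L]
      if (k == l) S[k, k] <- sv[j] else S[k, l] <- S[l, k] <- sv[j] / 2
    }
    S
  }
  par <- unpack_theta(theta, t)
  S_G <- mk_S(score[seq_len(np)])
  S_R <- mk_S(score[np + seq_len(np)])
  G0n <- par$G0 + (2 / q) * (par$G0 %*% S_G %*% par$G0)
  R0n <- par$R0 + (2 / max(nrec)) * (par$R0 %*% S_R %*% par$R0)
  pack_theta(G0n, R0n)
}

#' Estimate variance components by AI-REML with EM fallback
#'
#' Iterates Newton-type updates of the additive and residual (co)variance
#' components using the average-information matrix. Any proposal that is not
#' positive definite or that decreases the restricted likelihood is replaced
#' by a (damped) EM-REML step, which preserves positive definiteness and
#' ascends the likelihood. Iteration stops when the relative parameter change
#' is below `tol_param` and the likelihood change below `tol_loglik`, or at
#' `max_iter` (in which case the result is flagged, not raised).
#'
#' @param design an [build_design()] object.
#' @param ainv sparse A-inverse from [a_inverse()].
#' @param init optional [variance_components()] starting values; the default
#'   assigns half the per-trait phenotypic variance to `G0` and half to `R0`
#'   with zero covariances.
#' @param tol_param relative parameter-change tolerance (default `1e-6`).
#' @param tol_loglik likelihood-change tolerance (default `1e-6`).
#' @param max_iter maximum iterations (default 200).
#' @param verbose print per-iteration progress.
#' @return object of class `reml_result`: `vc` (the estimates), `ai` and
#'   `ai_inv` (information matrix over the parameters and its inverse, the
#'   asymptotic covariance used for delta-method SEs), `h2` (per-trait
#'   heritability with SE), `rg`/`rp` (genetic and phenotypic correlation
#'   matrices), `loglik`, `trace` (per-iteration restricted log-likelihood and
#'   step type), `converged`, `n_iter`.
#' @export
ai_reml <- function(design, ainv, init = NULL, tol_param = 1e-6,
                    tol_loglik = 1e-6, max_iter = 200L, verbose = FALSE) {
  stopifnot(inherits(design, "mme_design"))
  t <- design$t; q <- design$q
  ap <- ainv_prep(ainv)

  if (is.null(init)) {
    vphen <- vapply(seq_len(t), function(k) stats::var(design$Y[design$O[, k], k]), 0)
    init <- variance_components(diag(vphen / 2, t), diag(vphen / 2, t),
                                traits = design$traits)
  }
  theta <- pack_theta(init$G0, init$R0)
  ev <- reml_eval(design, ap, init$G0, init$R0, want_sol = TRUE)
  if (!is.finite(ev$ll))
    stop("restricted likelihood not finite at the starting values; consider rescaling the traits")

  trace <- data.frame(iter = 0L, loglik = ev$ll, step = "init",
                      max_rel_change = NA_real_, stringsAsFactors = FALSE)
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    par <- unpack_theta(theta, t)
    AI <- reml_ai_matrix(design, ap, par$G0, par$R0, ev)
    scales <- param_scales(theta, t)
    score <- reml_score_fd(design, ap, theta, t, ev$ll, scales)

    # solve for the Newton direction in scale-free parameters so the ridge
    # (needed when the information is near-singular, e.g. correlations
    # close to 1) does not swamp small-variance traits
    AIs <- AI * tcrossprod(scales)
    ridge <- 1e-9 * mean(diag(AIs))
    delta <- tryCatch(scales * solve(AIs + diag(ridge, nrow(AIs)), scales * score),
                      error = function(e) NULL)
    step_type <- "AI"
    accepted <- FALSE
    if (!is.null(delta)) {
      for (damp in c(1, 0.5, 0.25, 0.125)) {   # shorten overshooting AI steps
        prop <- theta + damp * delta
        pp <- unpack_theta(prop, t)
        if (is_pd(pp$G0) && is_pd(pp$R0)) {
          evp <- reml_eval(design, ap, pp$G0, pp$R0, want_sol = TRUE)
          if (is.finite(evp$ll) && evp$ll >= ev$ll - 1e-6) {
            theta_new <- prop; ev_new <- evp; accepted <- TRUE
            break
          }
        }
      }
    }
    if (!accepted) {               # EM-REML fallback, damped if necessary
      step_type <- "EM"
      em <- em_step(theta, score, t, q, design$n_records)
      damp <- 1
      for (half in 0:5) {
        prop <- theta + damp * (em - theta)
        pp <- unpack_theta(prop, t)
        if (is_pd(pp$G0) && is_pd(pp$R0)) {
          evp <- reml_eval(design, ap, pp$G0, pp$R0, want_sol = TRUE)
          if (is.finite(evp$ll) && evp$ll >= ev$ll - 1e-6) {
            theta_new <- prop; ev_new <- evp; accepted <- TRUE
            break
          }
        }
        damp <- damp / 2
      }
    }
    if (!accepted) break           # no uphill step found: stop where we are

    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 0.01 * scales))
    dll <- ev_new$ll - ev$ll
    # Newton decrement: the likelihood gain the quadratic model predicts for
    # the full step; when both it and the realized gain are below tolerance
    # the optimum is reached even if flat directions still jitter
    decrement <- if (!is.null(delta)) 0.5 * sum(score * delta) else Inf
    trace <- rbind(trace, data.frame(iter = iter, loglik = ev_new$ll,
                                     step = step_type, max_rel_change = rel))
    if (verbose)
      message(sprintf("iter %3d  logL %.6f  step %s  max rel change %.2e",
                      iter, ev_new$ll, step_type, rel))
    theta <- theta_new
    ev <- ev_new
    if (abs(dll) < tol_loglik && (rel < tol_param || decrement < tol_loglik)) {
      converged <- TRUE
      break
    }
  }

  par <- unpack_theta(theta, t)
  vc <- variance_components(par$G0, par$R0, traits = design$traits)
  AI <- reml_ai_matrix(design, ap, par$G0, par$R0, ev)
  ai_inv <- tryCatch(solve(AI), error = function(e) NULL)
  cors <- vc_correlations(vc)
  res <- list(vc = vc, ai = AI, ai_inv = ai_inv,
              h2 = heritability(vc, ai_inv),
              rg = cors$rg, rp = cors$rp,
              loglik = ev$ll, trace = trace, converged = converged,
              n_iter = iter, traits = design$traits)
  class(res) <- "reml_result"
  res
}

#' @export
print.reml_result <- function(x, ...) {
  cat("AI-REML estimates (", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("restricted logL:", format(x$loglik), "\n")
  print(x$h2, row.names = FALSE)
  if (length(x$traits) > 1L) {
    cat("genetic correlations:\n"); print(round(x$rg, 3))
  }
  invisible(x)
}

#' Heritabilities with delta-method standard errors
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)` per trait; when the inverse AI
#' matrix is available its diagonal blocks provide the asymptotic covariance
#' of `(sigma2_a, sigma2_e)` and the SE follows by the delta method.
#'
#' @param vc a [variance_components()] object.
#' @param ai_inv optional inverse AI matrix (parameter order as in the REML
#'   driver: vech(G0) then vech(R0)).
#' @return data.frame `trait, va, ve, vt, h2, se`.
#' @export
heritability <- function(vc, ai_inv = NULL) {
  t <- length(vc$traits)
  ix <- vech_index(t)
  np <- nrow(ix)
  diag_pos <- which(ix[, 1L] == ix[, 2L])
  va <- diag(vc$G0); ve <- diag(vc$R0); vt <- va + ve
  h2 <- va / vt
  se <- rep(NA_real_, t)
  if (!is.null(ai_inv)) {
    for (k in seq_len(t)) {
      ig <- diag_pos[k]; ir <- np + diag_pos[k]
      V <- ai_inv[c(ig, ir), c(ig, ir)]
      grad <- c(ve[k], -va[k]) / vt[k]^2
      v <- drop(t(grad) %*% V %*% grad)
      se[k] <- if (v >= 0) sqrt(v) else NA_real_
    }
  }
  data.frame(trait = vc$traits, va = va, ve = ve, vt = vt, h2 = h2, se = se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genetic and phenotypic correlations from variance components
#'
#' `rg_ij = G0_ij / sqrt(G0_ii G0_jj)` and
#' `rp_ij = (G0_ij + R0_ij) / sqrt((G0_ii + R0_ii)(G0_jj + R0_jj))`.
#'
#' @param vc a [variance_components()] object (a trait with zero variance is
#'   an error).
#' @return list with symmetric unit-diagonal matrices `rg` and `rp`.
#' @export
vc_correlations <- function(vc) {
  if (any(diag(vc$G0) <= 0) || any(diag(vc$G0 + vc$R0) <= 0))
    stop("zero or negative trait variance; correlations undefined")
  rg <- stats::cov2cor(vc$G0)
  rp <- stats::cov2cor(vc$G0 + vc$R0)
  dimnames(rg) <- dimnames(rp) <- list(vc$traits, vc$traits)
  list(rg = rg, rp = rp)
}
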