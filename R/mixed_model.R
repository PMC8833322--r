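# Multi-trait animal-model mixed-model equations (Henderson form):
#   y = Xb + Za + e,  a ~ N(0, A (x) G0),  e ~ N(0, R)
# with R block-diagonal per animal, using the inverse of the R0 submatrix
# restricted to each animal's observed traits. Equation order: fixed effects
# (trait-major), then animals in pedigree order with traits innermost.

#' Trait (co)variance components
#'
#' Container for the additive (`G0`) and residual (`R0`) trait-by-trait
#' covariance matrices of a multi-trait animal model. Both must be symmetric
#' positive definite with matching trait names.
#'
#' @param G0,R0 t-by-t matrices (scalars allowed for a single trait).
#' @param traits optional trait names (defaults to `G0` dimnames).
#' @return object of class `variance_components` with elements `G0`, `R0`,
#'   `traits`.
#' @export
variance_components <- function(G0, R0, traits = NULL) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  if (!all(dim(G0) == dim(R0))) stop("G0 and R0 dimensions differ")
  if (is.null(traits)) traits <- rownames(G0)
  if (is.null(traits)) traits <- paste0("trait", seq_len(nrow(G0)))
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  if (max(abs(G0 - t(G0))) > 1e-8 || max(abs(R0 - t(R0))) > 1e-8)
    stop("G0/R0 must be symmetric")
  for (nm in c("G0", "R0")) {
    M <- get(nm)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " is not positive definite")
  }
  structure(list(G0 = (G0 + t(G0)) / 2, R0 = (R0 + t(R0)) / 2, traits = traits),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components for", length(x$traits), "trait(s):",
      paste(x$traits, collapse = ", "), "\n")
  cat("additive (G0):\n"); print(x$G0)
  cat("residual (R0):\n"); print(x$R0)
  invisible(x)
}

#' Specify the fixed and random structure of the animal model
#'
#' Each trait gets an intercept plus the listed fixed factors; `sex` is
#' excluded automatically for sex-limited traits (recorded in one sex only),
#' where it would be confounded. The single random effect is the additive
#' animal effect with covariance `A (x) G0`.
#'
#' @param traits ordered character vector of trait codes.
#' @param fixed character subset of `c("hatch_set", "sex")` applied to every
#'   trait (default both), or a named list giving the factors per trait.
#' @param sex_limited traits recorded in females only (default: the egg traits
#'   `AFE`, `240EP`, `270EP`, `300EP`, `365EP` when present).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(traits, fixed = c("hatch_set", "sex"), sex_limited = NULL) {
  if (is.null(sex_limited))
    sex_limited <- intersect(traits, c("AFE", "240EP", "270EP", "300EP", "365EP"))
  if (!is.list(fixed)) fixed <- stats::setNames(rep(list(fixed), length(traits)), traits)
  fixed <- lapply(stats::setNames(traits, traits), function(tr) {
    f <- fixed[[tr]]
    if (tr %in% sex_limited) f <- setdiff(f, "sex")
    f
  })
  structure(list(traits = traits, fixed = fixed, sex_limited = sex_limited),
            class = "model_spec")
}

#' Build the design structures of the multi-trait animal model
#'
#' Aligns the phenotype table to the pedigree (one equation block per pedigree
#' animal, whether or not it has records), builds per-trait fixed-effect
#' incidence matrices with corner-point constraints (first observed level of
#' each factor is the reference), and indexes the missing-trait patterns used
#' for residual submatrix inversion. Factor levels with no records for a trait
#' are dropped with a warning.
#'
#' @param pheno phenotype data.frame (column `animal` + trait columns).
#' @param spec a [model_spec()].
#' @param ped a [pedigree()]; every phenotyped animal must appear in it. The
#'   factor columns (`sex`, `hatch_set`) are taken from the pedigree records.
#' @return object of class `mme_design` (per-trait X, response matrix,
#'   observation masks, missingness patterns, record counts).
#' @export
build_design <- function(pheno, spec, ped) {
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "pedigree"))
  ids <- animal_ids(ped)
  q <- length(ids)
  t <- length(spec$traits)
  bad <- setdiff(pheno$animal, ids)
  if (length(bad)) stop("phenotyped animal(s) not in pedigree: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  row <- match(pheno$animal, ids)

  Y <- matrix(0, q, t, dimnames = list(ids, spec$traits))
  O <- matrix(FALSE, q, t, dimnames = list(ids, spec$traits))
  for (k in seq_len(t)) {
    tr <- spec$traits[k]
    if (!tr %in% names(pheno)) stop("trait with zero records (column absent): ", tr)
    v <- pheno[[tr]]
    obs <- !is.na(v)
    if (!any(obs)) stop("trait with zero records: ", tr)
    Y[row[obs], k] <- v[obs]
    O[row[obs], k] <- TRUE
  }

  fac_data <- ped$data[, c("sex", "hatch_set"), drop = FALSE]
  X <- vector("list", t)
  for (k in seq_len(t)) {
    facs <- spec$fixed[[spec$traits[k]]]
    cols <- list(`(Intercept)` = Matrix::sparseMatrix(
      i = seq_len(q), j = rep(1L, q), x = 1, dims = c(q, 1L),
      dimnames = list(NULL, paste0(spec$traits[k], ":(Intercept)"))))
    for (f in facs) {
      vals <- as.character(fac_data[[f]])
      obs_levels <- sort(unique(vals[O[, k]]))
      if (any(is.na(vals) & O[, k])) stop("missing ", f, " for recorded animals (trait ",
                                          spec$traits[k], ")")
      all_levels <- sort(unique(vals[!is.na(vals)]))
      if (length(setdiff(all_levels, obs_levels)))
        warning("factor ", f, ", trait ", spec$traits[k], ": level(s) with zero records dropped: ",
                paste(setdiff(all_levels, obs_levels), collapse = ", "))
      if (length(obs_levels) < 2L) next  # constant factor adds nothing beyond intercept
      vals[is.na(vals) | !(vals %in% obs_levels)] <- obs_levels[1L]
      fi <- factor(vals, levels = obs_levels)
      m <- Matrix::sparse.model.matrix(~ fi)[, -1L, drop = FALSE]
      colnames(m) <- paste0(spec$traits[k], ":", f, levels(fi)[-1L])
      cols[[f]] <- m
    }
    X[[k]] <- do.call(cbind, cols)
  }

  pat_key <- apply(O, 1L, function(z) paste(as.integer(z), collapse = ""))
  patterns <- unique(pat_key)
  pat_id <- match(pat_key, patterns)
  pat_mask <- do.call(rbind, lapply(patterns, function(s)
    as.integer(strsplit(s, "")[[1L]]) == 1L))

  structure(list(Y = Y, O = O, X = X, traits = spec$traits, spec = spec,
                 q = q, t = t, ids = ids,
                 n_records = colSums(O),
                 pat_id = pat_id, pat_mask = pat_mask,
                 F = inbreeding(ped), generation = ped$data$generation,
                 sex = ped$data$sex),
            class = "mme_design")
}

#' @export
print.mme_design <- function(x, ...) {
  cat("Animal-model design:", x$q, "animals x", x$t, "trait(s)\n")
  cat("records per trait:\n"); print(x$n_records)
  invisible(x)
}

# log-determinant of the matrix factored by a CHMfactor object
chol_logdet <- function(CF) {
  2 * as.numeric(Matrix::determinant(CF, logarithm = TRUE, sqrt = TRUE)$modulus)
}

# Assemble the data-dependent parts of the MME for given (G0, R0):
# coefficient matrix C, right-hand side, and the likelihood ingredients
# log|R| and y'R^-1 y, plus closures reused by REML working variates.
mme_parts <- function(design, G0, R0) {
  q <- design$q; t <- design$t
  pat_mask <- design$pat_mask
  npat <- nrow(pat_mask)
  Rinv_pat <- array(0, dim = c(npat, t, t))
  logR <- 0
  pat_n <- tabulate(design$pat_id, nbins = npat)
  for (p in seq_len(npat)) {
    s <- pat_mask[p, ]
    if (!any(s)) next
    Rs <- R0[s, s, drop = FALSE]
    Rinv_pat[p, s, s] <- solve(Rs)
    logR <- logR + pat_n[p] * as.numeric(determinant(Rs, logarithm = TRUE)$modulus)
  }
  # w[i, k, l] = element (k,l) of the inverse residual submatrix of animal i
  w <- Rinv_pat[design$pat_id, , , drop = FALSE]

  Rinv_apply <- function(M) {      # per-animal R^-1 applied to a q x t matrix
    out <- matrix(0, q, t)
    for (k in seq_len(t)) {
      acc <- 0
      for (l in seq_len(t)) acc <- acc + w[, k, l] * M[, l]
      out[, k] <- acc
    }
    out
  }

  X <- design$X
  p_k <- vapply(X, ncol, 0L)
  off <- cumsum(c(0L, p_k))
  nfix <- sum(p_k)
  acol <- function(i, k) nfix + (i - 1L) * t + k   # animal-trait column index

  FFb <- vector("list", t * t); FAb <- vector("list", t * t)
  aa_i <- integer(0); aa_j <- integer(0); aa_x <- numeric(0)
  for (k in seq_len(t)) for (l in seq_len(t)) {
    wv <- w[, k, l]
    nz <- wv != 0
    if (!any(nz)) next
    idx <- (k - 1L) * t + l
    FFb[[idx]] <- list(k = k, l = l, M = Matrix::crossprod(X[[k]], X[[l]] * wv))
    Tm <- methods::as(Matrix::t(X[[k]] * wv), "TsparseMatrix")
    FAb[[idx]] <- list(k = k, l = l,
                       i = off[k] + Tm@i + 1L,
                       j = nfix + (Tm@j) * t + l,
                       x = Tm@x)
    ii <- which(nz)
    aa_i <- c(aa_i, nfix + (ii - 1L) * t + k)
    aa_j <- c(aa_j, nfix + (ii - 1L) * t + l)
    aa_x <- c(aa_x, wv[nz])
  }

  dim_c <- nfix + q * t
  FF <- matrix(0, nfix, nfix)
  for (b in FFb) if (!is.null(b)) {
    rows <- (off[b$k] + 1L):(off[b$k] + p_k[b$k])
    cols <- (off[b$l] + 1L):(off[b$l] + p_k[b$l])
    FF[rows, cols] <- FF[rows, cols] + as.matrix(b$M)
  }
  Tf <- methods::as(methods::as(Matrix::Matrix(FF, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  fa_i <- unlist(lapply(FAb, function(b) if (is.null(b)) integer(0) else b$i))
  fa_j <- unlist(lapply(FAb, function(b) if (is.null(b)) integer(0) else b$j))
  fa_x <- unlist(lapply(FAb, function(b) if (is.null(b)) numeric(0) else b$x))

  Ci <- c(Tf@i + 1L, fa_i, fa_j, aa_i)
  Cj <- c(Tf@j + 1L, fa_j, fa_i, aa_j)
  Cx <- c(Tf@x, fa_x, fa_x, aa_x)
  Cdata <- Matrix::sparseMatrix(i = Ci, j = Cj, x = Cx, dims = c(dim_c, dim_c))

  rhs <- numeric(dim_c)
  WY <- Rinv_apply(design$Y)       # q x t of R^-1 y per animal
  for (k in seq_len(t)) {
    rhs[(off[k] + 1L):(off[k] + p_k[k])] <- as.numeric(Matrix::crossprod(X[[k]], WY[, k]))
    rhs[nfix + (seq_len(q) - 1L) * t + k] <- WY[, k]
  }
  yRy <- sum(design$Y * WY)

  rhs_for <- function(Fm) {        # W'R^-1 f for a q x t working variate
    out <- numeric(dim_c)
    WF <- Rinv_apply(Fm)
    for (k in seq_len(t)) {
      out[(off[k] + 1L):(off[k] + p_k[k])] <- as.numeric(Matrix::crossprod(X[[k]], WF[, k]))
      out[nfix + (seq_len(q) - 1L) * t + k] <- WF[, k]
    }
    out
  }
  fitted_for <- function(sol) {    # X b + u as a q x t matrix
    fit <- matrix(sol[(nfix + 1L):dim_c], nrow = q, ncol = t, byrow = TRUE)
    for (k in seq_len(t))
      fit[, k] <- fit[, k] + as.numeric(X[[k]] %*% sol[(off[k] + 1L):(off[k] + p_k[k])])
    fit
  }

  list(Cdata = Cdata, rhs = rhs, logR = logR, yRy = yRy, nfix = nfix,
       off = off, p_k = p_k, dim = dim_c,
       Rinv_apply = Rinv_apply, rhs_for = rhs_for, fitted_for = fitted_for)
}

mme_coefmat <- function(parts, ainv, G0, q, t) {
  G0inv <- solve(G0)
  Gpart <- Matrix::kronecker(ainv, Matrix::Matrix(G0inv, sparse = TRUE))
  n <- parts$nfix
  dim_c <- parts$dim
  pad <- Matrix::bdiag(Matrix::Diagonal(n, 0), Gpart)
  Matrix::forceSymmetric(parts$Cdata + pad)
}

#' Solve the multi-trait mixed-model equations
#'
#' Builds and solves the Henderson equations by sparse Cholesky
#' factorisation, returning fixed-effect solutions, estimated breeding values
#' (EBVs) for every pedigree animal, and (optionally) exact prediction-error
#' variances (PEVs) and accuracies from the inverse of the coefficient
#' matrix. Fixed effects use corner-point constraints (first observed level
#' of each factor is zero), so individual level solutions are estimable only
#' relative to the reference level.
#'
#' Accuracy is `sqrt(1 - PEV / ((1 + F_i) * g_kk))`, clipped to `[0, 1]`; a
#' PEV exceeding `(1 + F_i) g_kk` beyond numerical tolerance signals an
#' inconsistent solve and is an error.
#'
#' @param design an [build_design()] object.
#' @param ainv sparse A-inverse from [a_inverse()].
#' @param vc a [variance_components()] object (must be positive definite).
#' @param pev compute exact PEVs/accuracies by (chunked) inversion of the
#'   coefficient matrix (default `TRUE`; exact, intended for desk-scale
#'   problems — set `FALSE` to skip on large ones).
#' @return object of class `mme_solution`: `fixed` (data.frame trait, factor
#'   level, estimate), `ebv`, `pev`, `accuracy` (animal-by-trait matrices),
#'   `loglik_parts`, plus internals reused by the REML driver.
#' @export
solve_mme <- function(design, ainv, vc, pev = TRUE) {
  stopifnot(inherits(design, "mme_design"), inherits(vc, "variance_components"))
  t <- design$t; q <- design$q
  if (length(vc$traits) != t) stop("variance components do not match the trait list")
  parts <- mme_parts(design, vc$G0, vc$R0)
  C <- mme_coefmat(parts, ainv, vc$G0, q, t)
  CF <- Matrix::Cholesky(C, LDL = FALSE)
  sol <- as.numeric(Matrix::solve(CF, parts$rhs))
  nfix <- parts$nfix
  ebv <- matrix(sol[(nfix + 1L):parts$dim], nrow = q, ncol = t, byrow = TRUE,
                dimnames = list(design$ids, design$traits))
  fixed <- data.frame(effect = unlist(lapply(design$X, colnames)),
                      estimate = sol[seq_len(nfix)], stringsAsFactors = FALSE)

  pev_m <- acc_m <- NULL
  if (isTRUE(pev)) {
    pev_m <- mme_pev(CF, parts, q, t, design)
    acc_m <- ebv_accuracy(pev_m, vc, design$F)
  }
  structure(list(fixed = fixed, ebv = ebv, pev = pev_m, accuracy = acc_m,
                 sol = sol, parts = parts, CF = CF,
                 logdet_C = chol_logdet(CF),
                 vc = vc, ids = design$ids, traits = design$traits),
            class = "mme_solution")
}

# diagonal of the animal block of C^-1, by chunked sparse solves
mme_pev <- function(CF, parts, q, t, design, chunk = 512L) {
  dim_c <- parts$dim
  nfix <- parts$nfix
  cols <- (nfix + 1L):dim_c
  out <- numeric(length(cols))
  pos <- 1L
  while (pos <= length(cols)) {
    jj <- cols[pos:min(pos + chunk - 1L, length(cols))]
    E <- Matrix::sparseMatrix(i = jj, j = seq_along(jj), x = 1,
                              dims = c(dim_c, length(jj)))
    S <- Matrix::solve(CF, E)
    out[(pos - 1L) + seq_along(jj)] <- S[cbind(jj, seq_along(jj))]
    pos <- pos + chunk
  }
  matrix(out, nrow = q, ncol = t, byrow = TRUE,
         dimnames = list(design$ids, design$traits))
}

#' Accuracy of breeding-value predictions
#'
#' `accuracy = sqrt(1 - PEV / ((1 + F) * sigma2_a))` per animal and trait,
#' clipped to `[0, 1]`. An animal with no record and no informative relatives
#' has PEV equal to `(1 + F) sigma2_a` and hence accuracy 0.
#'
#' @param pev animal-by-trait matrix of prediction-error variances.
#' @param vc a [variance_components()] object.
#' @param F named inbreeding-coefficient vector (pedigree order).
#' @param tol relative tolerance before an over-large PEV is an error.
#' @return animal-by-trait accuracy matrix.
#' @export
ebv_accuracy <- function(pev, vc, F, tol = 1e-6) {
  g <- diag(vc$G0)
  denom <- outer(1 + F, g)
  rel <- pev / denom
  if (any(rel > 1 + tol)) stop("PEV exceeds (1+F) * additive variance: inconsistent solve")
  sqrt(pmin(pmax(1 - rel, 0), 1))
}

#' Write BLUP solutions as delimited text
#'
#' One row per animal and trait: `animal_id, trait, ebv, pev, accuracy`;
#' fixed effects in a companion file as `effect, estimate`.
#'
#' @param solution an [solve_mme()] result.
#' @param path output path for the EBV table.
#' @param fixed_path optional path for the fixed-effect table.
#' @export
write_solutions <- function(solution, path, fixed_path = NULL) {
  long <- data.frame(
    animal_id = rep(solution$ids, times = length(solution$traits)),
    trait = rep(solution$traits, each = length(solution$ids)),
    ebv = as.numeric(solution$ebv),
    pev = if (is.null(solution$pev)) NA_real_ else as.numeric(solution$pev),
    accuracy = if (is.null(solution$accuracy)) NA_real_ else as.numeric(solution$accuracy))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fixed_path))
    utils::write.table(solution$fixed, fixed_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
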