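# Shared fixture builders: random pedigrees and small simulated data sets,
# all generated in code at test time.

# random overlapping-parentage pedigree with founders first
make_random_pedigree <- function(n, seed, n_founders = max(8L, n %/% 10L),
                                 hatch = TRUE) {
  set.seed(seed)
  id <- sprintf("a%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  for (i in (n_founders + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    fems <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) && length(fems)) {
      sire[i] <- id[sample(males, 1L)]
      dam[i] <- id[sample(fems, 1L)]
    }
  }
  df <- data.frame(animal = id, sire = sire, dam = dam, sex = sex,
                   stringsAsFactors = FALSE)
  if (hatch) df$hatch_set <- sample(as.character(1:3), n, replace = TRUE)
  pedigree(df)
}

# dense GLS/BLUP oracle for the multi-trait animal model (corner-constraint
# fixed effects must be supplied as a record-level matrix)
gls_oracle <- function(ped, pheno, traits, G0, R0, X_of_record) {
  ids <- animal_ids(ped)
  A <- relationship_matrix(ped)
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  t <- length(traits)
  ridx <- match(pheno$animal, ids)
  recs <- list()
  for (r in seq_len(nrow(pheno))) for (k in seq_len(t)) {
    if (!is.na(pheno[r, traits[k]])) recs[[length(recs) + 1L]] <- c(ridx[r], k, pheno[r, traits[k]])
  }
  M <- do.call(rbind, recs)
  nr <- nrow(M)
  V <- matrix(0, nr, nr)
  for (a in seq_len(nr)) for (b in seq_len(nr)) {
    V[a, b] <- A[M[a, 1L], M[b, 1L]] * G0[M[a, 2L], M[b, 2L]] +
      (M[a, 1L] == M[b, 1L]) * R0[M[a, 2L], M[b, 2L]]
  }
  X <- X_of_record(M)
  y <- M[, 3L]
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  bhat <- solve(XVX, t(X) %*% Vi %*% y)
  Py <- Vi %*% (y - X %*% bhat)
  n <- length(ids)
  Zm <- matrix(0, nr, t * n)
  Zm[cbind(seq_len(nr), (M[, 1L] - 1L) * t + M[, 2L])] <- 1
  uhat <- kronecker(A, G0) %*% t(Zm) %*% Py
  yPy <- drop(t(y - X %*% bhat) %*% Py)
  ll <- -0.5 * (as.numeric(determinant(V)$modulus) +
                as.numeric(determinant(XVX)$modulus) + yPy)
  list(fixed = drop(bhat), ebv = matrix(uhat, n, t, byrow = TRUE), loglik = ll)
}

# small multivariate animal-model data set on a random pedigree
make_small_dataset <- function(n = 60, seed = 1, t = 2,
                               G0 = matrix(c(4, 1.5, 1.5, 2), 2),
                               R0 = matrix(c(5, 1, 1, 3), 2),
                               miss = 0.2) {
  ped <- make_random_pedigree(n, seed)
  set.seed(seed + 1L)
  ids <- animal_ids(ped)
  A <- relationship_matrix(ped)
  G0 <- as.matrix(G0)[seq_len(t), seq_len(t), drop = FALSE]
  R0 <- as.matrix(R0)[seq_len(t), seq_len(t), drop = FALSE]
  U <- matrix(MASS::mvrnorm(1, rep(0, t * n), kronecker(A, G0)), n, t, byrow = TRUE)
  E <- MASS::mvrnorm(n, rep(0, t), R0)
  if (t == 1L) E <- matrix(E, ncol = 1L)
  Y <- U + E + 10
  traits <- paste0("t", seq_len(t))
  pheno <- data.frame(animal = ids, Y, stringsAsFactors = FALSE)
  names(pheno)[-1L] <- traits
  if (miss > 0 && t > 1L) {
    for (k in seq_len(t)) pheno[[traits[k]]][sample(n, round(miss * n))] <- NA
    pheno <- pheno[rowSums(!is.na(pheno[, traits, drop = FALSE])) > 0L, , drop = FALSE]
  }
  list(ped = ped, pheno = pheno, traits = traits, G0 = G0, R0 = R0, U = U)
}

# single-trait nucleus simulation matching the emulated program's structure
nucleus_sim <- function(seed, va = 8.77, ve = 4.89, mean = 37.9,
                        selection = "none", n_generations = 6,
                        n_recorded = 452) {
  cfg <- sim_config(traits = "BW0", G0 = va, R0 = ve, means = mean,
                    selection = selection, n_generations = n_generations,
                    n_recorded = n_recorded,
                    hatch_effects = matrix(c(-0.5, 0, 0.5), 3, 1),
                    seed = seed)
  simulate_program(cfg)
}
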