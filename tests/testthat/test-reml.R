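test_that("restricted log-likelihood matches the dense-V evaluation", {
  for (seed in c(6, 19)) {
    d <- make_small_dataset(55, seed = seed, t = 2, miss = 0.2)
    spec <- model_spec(d$traits, fixed = "hatch_set", sex_limited = character(0))
    des <- build_design(d$pheno, spec, d$ped)
    vc <- variance_components(d$G0, d$R0, d$traits)
    ll <- restricted_loglik(des, a_inverse(d$ped), vc)
    X_of <- function(M) {
      hv <- d$ped$data$hatch_set[M[, 1]]
      Xk <- cbind(1, hv == "2", hv == "3")
      X <- matrix(0, nrow(M), 6)
      X[M[, 2] == 1, 1:3] <- Xk[M[, 2] == 1, ]
      X[M[, 2] == 2, 4:6] <- Xk[M[, 2] == 2, ]
      X
    }
    orc <- gls_oracle(d$ped, d$pheno, d$traits, d$G0, d$R0, X_of)
    expect_equal(ll, orc$loglik, tolerance = 1e-6)
  }
})

test_that("restricted likelihood is invariant to fixed-effect translation", {
  d <- make_small_dataset(40, seed = 9, t = 1, miss = 0)
  spec <- model_spec("t1", fixed = "hatch_set", sex_limited = character(0))
  ainv <- a_inverse(d$ped)
  vc <- variance_components(d$G0[1, 1], d$R0[1, 1], "t1")
  ll1 <- restricted_loglik(build_design(d$pheno, spec, d$ped), ainv, vc)
  ph2 <- d$pheno
  ph2$t1 <- ph2$t1 + 500   # global shift is absorbed by the intercept
  ll2 <- restricted_loglik(build_design(ph2, spec, d$ped), ainv, vc)
  expect_equal(ll1, ll2, tolerance = 1e-6)
})

test_that("restricted likelihood favours the generating components over inflated ones", {
  hits <- 0L
  for (seed in 1:10) {
    d <- make_small_dataset(120, seed = 100 + seed, t = 1, miss = 0)
    spec <- model_spec("t1", fixed = character(0), sex_limited = character(0))
    des <- build_design(d$pheno, spec, d$ped)
    ainv <- a_inverse(d$ped)
    ll_truth <- restricted_loglik(des, ainv, variance_components(4, 5, "t1"))
    ll_double <- restricted_loglik(des, ainv, variance_components(8, 10, "t1"))
    hits <- hits + (ll_truth > ll_double)
  }
  expect_gte(hits, 9L)
})

test_that("AI-REML recovers a null additive variance as near-zero heritability", {
  h2 <- sapply(1:6, function(seed) {
    set.seed(400 + seed)
    ped <- make_random_pedigree(600, seed = 400 + seed)
    ph <- data.frame(animal = animal_ids(ped), t1 = rnorm(600, 20, 3))
    des <- build_design(ph, model_spec("t1", fixed = "hatch_set",
                                       sex_limited = character(0)), ped)
    ai_reml(des, a_inverse(ped))$h2$h2
  })
  expect_gte(sum(h2 < 0.07), 5L)
})

test_that("AI-REML matches the ANOVA estimator in the balanced half-sib limit", {
  set.seed(31)
  ns <- 40; noff <- 20; va <- 40; ve <- 60
  sires <- sprintf("S%02d", seq_len(ns))
  us <- rnorm(ns, 0, sqrt(va))
  off <- do.call(rbind, lapply(seq_len(ns), function(s) {
    data.frame(animal = sprintf("O%02d_%02d", s, seq_len(noff)),
               sire = sires[s], dam = NA, sex = "F",
               y = 50 + 0.5 * us[s] + rnorm(noff, 0, sqrt(0.75 * va)) +
                 rnorm(noff, 0, sqrt(ve)))
  }))
  ped <- pedigree(rbind(data.frame(animal = sires, sire = NA, dam = NA,
                                   sex = "M", y = NA)[, names(off)], off)[,
                  c("animal", "sire", "dam", "sex")])
  des <- build_design(off[, c("animal", "y")],
                      model_spec("y", fixed = character(0),
                                 sex_limited = character(0)), ped)
  fit <- ai_reml(des, a_inverse(ped))
  aovt <- anova(lm(y ~ factor(sire), off))
  va_anova <- 4 * (aovt[1, "Mean Sq"] - aovt[2, "Mean Sq"]) / noff
  expect_equal(fit$h2$va, va_anova, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("REML estimates are invariant to animal ordering of the input", {
  d <- make_small_dataset(120, seed = 55, t = 1, miss = 0)
  spec <- model_spec("t1", fixed = "hatch_set", sex_limited = character(0))
  f1 <- ai_reml(build_design(d$pheno, spec, d$ped), a_inverse(d$ped))
  set.seed(1)
  df <- as.data.frame(d$ped)
  ped2 <- pedigree(df[sample(nrow(df)), ])
  ph2 <- d$pheno[sample(nrow(d$pheno)), ]
  f2 <- ai_reml(build_design(ph2, spec, ped2), a_inverse(ped2))
  expect_equal(f1$h2$h2, f2$h2$h2, tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
})

test_that("accepted AI/EM iterations never decrease the restricted likelihood", {
  d <- make_small_dataset(150, seed = 61, t = 2, miss = 0.2)
  spec <- model_spec(d$traits, fixed = "hatch_set", sex_limited = character(0))
  fit <- ai_reml(build_design(d$pheno, spec, d$ped), a_inverse(d$ped))
  expect_true(all(diff(fit$trace$loglik) > -1e-6))
  expect_true(fit$converged)
})

test_that("heritability and correlation identities hold on reference components", {
  # printed-variance identities: va/(va+ve)
  vc <- variance_components(diag(c(8.77, 138.10, 86.50)),
                            diag(c(4.89, 185.40, 234.80)),
                            c("BW0", "240EP", "AFE"))
  h <- heritability(vc)
  expect_equal(round(h$h2, 3), c(0.642, 0.427, 0.269))
  expect_equal(heritability(variance_components(1e-12, 5, "x"))$h2, 0,
               tolerance = 1e-10)

  # diagonal G0 -> rg identity; proportional G0 = R0 -> rg = rp
  vc2 <- variance_components(diag(c(2, 3)), matrix(c(4, 1, 1, 5), 2))
  expect_equal(vc_correlations(vc2)$rg, diag(2), ignore_attr = TRUE)
  G <- matrix(c(4, 1.2, 1.2, 2), 2)
  vc3 <- variance_components(G, G)
  cr <- vc_correlations(vc3)
  expect_equal(cr$rg, cr$rp)
  expect_true(all(abs(cr$rg) <= 1) && all(diag(cr$rg) == 1))
})

test_that("delta-method heritability SEs are finite and positive at convergence", {
  d <- make_small_dataset(200, seed = 71, t = 1, miss = 0)
  fit <- ai_reml(build_design(d$pheno, model_spec("t1", fixed = "hatch_set",
                                                  sex_limited = character(0)),
                              d$ped), a_inverse(d$ped))
  expect_true(is.finite(fit$h2$se) && fit$h2$se > 0 && fit$h2$se < 0.5)
})
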