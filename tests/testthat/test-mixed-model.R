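test_that("hand-solved 3x3 mixed-model equations are reproduced", {
  # two unrelated animals with records 10 and 14, va = ve = 1, intercept only:
  # intercept 12, EBVs -1 and +1
  ped <- pedigree(data.frame(animal = c("a", "b"), sire = NA, dam = NA,
                             sex = c("M", "F")))
  ph <- data.frame(animal = c("a", "b"), y = c(10, 14))
  des <- build_design(ph, model_spec("y", fixed = character(0),
                                     sex_limited = character(0)), ped)
  fit <- solve_mme(des, a_inverse(ped), variance_components(1, 1, "y"))
  expect_equal(fit$fixed$estimate, 12)
  expect_equal(unname(fit$ebv[, 1]), c(-1, 1))
})

test_that("vanishing additive variance shrinks EBVs to zero and fixed effects to OLS", {
  d <- make_small_dataset(50, seed = 21, t = 1, miss = 0)
  des <- build_design(d$pheno, model_spec("t1", fixed = "hatch_set",
                                          sex_limited = character(0)), d$ped)
  fit <- solve_mme(des, a_inverse(d$ped),
                   variance_components(1e-8, d$R0[1, 1], "t1"), pev = FALSE)
  expect_lt(max(abs(fit$ebv)), 1e-6)
  ols <- lm(t1 ~ factor(hatch_set), data = cbind(d$pheno, as.data.frame(d$ped)))
  expect_equal(unname(fit$fixed$estimate), unname(coef(ols)), tolerance = 1e-6)
})

test_that("sex-limited traits contribute no records for males", {
  ped <- pedigree(data.frame(animal = c("m", "f"), sire = NA, dam = NA,
                             sex = c("M", "F"), hatch_set = "1"))
  ph <- data.frame(animal = c("m", "f"), AFE = c(170, 165))
  spec <- model_spec("AFE", fixed = character(0))
  expect_true("AFE" %in% spec$sex_limited)   # sex dropped automatically
  ph$AFE[1] <- NA                            # males carry no AFE record
  des <- build_design(ph, spec, ped)
  expect_equal(unname(des$n_records), 1L)
})

test_that("multi-trait MME solutions equal the dense GLS/BLUP oracle", {
  for (seed in c(3, 14)) {
    d <- make_small_dataset(70, seed = seed, t = 2, miss = 0.25)
    spec <- model_spec(d$traits, fixed = list(t1 = c("sex", "hatch_set"),
                                              t2 = "hatch_set"),
                       sex_limited = character(0))
    des <- build_design(d$pheno, spec, d$ped)
    vc <- variance_components(d$G0, d$R0, d$traits)
    fit <- solve_mme(des, a_inverse(d$ped), vc, pev = FALSE)
    ids <- animal_ids(d$ped)
    X_of <- function(M) {
      sexv <- d$ped$data$sex[M[, 1]]
      hv <- d$ped$data$hatch_set[M[, 1]]
      X1 <- cbind(1, sexv == "M", hv == "2", hv == "3")
      X2 <- cbind(1, hv == "2", hv == "3")
      X <- matrix(0, nrow(M), 7)
      X[M[, 2] == 1, 1:4] <- X1[M[, 2] == 1, ]
      X[M[, 2] == 2, 5:7] <- X2[M[, 2] == 2, ]
      X
    }
    orc <- gls_oracle(d$ped, d$pheno, d$traits, d$G0, d$R0, X_of)
    expect_lt(max(abs(fit$ebv - orc$ebv)), 1e-6)
    expect_lt(max(abs(fit$fixed$estimate - orc$fixed)), 1e-6)
  }
})

test_that("block-separability: diagonal G0 and R0 equal independent single-trait solves", {
  d <- make_small_dataset(60, seed = 8, t = 2, miss = 0.2,
                          G0 = diag(c(4, 2)), R0 = diag(c(5, 3)))
  spec2 <- model_spec(d$traits, fixed = "hatch_set", sex_limited = character(0))
  des2 <- build_design(d$pheno, spec2, d$ped)
  ainv <- a_inverse(d$ped)
  fit2 <- solve_mme(des2, ainv, variance_components(d$G0, d$R0, d$traits), pev = FALSE)
  for (k in 1:2) {
    ph1 <- d$pheno[!is.na(d$pheno[[d$traits[k]]]), c("animal", d$traits[k])]
    des1 <- build_design(ph1, model_spec(d$traits[k], fixed = "hatch_set",
                                         sex_limited = character(0)), d$ped)
    fit1 <- solve_mme(des1, ainv, variance_components(d$G0[k, k], d$R0[k, k],
                                                      d$traits[k]), pev = FALSE)
    expect_equal(unname(fit2$ebv[, k]), unname(fit1$ebv[, 1]), tolerance = 1e-8)
  }
})

test_that("EBVs are invariant to translating one fixed-effect level", {
  d <- make_small_dataset(50, seed = 30, t = 1, miss = 0)
  spec <- model_spec("t1", fixed = "hatch_set", sex_limited = character(0))
  ainv <- a_inverse(d$ped)
  vc <- variance_components(d$G0[1, 1], d$R0[1, 1], "t1")
  fit1 <- solve_mme(build_design(d$pheno, spec, d$ped), ainv, vc, pev = FALSE)
  ph2 <- d$pheno
  shift <- d$ped$data$hatch_set[match(ph2$animal, animal_ids(d$ped))] == "2"
  ph2$t1[shift] <- ph2$t1[shift] + 100
  fit2 <- solve_mme(build_design(ph2, spec, d$ped), ainv, vc, pev = FALSE)
  expect_equal(fit1$ebv, fit2$ebv, tolerance = 1e-7)
})

test_that("accuracy follows the PEV identity in closed-form cases", {
  # record-less, relative-less animal: accuracy 0
  ped <- pedigree(data.frame(animal = c("a", "b"), sire = NA, dam = NA,
                             sex = c("M", "F")))
  ph <- data.frame(animal = "a", y = 12)
  des <- build_design(ph, model_spec("y", fixed = character(0),
                                     sex_limited = character(0)), ped)
  va <- 2; ve <- 3
  fit <- solve_mme(des, a_inverse(ped), variance_components(va, ve, "y"))
  expect_equal(unname(fit$accuracy["b", 1]), 0)

  # single record with a fitted mean: the hand-inverted 2x2 MME gives
  # PEV = va exactly (the one record is absorbed by the intercept)
  C2 <- matrix(c(1/ve, 1/ve, 1/ve, 1/ve + 1/va), 2)
  expect_equal(solve(C2)[2, 2], va, tolerance = 1e-10)
  expect_equal(unname(fit$pev["a", 1]), va, tolerance = 1e-8)

  # two unrelated recorded animals: compare with the hand-inverted 3x3 MME
  ph2 <- data.frame(animal = c("a", "b"), y = c(12, 9))
  des2 <- build_design(ph2, model_spec("y", fixed = character(0),
                                       sex_limited = character(0)), ped)
  fit2 <- solve_mme(des2, a_inverse(ped), variance_components(va, ve, "y"))
  C3 <- matrix(c(2/ve, 1/ve, 1/ve,
                 1/ve, 1/ve + 1/va, 0,
                 1/ve, 0, 1/ve + 1/va), 3, byrow = TRUE)
  pev_hand <- solve(C3)[2, 2]
  expect_equal(unname(fit2$pev["a", 1]), pev_hand, tolerance = 1e-10)
  expect_equal(unname(fit2$accuracy["a", 1]), sqrt(1 - pev_hand / va),
               tolerance = 1e-10)
})

test_that("adding a progeny record never decreases a sire's accuracy", {
  base <- data.frame(animal = c("s", "d", "o"), sire = c(NA, NA, "s"),
                     dam = c(NA, NA, "d"), sex = c("M", "F", "F"))
  ped <- pedigree(base)
  vc <- variance_components(4, 6, "y")
  spec <- model_spec("y", fixed = character(0), sex_limited = character(0))
  ph_a <- data.frame(animal = "s", y = 10)
  ph_b <- data.frame(animal = c("s", "o"), y = c(10, 13))
  acc_a <- solve_mme(build_design(ph_a, spec, ped), a_inverse(ped), vc)$accuracy["s", 1]
  acc_b <- solve_mme(build_design(ph_b, spec, ped), a_inverse(ped), vc)$accuracy["s", 1]
  expect_gte(acc_b, acc_a)
})

test_that("solution files are written in the documented delimited layout", {
  d <- make_small_dataset(30, seed = 40, t = 1, miss = 0)
  des <- build_design(d$pheno, model_spec("t1", fixed = character(0),
                                          sex_limited = character(0)), d$ped)
  fit <- solve_mme(des, a_inverse(d$ped),
                   variance_components(d$G0[1, 1], d$R0[1, 1], "t1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_solutions(fit, path)
  out <- read.delim(path)
  expect_identical(names(out), c("animal_id", "trait", "ebv", "pev", "accuracy"))
  expect_equal(nrow(out), n_animals(d$ped))
})
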