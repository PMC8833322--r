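test_that("selection intensity matches truncated-normal closed forms", {
  expect_equal(selection_intensity(0.5), 2 * dnorm(0), tolerance = 1e-12)
  z <- qnorm(0.8)
  expect_equal(selection_intensity(0.2), dnorm(z) / 0.2, tolerance = 1e-12)
  expect_equal(round(selection_intensity(0.2), 2), 1.40)
  expect_lt(selection_intensity(0.999), 0.005)   # no selection -> no intensity
  expect_error(selection_intensity(0), "between 0 and 1")
  expect_error(selection_intensity(1.2), "between 0 and 1")
})

test_that("expected genetic progress is the product sigma_A * h * i", {
  expect_equal(delta_g(10, 0.6, 1.4), 8.4)
  expect_equal(delta_g(10, 0, 1.4), 0)
  expect_equal(delta_g(c(2, 3), c(0.5, 0.5), 1), c(1, 1.5))
  expect_error(delta_g(-1, 0.5, 1), "non-negative")
  expect_error(delta_g(1, 1.5, 1), "\\[0, 1\\]")
})

test_that("genetic trend recovers exact generation-mean slopes", {
  ebv <- cbind(tr = rep(c(0, 5, 10, 15), each = 5))
  rownames(ebv) <- sprintf("a%02d", 1:20)
  gen <- rep(0:3, each = 5)
  tr <- genetic_trend(ebv, gen)
  expect_equal(unname(tr$slope), 5)
  expect_equal(tr$means$tr, c(0, 5, 10, 15))
  # constant EBVs -> zero slope; single generation -> error
  expect_equal(unname(genetic_trend(cbind(x = rep(2, 10)), rep(0:1, 5))$slope), 0)
  expect_error(genetic_trend(ebv, rep(1, 20)), "single generation")
})

test_that("index coefficients solve P b = G v with closed-form special cases", {
  # single trait: b = h2 * v
  expect_equal(index_coefficients(10, 4, 2), 0.8)
  # G = P: b = v
  P <- matrix(c(4, 1, 1, 3), 2)
  expect_equal(index_coefficients(P, P, c(0.3, 0.7)), c(0.3, 0.7))
  # general case against a dense solve
  G <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  v <- c(0.25, 0.75)
  expect_equal(index_coefficients(P, G, v), drop(solve(P) %*% G %*% v),
               tolerance = 1e-10)
  expect_error(index_coefficients(matrix(0, 2, 2), G, v), "singular")
})

test_that("four-trait index coefficients from the published tables match a dense solve", {
  trs <- c("BW6", "BrC6", "240EP", "AFE")
  truth <- km2_sim_truth()
  va <- setNames(truth$va, truth$trait)[trs]
  vt <- va + setNames(truth$ve, truth$trait)[trs]
  G <- assemble_covariance(va, km2_genetic_correlations[trs, trs])
  P <- assemble_covariance(vt, km2_phenotypic_correlations[trs, trs])
  v <- c(0.25, 0.25, 0.30, 0.20)
  b <- index_coefficients(P, G, v)
  expect_lt(max(abs(P %*% b - G %*% v)), 1e-10)
})

test_that("index accuracy is the correlation with the aggregate genotype", {
  # single trait -> sqrt(h2); G = P -> 1
  expect_equal(as.numeric(index_accuracy(10, 4, 1)), sqrt(0.4), tolerance = 1e-12)
  P <- matrix(c(4, 1, 1, 3), 2)
  expect_equal(as.numeric(index_accuracy(P, P, c(0.4, 0.6))), 1, tolerance = 1e-10)

  # Monte Carlo: corr(I, H) at large n
  set.seed(123)
  P3 <- matrix(c(10, 4, 2, 4, 8, 1, 2, 1, 6), 3)
  G3 <- matrix(c(4, 1.5, 1, 1.5, 3, 0.5, 1, 0.5, 2), 3)
  v <- c(0.4, 0.35, 0.25)
  r <- index_accuracy(P3, G3, v)
  g <- MASS::mvrnorm(50000, rep(0, 3), G3)
  x <- g + MASS::mvrnorm(50000, rep(0, 3), P3 - G3)
  b <- index_coefficients(P3, G3, v)
  expect_lt(abs(cor(x %*% b, g %*% v) - as.numeric(r)), 0.02)
  expect_true(is.numeric(attr(r, "literal_ratio")))
})

test_that("index accuracy is scale-invariant in v and bounded in [0,1]", {
  set.seed(9)
  for (i in 1:20) {
    L <- matrix(rnorm(9), 3); E <- crossprod(L) + diag(3)   # PD residual part
    Lg <- matrix(rnorm(9), 3); G <- crossprod(Lg) + 0.1 * diag(3)
    P <- G + E
    v <- runif(3, 0.1, 1)
    r1 <- as.numeric(index_accuracy(P, G, v))
    r2 <- as.numeric(index_accuracy(P, G, 7.3 * v))
    expect_true(r1 >= 0 && r1 <= 1)
    expect_equal(r1, r2, tolerance = 1e-10)
  }
})

test_that("the EBV index applies the economic weights with the AFE sign flip", {
  spec <- selection_index_spec()
  ebv <- rbind(c(10, 2, 5, -4), c(0, 0, 0, 0))
  colnames(ebv) <- spec$traits
  rownames(ebv) <- c("x", "y")
  I <- ebv_index(ebv, spec)
  expect_equal(unname(I), c(0.25 * 10 + 0.25 * 2 + 0.30 * 5 - 0.20 * (-4), 0))
  expect_equal(unname(I["x"]), 5.3)
  # lowering EBV_AFE strictly raises the index
  ebv2 <- ebv; ebv2["x", "AFE"] <- -6
  expect_gt(ebv_index(ebv2, spec)["x"], I["x"])
  # weight constraints enforced
  expect_error(selection_index_spec(weights = c(0.3, 0.3, 0.2, 0.2)), "sum")
})

test_that("truncation selection takes the top fraction with deterministic ties", {
  idx <- setNames(c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4), paste0("a", 1:10))
  expect_identical(truncate_top(idx, 0.2), c("a1", "a2"))
  expect_identical(sort(truncate_top(idx, 1)), sort(names(idx)))
  # tie at the cut-off resolves by id, stably across runs
  tie <- setNames(c(3, 2, 2, 1), c("d", "c", "b", "a"))
  expect_identical(truncate_top(tie, 0.5), c("d", "b"))
  expect_identical(truncate_top(tie, 0.5), truncate_top(tie, 0.5))
  # within-sex selection
  sex <- rep(c("M", "F"), 5)
  sel <- truncate_top(idx, 0.4, sex = sex)
  expect_length(sel, 4L)
  expect_setequal(sel[startsWith(sel, "a") & sel %in% c("a1", "a3")], c("a1", "a3"))
})
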