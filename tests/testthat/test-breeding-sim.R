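test_that("effective population size follows 4NmNf/(Nm+Nf)", {
  expect_equal(effective_population_size(30, 150), 100)
  expect_equal(effective_population_size(25, 25), 50)   # balanced sexes: 2N
  expect_equal(effective_population_size(1, 1), 2)
  expect_error(effective_population_size(0, 10), "positive")
})

test_that("covariance assembly reproduces r * sqrt(vi vj) and repairs non-PD input", {
  v <- c(a = 2, b = 8)
  expect_equal(assemble_covariance(v, diag(2)), diag(c(2, 8)), ignore_attr = TRUE)
  S <- assemble_covariance(c(BW10 = 12602, BrC6 = 1.10),
                           matrix(c(1, 0.93, 0.93, 1), 2))
  expect_equal(S[1, 2], 0.93 * sqrt(12602 * 1.10))

  # an inconsistent correlation triple is repaired with modest distortion
  R <- matrix(c(1, 0.95, -0.9, 0.95, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_message(S2 <- assemble_covariance(c(1, 1, 1), R), "repaired")
  ev <- eigen(S2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_gt(attr(S2, "repair"), 0)
  expect_error(assemble_covariance(c(1, 1), matrix(c(1, 1.2, 1.2, 1), 2)),
               "\\[-1, 1\\]")
})

test_that("the full published correlation tables assemble into PD covariances", {
  truth <- km2_sim_truth()
  G <- assemble_covariance(setNames(truth$va, truth$trait), km2_genetic_correlations)
  P <- assemble_covariance(setNames(truth$va + truth$ve, truth$trait),
                           km2_phenotypic_correlations)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 0)
  # recomputed correlations stay within 0.05 of the published entries
  expect_lt(max(abs(cov2cor(G) - km2_genetic_correlations)), 0.05)
  R <- P - G
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("offspring breeding values are parent averages when G0 vanishes", {
  sires <- data.frame(id = sprintf("s%d", 1:2), sire = NA, dam = NA, F = 0)
  sires$bv <- cbind(x = c(4, -2))
  dams <- data.frame(id = sprintf("d%d", 1:10), sire = NA, dam = NA, F = 0)
  dams$bv <- cbind(x = seq(-1, 1, length.out = 10))
  cfg <- sim_config(traits = "x", G0 = 0, R0 = 1, n_sires = 2, n_dams = 10,
                    dams_per_sire = 5, seed = 1)
  set.seed(2)
  off <- simulate_generation(sires, dams, cfg, n_offspring = 40)
  mid <- 0.5 * (sires$bv[match(off$sire, sires$id), 1] +
                dams$bv[match(off$dam, dams$id), 1])
  expect_equal(unname(off$bv[, 1]), unname(mid))
  expect_error(simulate_generation(sires[1, , drop = FALSE], dams, cfg),
               "insufficient parents")
})

test_that("the default nucleus structure matches the emulated breeding program", {
  cfg <- km2_sim_config(traits = c("BW0", "BrC6", "AFE"), n_generations = 2,
                        seed = 123)
  sim <- simulate_program(cfg)
  ped <- as.data.frame(sim$pedigree)
  # 30 + 150 founders, i.e. records with both parents unknown
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 180L)
  # hatch counts inside the configured range, bookkept per generation
  expect_true(all(sim$per_generation$n[-1] >= 1500 &
                  sim$per_generation$n[-1] <= 1800))
  # 452 recorded per generation
  expect_equal(nrow(sim$phenotypes), 2L * 452L)
  # egg traits are female-only; growth traits recorded for both sexes
  sex <- ped$sex[match(sim$phenotypes$animal, ped$animal)]
  expect_true(all(is.na(sim$phenotypes$AFE[sex == "M"])))
  expect_true(all(!is.na(sim$phenotypes$AFE[sex == "F"])))
  expect_true(all(!is.na(sim$phenotypes$BW0)))
  expect_true(all(sim$phenotypes$AFE[sex == "F"] ==
                  round(sim$phenotypes$AFE[sex == "F"])))
  # exported pedigree = recorded birds plus ancestors, all parents present
  expect_true(all(ped$sire[!is.na(ped$sire)] %in% ped$animal))
})

test_that("sub-threshold birth-weight injection is recovered by the editing filter", {
  cfg <- km2_sim_config(traits = "BW0", n_generations = 2,
                        bw0_subthreshold_rate = 0.03, seed = 55)
  sim <- simulate_program(cfg)
  fb <- filter_birth_weight(sim$phenotypes)
  # every injected chick is caught; a handful of genuinely light chicks from
  # the trait distribution's own lower tail may join them
  expect_true(all(sim$injected_ids %in% fb$removed))
  expect_lte(length(setdiff(fb$removed, sim$injected_ids)), 5L)
  expect_gt(length(sim$injected_ids), 0L)
})

test_that("the same seed reproduces the simulation exactly", {
  cfg <- sim_config(traits = "x", G0 = 4, R0 = 6, n_sires = 10, n_dams = 50,
                    dams_per_sire = 5, n_generations = 2, n_recorded = Inf,
                    offspring_range = c(150, 160), selection = "phenotypic",
                    seed = 7)
  s1 <- simulate_program(cfg)
  s2 <- simulate_program(cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$true_bv, s2$true_bv)
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
})

test_that("index selection raises mean breeding values and inbreeding over generations", {
  ups <- vapply(1:6, function(seed) {
    cfg <- sim_config(traits = "x", G0 = 4, R0 = 6, n_sires = 8, n_dams = 40,
                      dams_per_sire = 5, n_generations = 3, n_recorded = Inf,
                      offspring_range = c(220, 240), selection = "phenotypic",
                      seed = 900 + seed)
    sim <- simulate_program(cfg)
    m <- sim$per_generation$x
    f <- sim$per_generation$mean_F
    (m[4] > m[1]) && all(diff(f) >= 0)
  }, logical(1))
  expect_gte(sum(ups), 5L)
})

test_that("unselected drift leaves no systematic trend in mean breeding value", {
  slopes <- vapply(1:8, function(seed) {
    cfg <- sim_config(traits = "x", G0 = 4, R0 = 6, n_sires = 10, n_dams = 50,
                      dams_per_sire = 5, n_generations = 3, n_recorded = Inf,
                      offspring_range = c(200, 220), selection = "none",
                      seed = 300 + seed)
    sim <- simulate_program(cfg)
    unname(coef(lm(sim$per_generation$x ~ sim$per_generation$generation))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)) + 0.05)
})

test_that("mid-parent regression recovers the configured heritability", {
  cfg <- sim_config(traits = "x", G0 = 40, R0 = 60, n_sires = 20, n_dams = 100,
                    dams_per_sire = 5, n_generations = 2, n_recorded = Inf,
                    offspring_range = c(900, 950), selection = "none", seed = 42)
  sim <- simulate_program(cfg)
  ped <- as.data.frame(sim$pedigree)
  ph <- sim$phenotypes
  kids <- ped[ped$generation == 2, ]
  y <- ph$x[match(kids$animal, ph$animal)]
  mp <- 0.5 * (ph$x[match(kids$sire, ph$animal)] + ph$x[match(kids$dam, ph$animal)])
  ok <- !is.na(mp) & !is.na(y)
  h2_real <- unname(coef(lm(y[ok] ~ mp[ok]))[2])
  expect_lt(abs(h2_real - 0.4), 0.12)   # ~3 SEs at this scale
})

test_that("simulator exports round-trip through the file interface", {
  cfg <- sim_config(traits = c("BW0", "AFE"), G0 = diag(c(8, 80)),
                    R0 = diag(c(5, 230)), means = c(BW0 = 38, AFE = 168),
                    sex_limited = "AFE", integer_traits = "AFE",
                    n_sires = 10, n_dams = 50, dams_per_sire = 5,
                    n_generations = 2, n_recorded = Inf,
                    offspring_range = c(150, 160), selection = "none", seed = 3)
  sim <- simulate_program(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_output(sim, dir, oracle = TRUE)
  ped2 <- read_pedigree(paths[["pedigree"]])
  ph2 <- read_phenotypes(paths[["phenotypes"]])
  expect_identical(as.data.frame(ped2), as.data.frame(sim$pedigree))
  expect_equal(ph2$BW0, sim$phenotypes$BW0, tolerance = 1e-8)
  # true breeding values never leak into the phenotype export
  expect_false(any(grepl("bv", names(ph2), ignore.case = TRUE)))
  expect_true(file.exists(paths[["true_bv"]]))
})
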