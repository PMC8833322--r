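# Stochastic closed-nucleus breeding-program simulator: 30 sires x 150 dams
# (5 hens per cock), offspring hatched in sets, truncation selection of
# replacements each cycle, multivariate additive genetics with Mendelian
# sampling that accounts for parental inbreeding, and sex-limited egg traits.
# The generator is the package's synthetic-data source: its outputs feed every
# other module and carry the true breeding values needed for oracle tests.

#' Covariance matrix from variances and a correlation matrix
#'
#' `Sigma_ij = r_ij * sqrt(v_i * v_j)`. If the result is not positive
#' definite (printed correlation tables often are not, having been estimated
#' pairwise), it is repaired on the correlation scale with [Matrix::nearPD()]
#' and rescaled to the original variances; the largest absolute change to any
#' correlation is reported in attribute `"repair"` and via a message.
#'
#' @param variances positive per-trait variances (named).
#' @param correlations symmetric correlation matrix with unit diagonal,
#'   entries in `[-1, 1]`.
#' @param min_eigen smallest admissible eigenvalue, as a fraction of the mean
#'   diagonal (default `1e-6`).
#' @return covariance matrix (PD), dimnames from `variances`.
#' @export
assemble_covariance <- function(variances, correlations, min_eigen = 1e-6) {
  v <- unlist(variances)
  if (any(v <= 0)) stop("variances must be positive")
  R <- as.matrix(correlations)
  if (any(abs(R) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10)
    stop("correlation matrix must be symmetric with unit diagonal")
  repair <- 0
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < min_eigen) {
    Rfix <- as.matrix(Matrix::nearPD(R, corr = TRUE, eig.tol = min_eigen)$mat)
    repair <- max(abs(Rfix - R))
    message(sprintf("correlation matrix repaired to positive definite (max |change| = %.4f)", repair))
    R <- Rfix
  }
  s <- sqrt(v)
  Sigma <- R * tcrossprod(s)
  dimnames(Sigma) <- if (!is.null(names(v))) list(names(v), names(v)) else dimnames(R)
  attr(Sigma, "repair") <- repair
  Sigma
}

#' Effective population size for unequal sex numbers
#'
#' `Ne = 4 Nm Nf / (Nm + Nf)`: with 30 sires and 150 dams this gives the
#' nucleus an effective size of 100.
#'
#' @param n_males,n_females numbers of breeding males and females (positive).
#' @return effective population size.
#' @export
effective_population_size <- function(n_males, n_females) {
  if (any(n_males <= 0) || any(n_females <= 0)) stop("parent counts must be positive")
  4 * n_males * n_females / (n_males + n_females)
}

#' Configure the closed-nucleus simulator
#'
#' The defaults are the nucleus structure of the emulated breeding program:
#' 30 sires each mated to 5 hens (150 dams, effective population size 100),
#' six discrete generations, offspring hatched in 3 sets with per-generation
#' hatch counts drawn from 1500-1800, about 452 birds recorded per generation
#' (2712 phenotyped in total), and replacements taken from the top 20% of the
#' recorded flock by a phenotypic selection index.
#'
#' @param traits trait codes.
#' @param G0,R0 true additive and residual covariance matrices (scalars for a
#'   single trait); repaired inputs can be built with [assemble_covariance()].
#' @param means per-trait population means.
#' @param n_sires,n_dams,dams_per_sire nucleus structure; `n_dams` must equal
#'   `n_sires * dams_per_sire`.
#' @param n_generations number of offspring generations (founders are
#'   generation 0).
#' @param hatch_sets number of hatch sets per generation.
#' @param offspring_range range the per-generation hatch count is drawn from.
#' @param n_recorded birds phenotyped per generation (replacements are chosen
#'   among these); `Inf` records every bird.
#' @param selected_proportion truncation proportion for the candidate pool.
#' @param selection `"phenotypic"` (standardised phenotypic index; the
#'   realistic mode), `"oracle"` (index on true breeding values), `"blup"`
#'   (re-runs the animal-model BLUP each cycle; desk-scale configs only) or
#'   `"none"` (random replacements).
#' @param criterion named weights of the selection criterion over (a subset
#'   of) the traits; negative weight = lower is better. Default: equal
#'   positive weights, except `AFE` which is weighted negatively when present.
#' @param sex_effects named additive effects for males (sexual dimorphism);
#'   default none.
#' @param hatch_effects `hatch_sets`-by-traits matrix of hatch-set effects;
#'   default none.
#' @param sex_limited trait codes recorded on females only.
#' @param integer_traits trait codes rounded to whole numbers (egg counts,
#'   days).
#' @param bw0_subthreshold_rate fraction of recorded chicks injected with a
#'   below-threshold birth weight (quality-control fodder for the editing
#'   filters; default 0).
#' @param seed mandatory RNG seed (reproducibility contract: same config and
#'   seed give byte-identical outputs).
#' @param prune_pedigree export only recorded animals and their ancestors
#'   (the traced pedigree a breeding program would keep); `FALSE` keeps every
#'   hatched chick.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(traits, G0, R0, means = NULL,
                       n_sires = 30L, n_dams = 150L, dams_per_sire = 5L,
                       n_generations = 6L, hatch_sets = 3L,
                       offspring_range = c(1500L, 1800L),
                       n_recorded = 452L,
                       selected_proportion = 0.2,
                       selection = c("phenotypic", "oracle", "blup", "none"),
                       criterion = NULL,
                       sex_effects = NULL, hatch_effects = NULL,
                       sex_limited = character(0),
                       integer_traits = character(0),
                       bw0_subthreshold_rate = 0,
                       seed = NULL,
                       prune_pedigree = TRUE) {
  selection <- match.arg(selection)
  t <- length(traits)
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  if (n_dams != n_sires * dams_per_sire)
    stop("n_dams must equal n_sires * dams_per_sire")
  if (is.null(means)) means <- rep(0, t)
  means <- if (is.null(names(means))) stats::setNames(rep_len(means, t), traits) else means[traits]
  if (anyNA(means)) stop("means must cover every trait")
  if (is.null(sex_effects)) sex_effects <- stats::setNames(rep(0, t), traits)
  se <- stats::setNames(rep(0, t), traits); se[names(sex_effects)] <- sex_effects
  if (is.null(hatch_effects)) hatch_effects <- matrix(0, hatch_sets, t)
  hatch_effects <- as.matrix(hatch_effects)
  stopifnot(nrow(hatch_effects) == hatch_sets, ncol(hatch_effects) == t)
  if (is.null(criterion)) {
    criterion <- stats::setNames(rep(1 / t, t), traits)
    if ("AFE" %in% traits) criterion["AFE"] <- -criterion["AFE"]
  }
  structure(list(traits = traits, G0 = G0, R0 = R0, means = means,
                 n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
                 dams_per_sire = as.integer(dams_per_sire),
                 n_generations = as.integer(n_generations),
                 hatch_sets = as.integer(hatch_sets),
                 offspring_range = as.integer(offspring_range),
                 n_recorded = n_recorded,
                 selected_proportion = selected_proportion,
                 selection = selection, criterion = criterion,
                 sex_effects = se, hatch_effects = hatch_effects,
                 sex_limited = sex_limited, integer_traits = integer_traits,
                 bw0_subthreshold_rate = bw0_subthreshold_rate,
                 seed = seed, prune_pedigree = prune_pedigree),
            class = "sim_config")
}

#' Simulator configuration with the published KM2 parameters
#'
#' Builds the full 11-trait configuration: covariances assembled from the
#' published per-trait variances and the genetic/phenotypic correlation
#' tables (PD-repaired where needed; the residual covariance is the
#' phenotypic minus the genetic covariance), published trait means, egg
#' traits female-only, male body-weight advantage from 4 weeks on, and mild
#' hatch-set effects.
#'
#' @param traits subset of the 11 KM2 traits (default all).
#' @param ... overrides passed on to [sim_config()].
#' @return object of class `sim_config`.
#' @export
km2_sim_config <- function(traits = km2_trait_names, ...) {
  truth <- km2_sim_truth()
  i <- match(traits, truth$trait)
  if (anyNA(i)) stop("unknown KM2 trait(s): ", paste(traits[is.na(i)], collapse = ", "))
  va <- stats::setNames(truth$va[i], traits)
  ve <- stats::setNames(truth$ve[i], traits)
  vt <- va + ve
  G0 <- assemble_covariance(va, km2_genetic_correlations[traits, traits, drop = FALSE])
  P  <- assemble_covariance(vt, km2_phenotypic_correlations[traits, traits, drop = FALSE])
  R0 <- P - G0
  ev <- eigen(R0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6 * mean(diag(R0))) {
    R0 <- as.matrix(Matrix::nearPD(R0, keepDiag = TRUE)$mat)
    message("residual covariance repaired to positive definite")
  }
  desc <- km2_descriptives[match(traits, km2_descriptives$trait), ]
  sex_eff <- c(BW4 = 80, BW6 = 120, BW8 = 180, BW10 = 250)
  sex_eff <- sex_eff[names(sex_eff) %in% traits]
  hatch_eff <- outer(c(-0.15, 0, 0.15), desc$sd)
  crit <- c(BW6 = 0.25, BrC6 = 0.25, `240EP` = 0.30, AFE = -0.20)
  crit <- crit[names(crit) %in% traits]
  if (!length(crit)) crit <- NULL
  sim_config(traits = traits, G0 = G0, R0 = R0,
             means = stats::setNames(desc$mean, traits),
             sex_effects = sex_eff, hatch_effects = hatch_eff,
             sex_limited = intersect(traits, c("AFE", "240EP", "270EP", "300EP", "365EP")),
             integer_traits = intersect(traits, c("AFE", "240EP", "270EP", "300EP", "365EP")),
             criterion = crit, ...)
}

#' Produce one generation of offspring
#'
#' Mates each sire to `dams_per_sire` dams, allocates offspring to hatch
#' sets, assigns sex 1:1, and draws each offspring's true breeding value as
#' the parent average plus a Mendelian-sampling deviation with covariance
#' `0.5 * (1 - (F_s + F_d)/2) * G0`. With `G0 = 0` offspring breeding values
#' equal the parent average exactly.
#'
#' @param sires,dams data.frames with columns `id`, `F`, and the true
#'   breeding values in `bv` (matrix column); at least `n_sires`/`n_dams`
#'   rows.
#' @param config a [sim_config()].
#' @param n_offspring total offspring to produce (default: drawn from
#'   `config$offspring_range`).
#' @param generation generation label for the offspring.
#' @return data.frame of offspring (`id`, `sire`, `dam`, `sex`, `generation`,
#'   `hatch_set`, `F` placeholder) with the true-BV matrix in `bv`.
#' @export
simulate_generation <- function(sires, dams, config, n_offspring = NULL,
                                generation = 1L) {
  t <- length(config$traits)
  if (nrow(sires) < config$n_sires || nrow(dams) < config$n_dams)
    stop("insufficient parents: need ", config$n_sires, " sires and ",
         config$n_dams, " dams")
  sires <- sires[seq_len(config$n_sires), , drop = FALSE]
  dams <- dams[seq_len(config$n_dams), , drop = FALSE]
  if (is.null(n_offspring))
    n_offspring <- sample(config$offspring_range[1L]:config$offspring_range[2L], 1L)

  # pair every sire with dams_per_sire dams, avoiding full-sib and
  # parent-offspring matings where a reshuffle can manage it
  dam_order <- sample.int(nrow(dams))
  related <- function(si, di) {
    (!is.na(sires$sire[si]) && !is.na(dams$sire[di]) && sires$sire[si] == dams$sire[di]) ||
    (!is.na(sires$dam[si]) && !is.na(dams$dam[di]) && sires$dam[si] == dams$dam[di]) ||
    identical(sires$id[si], dams$sire[di]) || identical(dams$id[di], sires$sire[si])
  }
  pair_sire <- rep(seq_len(config$n_sires), each = config$dams_per_sire)
  for (pos in seq_along(dam_order)) {
    if (related(pair_sire[pos], dam_order[pos])) {
      for (alt in seq_along(dam_order)) {
        if (alt != pos && !related(pair_sire[pos], dam_order[alt]) &&
            !related(pair_sire[alt], dam_order[pos])) {
          tmp <- dam_order[pos]; dam_order[pos] <- dam_order[alt]; dam_order[alt] <- tmp
          break
        }
      }
    }
  }

  n_pairs <- length(pair_sire)
  base <- n_offspring %/% n_pairs
  extra <- sample.int(n_pairs, n_offspring %% n_pairs)
  counts <- rep(base, n_pairs); counts[extra] <- counts[extra] + 1L
  off_sire <- rep(pair_sire, counts)
  off_dam  <- rep(dam_order, counts)
  hatch <- unlist(lapply(counts, function(k) rep_len(seq_len(config$hatch_sets), k)),
                  use.names = FALSE)

  bv_s <- sires$bv[off_sire, , drop = FALSE]
  bv_d <- dams$bv[off_dam, , drop = FALSE]
  scale <- sqrt(pmax(0.5 * (1 - (sires$F[off_sire] + dams$F[off_dam]) / 2), 0))
  if (all(config$G0 == 0)) {
    mend <- matrix(0, n_offspring, t)
  } else {
    mend <- MASS::mvrnorm(n_offspring, rep(0, t), config$G0) * scale
    if (n_offspring == 1L) mend <- matrix(mend, 1L)
  }
  bv <- 0.5 * (bv_s + bv_d) + mend
  colnames(bv) <- config$traits

  out <- data.frame(
    id = sprintf("G%d_%05d", generation, seq_len(n_offspring)),
    sire = sires$id[off_sire], dam = dams$id[off_dam],
    sex = sample(c("M", "F"), n_offspring, replace = TRUE),
    generation = generation, hatch_set = as.character(hatch),
    stringsAsFactors = FALSE)
  out$bv <- bv
  out
}

# phenotypes for the recorded subset of one generation
sim_phenotypes <- function(off, config) {
  t <- length(config$traits)
  n <- nrow(off)
  e <- MASS::mvrnorm(n, rep(0, t), config$R0)
  if (n == 1L) e <- matrix(e, 1L)
  y <- sweep(off$bv + e, 2L, config$means, "+")
  y <- y + config$hatch_effects[as.integer(off$hatch_set), , drop = FALSE]
  male <- off$sex == "M"
  y[male, ] <- sweep(y[male, , drop = FALSE], 2L, config$sex_effects, "+")
  colnames(y) <- config$traits
  for (tr in config$sex_limited) y[male, tr] <- NA
  for (tr in config$integer_traits) y[, tr] <- round(y[, tr])
  y
}

#' Run the closed-nucleus breeding-program simulation
#'
#' Generation cycle: hatch offspring from the current parent stock
#' ([simulate_generation()]), record a subset, apply the configured selection
#' rule to the recorded candidates, and promote the top `n_sires` cocks and
#' `n_dams` hens (from the top `selected_proportion` of each sex) to parent
#' the next generation. Phenotypes are trait mean + hatch-set effect + sex
#' effect (males) + true breeding value + residual; egg traits are recorded
#' on hens only. True breeding values are returned separately and never
#' appear in the exported phenotype table.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` (one of the two must be set).
#' @return object of class `sim_output`: `pedigree` ([pedigree()] object),
#'   `phenotypes` (recorded animals only), `true_bv` (matrix over the
#'   exported pedigree), `per_generation` (mean true BV and inbreeding of
#'   every hatched chick per generation), `injected_ids` (sub-threshold birth
#'   weights), `parents` (selected ids per cycle), `config`.
#' @export
simulate_program <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required (set it in the config or pass `seed`)")
  set.seed(seed)
  t <- length(config$traits)

  nf <- config$n_sires + config$n_dams
  founders <- data.frame(
    id = sprintf("G0_%05d", seq_len(nf)),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), c(config$n_sires, config$n_dams)),
    generation = 0L, hatch_set = NA_character_,
    stringsAsFactors = FALSE)
  founders$bv <- MASS::mvrnorm(nf, rep(0, t), config$G0)
  colnames(founders$bv) <- config$traits
  founders$F <- 0

  all_gen <- list(founders)
  pheno_rows <- list()
  recorded_ids <- character(0)
  injected <- character(0)
  parents_log <- list()
  per_gen <- data.frame(generation = 0L, n = nf, mean_F = 0,
                        t(colMeans(founders$bv)), check.names = FALSE)
  parent_pool <- founders
  parent_pool$recorded <- TRUE

  for (g in seq_len(config$n_generations)) {
    sires <- parent_pool[parent_pool$sex == "M", , drop = FALSE]
    dams  <- parent_pool[parent_pool$sex == "F", , drop = FALSE]
    off <- simulate_generation(sires, dams, config, generation = g)

    # inbreeding of the new cohort from the accumulated pedigree
    ped_ids <- c(unlist(lapply(all_gen, `[[`, "id")), off$id)
    ped_sire <- c(unlist(lapply(all_gen, `[[`, "sire")), off$sire)
    ped_dam <- c(unlist(lapply(all_gen, `[[`, "dam")), off$dam)
    si <- match(ped_sire, ped_ids); si[is.na(si)] <- 0L
    di <- match(ped_dam, ped_ids); di[is.na(di)] <- 0L
    Fall <- ml_inbreeding(si, di)
    off$F <- Fall[match(off$id, ped_ids)]

    n_rec <- min(nrow(off), config$n_recorded)
    rec_idx <- sort(sample.int(nrow(off), n_rec))
    rec <- off[rec_idx, , drop = FALSE]
    y <- sim_phenotypes(rec, config)
    if (config$bw0_subthreshold_rate > 0 && "BW0" %in% config$traits) {
      hit <- which(stats::runif(n_rec) < config$bw0_subthreshold_rate)
      if (length(hit)) {
        y[hit, "BW0"] <- stats::runif(length(hit), 20, 25.9)
        injected <- c(injected, rec$id[hit])
      }
    }
    pheno_rows[[g]] <- data.frame(animal = rec$id, y, check.names = FALSE,
                                  stringsAsFactors = FALSE)
    recorded_ids <- c(recorded_ids, rec$id)

    per_gen <- rbind(per_gen,
                     data.frame(generation = g, n = nrow(off), mean_F = mean(off$F),
                                t(colMeans(off$bv)), check.names = FALSE))
    all_gen[[g + 1L]] <- off

    if (g < config$n_generations) {
      parent_pool <- next_parents(rec, y, config, all_gen, pheno_rows)
      parents_log[[g]] <- parent_pool$id
    }
  }

  ped_df <- do.call(rbind, lapply(all_gen, function(d)
    d[, c("id", "sire", "dam", "sex", "generation", "hatch_set")]))
  bv_all <- do.call(rbind, lapply(all_gen, `[[`, "bv"))
  rownames(bv_all) <- ped_df$id

  if (config$prune_pedigree) {
    keep <- ped_df$id %in% c(recorded_ids, founders$id)
    repeat {
      need <- unique(c(ped_df$sire[keep], ped_df$dam[keep]))
      grow <- !keep & ped_df$id %in% need
      if (!any(grow)) break
      keep <- keep | grow
    }
    ped_df <- ped_df[keep, , drop = FALSE]
    bv_all <- bv_all[keep, , drop = FALSE]
  }
  names(ped_df)[1L] <- "animal"
  ped <- pedigree(ped_df)
  bv_all <- bv_all[match(animal_ids(ped), rownames(bv_all)), , drop = FALSE]

  structure(list(pedigree = ped,
                 phenotypes = do.call(rbind, pheno_rows),
                 true_bv = bv_all,
                 per_generation = per_gen,
                 injected_ids = injected,
                 parents = parents_log,
                 config = config, seed = seed),
            class = "sim_output")
}

# rank recorded candidates and promote replacements
next_parents <- function(rec, y, config, all_gen, pheno_rows) {
  crit_traits <- names(config$criterion)
  score <- switch(config$selection,
    none = stats::setNames(stats::runif(nrow(rec)), rec$id),
    oracle = {
      M <- rec$bv[, crit_traits, drop = FALSE]
      stats::setNames(drop(M %*% config$criterion), rec$id)
    },
    phenotypic = phenotypic_index(rec, y, config),
    blup = blup_index(config, all_gen, pheno_rows, rec$id)
  )
  pool_ids <- if (config$selection == "none") rec$id
              else truncate_top(score, config$selected_proportion, sex = rec$sex)
  # The truncation proportion and the replacement quota are configured
  # independently; when the top-p pool is smaller than the quota the
  # remaining replacements are the next-best candidates in criterion order.
  pick_sex <- function(code, need) {
    ids <- rec$id[rec$sex == code]
    ranked <- names(sort(score[ids], decreasing = TRUE))
    pool <- intersect(ranked, pool_ids)
    if (length(pool) < need) pool <- c(pool, setdiff(ranked, pool))
    if (length(pool) < need)
      stop("not enough recorded ", if (code == "M") "males" else "females",
           " to fill the replacement quota")
    pool[seq_len(need)]
  }
  chosen <- c(pick_sex("M", config$n_sires), pick_sex("F", config$n_dams))
  out <- rec[match(chosen, rec$id), , drop = FALSE]
  out$recorded <- TRUE
  out
}

# standardised within-sex phenotypic index; weights renormalised over the
# traits each animal actually expresses (males lack the egg traits)
phenotypic_index <- function(rec, y, config) {
  crit <- config$criterion
  Z <- matrix(0, nrow(rec), length(crit), dimnames = list(rec$id, names(crit)))
  ok <- matrix(FALSE, nrow(rec), length(crit))
  for (j in seq_along(crit)) {
    tr <- names(crit)[j]
    v <- y[, tr]
    for (s in unique(rec$sex)) {
      idx <- rec$sex == s & !is.na(v)
      if (sum(idx) >= 2L) {
        Z[idx, j] <- (v[idx] - mean(v[idx])) / stats::sd(v[idx])
        ok[idx, j] <- TRUE
      }
    }
  }
  w <- abs(crit)
  sgn <- sign(crit)
  tot <- ok %*% w
  tot[tot == 0] <- 1
  stats::setNames(drop((Z * rep(sgn, each = nrow(Z))) %*% w / tot), rec$id)
}

# full animal-model BLUP on all data so far; index over the criterion traits
blup_index <- function(config, all_gen, pheno_rows, candidate_ids) {
  ped_df <- do.call(rbind, lapply(all_gen, function(d)
    d[, c("id", "sire", "dam", "sex", "generation", "hatch_set")]))
  names(ped_df)[1L] <- "animal"
  ped <- pedigree(ped_df)
  pheno <- do.call(rbind, pheno_rows)
  crit_traits <- names(config$criterion)
  spec <- model_spec(crit_traits, fixed = c("hatch_set", "sex"),
                     sex_limited = intersect(crit_traits, config$sex_limited))
  design <- build_design(pheno, spec, ped)
  vc <- variance_components(config$G0[crit_traits, crit_traits, drop = FALSE],
                            config$R0[crit_traits, crit_traits, drop = FALSE])
  fit <- solve_mme(design, a_inverse(ped), vc, pev = FALSE)
  M <- fit$ebv[candidate_ids, crit_traits, drop = FALSE]
  stats::setNames(drop(M %*% config$criterion), candidate_ids)
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Closed-nucleus simulation:", x$config$n_generations, "generations,",
      n_animals(x$pedigree), "animals in the exported pedigree,",
      nrow(x$phenotypes), "recorded\n")
  print(x$per_generation, row.names = FALSE)
  invisible(x)
}

#' Write simulator output to delimited text files
#'
#' Emits the pedigree and phenotype files in the formats consumed by
#' [read_pedigree()] / [read_phenotypes()], and (optionally) the true
#' breeding values to a separate oracle file — truths are never mixed into
#' the phenotype export.
#'
#' @param sim a [simulate_program()] result.
#' @param dir output directory (created if needed).
#' @param oracle also write `true_bv.tsv` (default `FALSE`).
#' @return invisibly, the paths written.
#' @export
write_sim_output <- function(sim, dir, oracle = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pedigree = file.path(dir, "pedigree.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_pedigree(sim$pedigree, paths[["pedigree"]])
  write_phenotypes(sim$phenotypes, paths[["phenotypes"]])
  if (oracle) {
    paths[["true_bv"]] <- file.path(dir, "true_bv.tsv")
    utils::write.table(data.frame(animal = rownames(sim$true_bv), sim$true_bv,
                                  check.names = FALSE),
                       paths[["true_bv"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
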