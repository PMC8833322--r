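# End-to-end orchestration: simulate or load data, edit, summarise, estimate
# variance components, predict breeding values, summarise genetic trends and
# expected progress, rank on the selection index, and write plain-text report
# tables. All randomness flows from the single config seed.

#' Read a flat key=value run configuration
#'
#' One `key=value` per line, `#` comments and blank lines ignored.
#' Recognised keys (all optional unless noted): `mode`
#' (`simulate`/`analyze`/`run`), `seed` (required for simulation), `outdir`,
#' `traits` (comma-separated; default all 11 KM2 traits), `n_generations`,
#' `n_recorded`, `offspring_min`, `offspring_max`, `selection`, `proportion`,
#' `pedigree_file`, `phenotype_file`, `bw_threshold`, `reml_max_iter`,
#' `reml_tol`, `block_size`, `bw_trait`, `ep_trait`.
#'
#' @param path config file path.
#' @return named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) config_error("malformed config line: ", lines[bad][1L])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  cfg <- stats::setNames(as.list(vals), keys)
  num <- c("seed", "n_generations", "n_recorded", "n_sires", "n_dams",
           "offspring_min", "offspring_max",
           "proportion", "bw_threshold", "reml_max_iter", "reml_tol", "block_size")
  for (k in intersect(num, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
  if ("traits" %in% names(cfg)) cfg$traits <- trimws(strsplit(cfg$traits, ",")[[1L]])
  structure(cfg, class = "run_config")
}

config_error <- function(...) stop(errorCondition(paste0(...), class = c("config_error", "error")))
data_error <- function(...) stop(errorCondition(paste0(...), class = c("data_error", "error")))
convergence_error <- function(...) stop(errorCondition(paste0(...), class = c("convergence_error", "error")))

pipeline_defaults <- function(cfg) {
  def <- list(mode = "run", outdir = "pedindex_out", traits = km2_trait_names,
              n_generations = 6, n_recorded = 452, n_sires = 30, n_dams = 150,
              offspring_min = 1500, offspring_max = 1800,
              selection = "phenotypic", proportion = 0.2, bw_threshold = 26,
              reml_max_iter = 100, reml_tol = 1e-6, block_size = 4,
              bw_trait = "BW6", ep_trait = "240EP")
  def[names(cfg)] <- cfg
  def
}

#' Run the full evaluation pipeline
#'
#' Stages: simulate (or read) pedigree + phenotypes, edit (birth-weight
#' discard + lower-IQR outliers), descriptive statistics, AI-REML variance
#' components in trait blocks, multi-trait BLUP with accuracies, genetic
#' trend and expected progress, selection index and top-fraction selection.
#' Writes plain-text report tables to `outdir` plus a structured log
#' recording every filter count, iteration count and repair. Any stage
#' failure aborts with the stage name in the message and no partial tables.
#'
#' @param config a list / [read_run_config()] result; see that help page for
#'   the keys. Alternatively pass a ready-made [sim_config()] as
#'   `config$sim_config`.
#' @return invisibly, a list with every stage's results and the paths of the
#'   written reports.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_defaults(config)
  results <- list()
  log <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, c("config_error", "data_error", "convergence_error"))) stop(e)
      stop(errorCondition(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                          class = c("data_error", "error")))
    })
  }

  # --- data stage ------------------------------------------------------
  simulate <- is.null(cfg$pedigree_file)
  if (simulate) {
    if (is.null(cfg$seed)) config_error("simulation requires a seed")
    sim_cfg <- cfg$sim_config
    if (is.null(sim_cfg)) {
      if (cfg$n_dams %% cfg$n_sires != 0) config_error("n_dams must be a multiple of n_sires")
      sim_cfg <- km2_sim_config(
        traits = cfg$traits,
        n_generations = as.integer(cfg$n_generations),
        n_recorded = cfg$n_recorded,
        n_sires = as.integer(cfg$n_sires), n_dams = as.integer(cfg$n_dams),
        dams_per_sire = as.integer(cfg$n_dams / cfg$n_sires),
        offspring_range = c(as.integer(cfg$offspring_min), as.integer(cfg$offspring_max)),
        selection = cfg$selection,
        selected_proportion = cfg$proportion,
        seed = as.integer(cfg$seed))
    }
    note("simulating: ", sim_cfg$n_generations, " generations, traits ",
         paste(sim_cfg$traits, collapse = ","), ", seed ", cfg$seed)
    sim <- stage("simulate", simulate_program(sim_cfg, seed = as.integer(cfg$seed)))
    ped <- sim$pedigree
    pheno <- sim$phenotypes
    results$sim <- sim
    cfg$traits <- sim_cfg$traits
  } else {
    if (!file.exists(cfg$pedigree_file)) data_error("pedigree file not found: ", cfg$pedigree_file)
    if (is.null(cfg$phenotype_file) || !file.exists(cfg$phenotype_file))
      data_error("phenotype file not found: ", cfg$phenotype_file %||% "<unset>")
    ped <- stage("read", read_pedigree(cfg$pedigree_file))
    pheno <- stage("read", read_phenotypes(cfg$phenotype_file))
    cfg$traits <- intersect(cfg$traits, names(pheno))
  }
  note("data: ", n_animals(ped), " pedigree animals, ", nrow(pheno), " phenotyped")

  # --- editing + descriptives -----------------------------------------
  ed <- stage("edit", edit_phenotypes(pheno, traits = cfg$traits,
                                      bw_threshold = if ("BW0" %in% cfg$traits) cfg$bw_threshold else NA))
  note("editing removed ", nrow(ed$removed_animals), " animal(s); masked ",
       sum(ed$n_masked), " record(s)")
  pheno <- ed$data
  results$edit <- ed
  results$descriptives <- stage("descriptives", descriptive_stats(pheno, cfg$traits))

  # --- variance components in trait blocks ----------------------------
  blocks <- split(cfg$traits, ceiling(seq_along(cfg$traits) / cfg$block_size))
  ainv <- stage("pedigree", a_inverse(ped))
  t_all <- length(cfg$traits)
  G0 <- R0 <- matrix(NA_real_, t_all, t_all, dimnames = list(cfg$traits, cfg$traits))
  h2_rows <- list()
  ebv <- acc <- matrix(NA_real_, n_animals(ped), t_all,
                       dimnames = list(animal_ids(ped), cfg$traits))
  for (b in seq_along(blocks)) {
    trs <- blocks[[b]]
    note("REML block ", b, ": ", paste(trs, collapse = ","))
    spec <- model_spec(trs)
    design <- stage("design", build_design(pheno, spec, ped))
    fit <- stage("reml", ai_reml(design, ainv, max_iter = as.integer(cfg$reml_max_iter),
                                 tol_param = cfg$reml_tol))
    note("REML block ", b, ": ", fit$n_iter, " iterations, ",
         if (fit$converged) "converged" else "NOT converged")
    if (!fit$converged) convergence_error("REML did not converge for block ",
                                          paste(trs, collapse = ","))
    G0[trs, trs] <- fit$vc$G0
    R0[trs, trs] <- fit$vc$R0
    h2_rows[[b]] <- fit$h2
    blup <- stage("blup", solve_mme(design, ainv, fit$vc, pev = TRUE))
    ebv[, trs] <- blup$ebv
    acc[, trs] <- blup$accuracy
    results$reml[[b]] <- fit
  }
  results$h2 <- do.call(rbind, h2_rows)
  results$G0 <- G0; results$R0 <- R0
  results$ebv <- ebv; results$accuracy <- acc

  # --- trends, progress, index ----------------------------------------
  gen <- ped$data$generation
  results$trend <- stage("trend", genetic_trend(ebv, gen))
  i_sel <- selection_intensity(cfg$proportion)
  recorded <- animal_ids(ped) %in% pheno$animal
  results$progress <- data.frame(
    trait = cfg$traits,
    sigma_a = sqrt(diag(G0)),
    mean_accuracy = colMeans(acc[recorded, , drop = FALSE]),
    intensity = i_sel,
    delta_g = delta_g(sqrt(diag(G0)), colMeans(acc[recorded, , drop = FALSE]), i_sel),
    slope = results$trend$slope, stringsAsFactors = FALSE)

  idx_spec <- selection_index_spec(bw_trait = cfg$bw_trait, ep_trait = cfg$ep_trait)
  if (all(idx_spec$traits %in% cfg$traits) && !anyNA(G0[idx_spec$traits, idx_spec$traits])) {
    trs <- idx_spec$traits
    v <- unname(idx_spec$weights)
    P <- G0[trs, trs] + R0[trs, trs]
    b <- stage("index", index_coefficients(P, G0[trs, trs], v))
    r <- stage("index", index_accuracy(P, G0[trs, trs], v))
    I <- stage("index", ebv_index(ebv[recorded, , drop = FALSE], idx_spec))
    sel <- truncate_top(I, cfg$proportion, sex = ped$data$sex[match(names(I), animal_ids(ped))])
    results$index <- list(spec = idx_spec, b = b, accuracy = r, values = I, selected = sel)
    note("index: accuracy ", round(as.numeric(r), 3), ", selected ", length(sel),
         " of ", length(I))
  }

  # --- reports ---------------------------------------------------------
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage("report", write_reports(results, cfg, ped))
  writeLines(log, file.path(cfg$outdir, "log.txt"))
  results$paths <- paths
  results$log <- log
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format pipeline results as report tables
#'
#' Returns the descriptive, variance-component and correlation reports as
#' data.frames of formatted strings, following the conventional precision:
#' one decimal for descriptive statistics, three for heritabilities, two for
#' correlations (genetic above the diagonal, phenotypic below, `-` on it).
#'
#' @param results a [run_pipeline()] result list (fields `descriptives`,
#'   `h2`, `G0`, `R0`).
#' @return list of data.frames `descriptives`, `variance_components`,
#'   `correlations`.
#' @export
report_tables <- function(results) {
  if (is.null(results$descriptives) || nrow(results$descriptives) == 0L)
    stop("empty result set: nothing to report")
  d <- results$descriptives
  desc <- data.frame(trait = d$trait, n = d$n_records,
                     mean = fmt1(d$mean), sd = fmt1(d$sd),
                     min = fmt1(d$min), max = fmt1(d$max),
                     cv_percent = fmt1(d$cv_percent), stringsAsFactors = FALSE)
  out <- list(descriptives = desc)
  if (!is.null(results$h2)) {
    h <- results$h2
    out$variance_components <- data.frame(
      trait = h$trait, sigma_a2 = fmt(h$va, 2), sigma_e2 = fmt(h$ve, 2),
      sigma_t2 = fmt(h$vt, 2), h2 = fmt(h$h2, 3),
      se = fmt(h$se, 2), stringsAsFactors = FALSE)
  }
  if (!is.null(results$G0)) {
    trs <- colnames(results$G0)
    vt <- diag(results$G0) + diag(results$R0)
    M <- matrix("-", length(trs), length(trs), dimnames = list(trs, trs))
    for (i in seq_along(trs)) for (j in seq_along(trs)) {
      if (i < j) M[i, j] <- fmt(results$G0[i, j] / sqrt(results$G0[i, i] * results$G0[j, j]), 2)
      if (i > j) M[i, j] <- fmt((results$G0[i, j] + results$R0[i, j]) / sqrt(vt[i] * vt[j]), 2)
    }
    M[M == "NA"] <- ""
    out$correlations <- data.frame(trait = trs, M, check.names = FALSE,
                                   stringsAsFactors = FALSE)
  }
  out
}

fmt <- function(x, digits) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
fmt1 <- function(x) fmt(x, 1)

write_reports <- function(results, cfg, ped) {
  tabs <- report_tables(results)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(cfg$outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  wt(tabs$descriptives, "table1_descriptives.tsv")
  if (!is.null(tabs$variance_components)) wt(tabs$variance_components, "table2_variance_components.tsv")
  if (!is.null(tabs$correlations)) wt(tabs$correlations, "table3_correlations.tsv")
  if (!is.null(results$trend)) {
    tr <- results$trend
    wt(data.frame(generation = tr$means$generation,
                  lapply(tr$means[-1L], function(x) fmt(x, 3)), check.names = FALSE),
       "trend_by_generation.tsv")
    wt(data.frame(trait = results$progress$trait,
                  sigma_a = fmt(results$progress$sigma_a, 3),
                  mean_accuracy = fmt(results$progress$mean_accuracy, 3),
                  intensity = fmt(results$progress$intensity, 3),
                  delta_g = fmt(results$progress$delta_g, 3),
                  realized_slope = fmt(results$progress$slope, 3)),
       "genetic_progress.tsv")
  }
  if (!is.null(results$index)) {
    ids <- names(results$index$values)
    sex <- ped$data$sex[match(ids, animal_ids(ped))]
    wt(data.frame(animal_id = ids, sex = sex,
                  index = fmt(results$index$values, 4),
                  selected = as.integer(ids %in% results$index$selected)),
       "selection_index.tsv")
    spec <- results$index$spec
    wt(data.frame(parameter = c(paste0("b_", spec$traits), "accuracy_r",
                                paste0("weight_", names(spec$weights))),
                  value = fmt(c(results$index$b, as.numeric(results$index$accuracy),
                                unname(spec$weights)), 4)),
       "index_summary.tsv")
  }
  if (!is.null(results$edit)) {
    wt(results$edit$removed_animals, "removed_animals.tsv")
  }
  paths
}
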