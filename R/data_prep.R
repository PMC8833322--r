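# Data editing (birth-weight discard rule, one-sided IQR outlier rule),
# descriptive statistics and least-squares means with Tukey-Kramer groupings.

#' Read / write phenotype files
#'
#' Delimited text (comma or tab autodetected), one row per animal, first
#' column `animal`, remaining columns trait values with missing values empty.
#' Trait columns keep their field codes verbatim (e.g. `240EP`), so access
#' them with `[[`.
#'
#' @param path file path.
#' @return data.frame with `animal` (character) and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"animal" %in% names(df)) stop("phenotype file lacks an 'animal' column: ", path)
  df$animal <- as.character(df$animal)
  for (nm in setdiff(names(df), "animal")) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' @rdname read_phenotypes
#' @param pheno phenotype data.frame.
#' @param sep field separator for writing (default tab).
#' @export
write_phenotypes <- function(pheno, path, sep = "\t") {
  utils::write.table(pheno, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Discard chicks below the birth-weight threshold
#'
#' Removes whole animals whose birth weight is strictly below `threshold`
#' grams (default 26 g; a record of exactly 26 g is retained). This mirrors
#' the hatchery editing step in which under-weight chicks are discarded from
#' the data set entirely, as opposed to per-trait outlier masking.
#'
#' @param pheno phenotype data.frame with a `BW0` column.
#' @param threshold grams; strict lower cut-off (default 26).
#' @return list with `data` (kept rows) and `removed` (character vector of
#'   removed animal ids). `kept + removed` partition the input.
#' @export
filter_birth_weight <- function(pheno, threshold = 26) {
  if (!"BW0" %in% names(pheno)) stop("phenotype table lacks a BW0 column")
  drop <- !is.na(pheno$BW0) & pheno$BW0 < threshold
  list(data = pheno[!drop, , drop = FALSE], removed = pheno$animal[drop])
}

#' One-sided lower IQR outlier rule
#'
#' Keep-mask for a numeric vector under the editing rule "more than 1.5 times
#' the interquartile range below the first quartile": a value is dropped iff
#' `v < Q1 - k * IQR`. The rule is lower-side only; extreme high values are
#' always retained. Missing values pass through (`TRUE`). Quartiles use linear
#' interpolation of order statistics (`stats::quantile` type 7) by default.
#'
#' @param x numeric vector (at least 4 non-missing values).
#' @param k fence multiplier (default 1.5).
#' @param qtype quantile definition passed to [stats::quantile()] (default 7).
#' @return logical keep-mask, same length as `x`.
#' @export
iqr_keep_mask <- function(x, k = 1.5, qtype = 7) {
  if (all(is.na(x))) stop("all values missing")
  if (sum(!is.na(x)) < 4L) stop("need at least 4 non-missing values for the IQR rule")
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = qtype)
  fence <- q[1L] - k * (q[2L] - q[1L])
  is.na(x) | x >= fence
}

#' Apply the full phenotype editing procedure
#'
#' Two-stage editing, mirroring the distinction between discarded chicks and
#' per-trait outliers: (1) animals with `BW0` strictly below `bw_threshold`
#' (or flagged by the lower-IQR rule on `BW0`) are removed entirely;
#' (2) for every other trait, values failing the lower-IQR rule are set to
#' missing for that trait only. Both filters are idempotent. The IQR rule is
#' applied within-trait globally by default; set `stratify_by` to a factor
#' column name (e.g. `"sex"`) to apply it within strata instead.
#'
#' @param pheno phenotype data.frame (first column `animal`).
#' @param traits trait columns to edit (default: all non-`animal` columns).
#' @param bw_threshold birth-weight discard threshold in grams (default 26);
#'   `NA` skips the birth-weight stage (e.g. when `BW0` is absent).
#' @param k,qtype IQR fence multiplier and quantile type, see [iqr_keep_mask()].
#' @param stratify_by optional column of `pheno` defining strata for the IQR
#'   rule (default `NULL` = global).
#' @return list: `data` (edited table), `removed_animals` (data.frame of id +
#'   reason), `n_masked` (named count of per-trait values set to missing).
#' @export
edit_phenotypes <- function(pheno, traits = setdiff(names(pheno), "animal"),
                            bw_threshold = 26, k = 1.5, qtype = 7,
                            stratify_by = NULL) {
  removed <- data.frame(animal = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (!is.na(bw_threshold) && "BW0" %in% names(pheno)) {
    fb <- filter_birth_weight(pheno, bw_threshold)
    if (length(fb$removed))
      removed <- rbind(removed, data.frame(animal = fb$removed,
                                           reason = "BW0 below threshold"))
    pheno <- fb$data
    keep <- strat_keep(pheno, "BW0", k, qtype, stratify_by)
    if (any(!keep))
      removed <- rbind(removed, data.frame(animal = pheno$animal[!keep],
                                           reason = "BW0 lower-IQR outlier"))
    pheno <- pheno[keep, , drop = FALSE]
  }
  n_masked <- integer(0)
  for (tr in setdiff(intersect(traits, names(pheno)), "BW0")) {
    if (sum(!is.na(pheno[[tr]])) < 4L) next
    keep <- strat_keep(pheno, tr, k, qtype, stratify_by)
    n_masked[tr] <- sum(!keep)
    pheno[[tr]][!keep] <- NA
  }
  list(data = pheno, removed_animals = removed, n_masked = n_masked)
}

strat_keep <- function(pheno, trait, k, qtype, stratify_by) {
  if (is.null(stratify_by)) return(iqr_keep_mask(pheno[[trait]], k, qtype))
  keep <- rep(TRUE, nrow(pheno))
  for (lev in unique(pheno[[stratify_by]])) {
    idx <- which(pheno[[stratify_by]] %in% lev)
    if (sum(!is.na(pheno[[trait]][idx])) >= 4L)
      keep[idx] <- iqr_keep_mask(pheno[[trait]][idx], k, qtype)
  }
  keep
}

#' Descriptive statistics per trait
#'
#' Number of non-missing records, mean, sample standard deviation (n-1
#' denominator), min, max and the coefficient of variation
#' `CV% = 100 * sd / mean`. Values are unrounded; presentation rounding (1
#' decimal) happens in [report_tables()].
#'
#' @param pheno phenotype data.frame.
#' @param traits trait columns to summarise (default: all non-`animal`).
#' @return data.frame, one row per trait: `trait, n_records, mean, sd, min,
#'   max, cv_percent` (`sd`/`cv` are `NA` for traits with < 2 records).
#' @export
descriptive_stats <- function(pheno, traits = setdiff(names(pheno), "animal")) {
  if (nrow(pheno) == 0L) stop("phenotype table is empty")
  rows <- lapply(traits, function(tr) {
    x <- pheno[[tr]]
    x <- x[!is.na(x)]
    n <- length(x)
    m <- if (n) mean(x) else NA_real_
    s <- if (n >= 2L) stats::sd(x) else NA_real_
    data.frame(trait = tr, n_records = n, mean = m, sd = s,
               min = if (n) min(x) else NA_real_,
               max = if (n) max(x) else NA_real_,
               cv_percent = if (!is.na(s) && !is.na(m) && m > 0) 100 * s / m else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Least-squares means with Tukey-Kramer letter groupings
#'
#' Fits, per trait, an additive fixed-effects linear model in the given
#' factors by least squares (unbalanced designs allowed) and reports
#' LS-means: model predictions averaged over the other factors' levels with
#' equal weights (via \pkg{emmeans}). All pairwise comparisons within each
#' factor use the Tukey-Kramer adjustment at level `alpha`; levels sharing a
#' letter are not significantly different. In a balanced design the LS-means
#' equal the raw group means.
#'
#' @param pheno data.frame holding the trait columns and factor columns.
#' @param traits character vector of trait column names.
#' @param factors character vector of factor column names (e.g.
#'   `c("sex", "generation", "hatch_set")`). Empty levels are dropped with a
#'   warning.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list (class `ls_means`), one element per trait, each a list of
#'   per-factor data.frames with columns `level, lsmean, se, letters`.
#' @export
ls_means <- function(pheno, traits, factors, alpha = 0.05) {
  stopifnot(length(factors) >= 1L)
  out <- list()
  for (tr in traits) {
    sub <- pheno[!is.na(pheno[[tr]]), c(tr, factors), drop = FALSE]
    names(sub)[1L] <- ".y"
    use <- character(0)
    level_map <- list()
    for (f in factors) {
      fac <- factor(sub[[f]])
      if (any(table(fac) == 0L)) {
        warning("dropping empty level(s) of ", f, " for trait ", tr)
        fac <- droplevels(fac)
      }
      # recode levels to syntactic labels so pairwise-contrast labels parse
      level_map[[f]] <- levels(fac)
      levels(fac) <- paste0("L", seq_along(levels(fac)))
      sub[[f]] <- fac
      if (nlevels(fac) >= 2L) use <- c(use, f)
    }
    if (!length(use)) next
    fit <- stats::lm(stats::as.formula(paste0(".y ~ ", paste(use, collapse = " + "))),
                     data = sub)
    res_f <- list()
    for (f in use) {
      em <- emmeans::emmeans(fit, stats::as.formula(paste0("~ ", f)))
      emdf <- as.data.frame(em)
      prs <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
      codes <- as.character(emdf[[1L]])
      pmat <- matrix(1, length(codes), length(codes), dimnames = list(codes, codes))
      for (r in seq_len(nrow(prs))) {
        ab <- strsplit(prs$contrast[r], " - ", fixed = TRUE)[[1L]]
        pmat[ab[1L], ab[2L]] <- pmat[ab[2L], ab[1L]] <- prs$p.value[r]
      }
      res_f[[f]] <- data.frame(level = level_map[[f]][match(codes, paste0("L", seq_along(level_map[[f]])))],
                               lsmean = emdf$emmean, se = emdf$SE,
                               letters = sig_letters(emdf$emmean, pmat, alpha),
                               stringsAsFactors = FALSE)
    }
    out[[tr]] <- res_f
  }
  structure(out, class = "ls_means")
}

# Compact letter display from a pairwise p-value matrix: order levels by
# descending mean, find maximal contiguous runs of mutually non-significant
# levels, drop runs contained in others, assign letters in order.
sig_letters <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  ord <- order(-means)
  ns <- pmat[ord, ord, drop = FALSE] > alpha
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(ns[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
  }
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) for (b in seq_along(runs)) {
    if (a != b && keep[a] && runs[[b]][1L] <= runs[[a]][1L] && runs[[a]][2L] <= runs[[b]][2L] &&
        !identical(runs[[a]], runs[[b]])) keep[a] <- FALSE
  }
  runs <- runs[keep]
  lab <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1L]:runs[[r]][2L]
    lab[idx] <- paste0(lab[idx], letters[r])
  }
  out <- character(k)
  out[ord] <- lab
  out
}
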