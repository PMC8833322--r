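# Truncation-selection theory (intensity, expected genetic progress), genetic
# trends from EBVs, and the Hazel economic selection index: coefficients
# b = P^-1 G v, index accuracy, per-animal index values and top-p selection.

#' Standardised selection intensity for truncation selection
#'
#' For a normally distributed criterion and selected proportion `p`, the mean
#' standardised superiority of the selected group is `i = phi(z_p) / p`,
#' where `z_p` is the truncation point leaving upper-tail mass `p`.
#'
#' @param p selected proportion(s), strictly between 0 and 1.
#' @return selection intensity (vectorised).
#' @examples
#' selection_intensity(0.5)   # 2 * dnorm(0) = 0.798
#' selection_intensity(0.2)   # about 1.40
#' @export
selection_intensity <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("selected proportion must lie strictly between 0 and 1")
  z <- stats::qnorm(1 - p)
  stats::dnorm(z) / p
}

#' Expected genetic progress per generation
#'
#' The breeder's-equation prediction `dG = sigma_A * h * i`: additive genetic
#' standard deviation times the accuracy of selection times the standardised
#' selection intensity, in trait units per generation.
#'
#' @param sigma_a additive genetic standard deviation (trait units), `>= 0`.
#' @param accuracy accuracy of selection `h` in `[0, 1]` (for selection on
#'   EBVs, the correlation between EBV and true breeding value).
#' @param intensity standardised selection intensity `i >= 0`, e.g. from
#'   [selection_intensity()].
#' @return expected genetic gain per generation (vectorised).
#' @export
delta_g <- function(sigma_a, accuracy, intensity) {
  if (any(sigma_a < 0)) stop("sigma_a must be non-negative")
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy must lie in [0, 1]")
  if (any(intensity < 0)) stop("intensity must be non-negative")
  sigma_a * accuracy * intensity
}

#' Genetic trend from estimated breeding values
#'
#' Per-generation mean EBV per trait, with the average progress summarised as
#' the least-squares slope of the generation means against the generation
#' index. Optional pairwise generation comparisons reuse the [ls_means()]
#' machinery applied to the EBVs.
#'
#' @param ebv animal-by-trait matrix of EBVs (rows named by animal).
#' @param generation generation label per animal (same order as `ebv` rows).
#' @param compare also run per-generation LS-means/Tukey comparisons of the
#'   EBVs (default `FALSE`).
#' @return object of class `genetic_trend`: `means` (generation x trait
#'   data.frame), `slope` (named per-trait least-squares slope per
#'   generation), `n` (animals per generation), optionally `comparisons`.
#' @export
genetic_trend <- function(ebv, generation, compare = FALSE) {
  ebv <- as.matrix(ebv)
  stopifnot(length(generation) == nrow(ebv))
  gens <- sort(unique(generation))
  if (length(gens) < 2L) stop("genetic trend undefined with a single generation")
  means <- do.call(rbind, lapply(gens, function(g)
    colMeans(ebv[generation == g, , drop = FALSE])))
  rownames(means) <- gens
  if (is.null(colnames(means))) colnames(means) <- paste0("trait", seq_len(ncol(means)))
  slope <- apply(means, 2L, function(m) unname(stats::coef(stats::lm(m ~ gens))[2L]))
  out <- list(means = data.frame(generation = gens, means, check.names = FALSE),
              slope = slope, n = as.integer(table(factor(generation, levels = gens))))
  if (compare) {
    df <- data.frame(generation = as.character(generation), ebv, check.names = FALSE)
    out$comparisons <- ls_means(df, colnames(ebv), "generation")
  }
  structure(out, class = "genetic_trend")
}

#' @export
print.genetic_trend <- function(x, ...) {
  cat("Genetic trend over", nrow(x$means), "generations\n")
  print(x$means, row.names = FALSE)
  cat("least-squares slope per generation:\n")
  print(round(x$slope, 4))
  invisible(x)
}

#' Specification of the economic selection index
#'
#' Relative economic weights for the four index traits in the fixed order
#' body weight, breast circumference, egg production, age at first egg. The
#' growth weights (body weight + breast circumference) must sum to 0.5 and
#' the egg weights (egg production + age at first egg) to 0.5; the age at
#' first egg enters the index with a negative sign (earlier maturity is
#' favoured). Defaults follow the weighting 0.25 / 0.25 / 0.30 / 0.20.
#'
#' @param weights positive numeric of length 4, named or in the order above.
#' @param bw_trait which body-weight trait's EBV enters the index (default
#'   `"BW6"`, the recommended selection age).
#' @param ep_trait which cumulative egg-production trait enters (default
#'   `"240EP"`).
#' @return object of class `selection_index_spec`.
#' @export
selection_index_spec <- function(weights = c(body_weight = 0.25,
                                             breast_circumference = 0.25,
                                             egg_production = 0.30,
                                             age_at_first_egg = 0.20),
                                 bw_trait = "BW6", ep_trait = "240EP") {
  stopifnot(length(weights) == 4L)
  if (any(weights <= 0)) stop("economic weights must be positive")
  if (abs(weights[1L] + weights[2L] - 0.5) > 1e-8 ||
      abs(weights[3L] + weights[4L] - 0.5) > 1e-8)
    stop("growth weights must sum to 0.5 and egg weights to 0.5")
  names(weights) <- c("body_weight", "breast_circumference",
                      "egg_production", "age_at_first_egg")
  structure(list(weights = weights, bw_trait = bw_trait, ep_trait = ep_trait,
                 traits = c(bw_trait, "BrC6", ep_trait, "AFE")),
            class = "selection_index_spec")
}

#' Selection-index coefficients b = P^-1 G v
#'
#' Solves `P b = G v` for the index coefficients, where `P` is the phenotypic
#' and `G` the genetic variance-covariance matrix of the index traits and `v`
#' the vector of relative economic weights.
#'
#' @param P,G phenotypic and genetic covariance matrices (same dimension).
#' @param v economic weights.
#' @return coefficient vector `b`.
#' @export
index_coefficients <- function(P, G, v) {
  P <- as.matrix(P); G <- as.matrix(G)
  stopifnot(all(dim(P) == dim(G)), length(v) == nrow(P))
  if (rcond_safe(P) < 1e-12) stop("phenotypic covariance matrix is singular")
  drop(solve(P, G %*% v))
}

rcond_safe <- function(M) tryCatch(rcond(M), error = function(e) 0)

#' Accuracy of the selection index
#'
#' Correlation between the index `I = b'x` (with `b = P^-1 G v`) and the
#' aggregate genotype `H = v'g`:
#' `r = sqrt(v' G P^-1 G v / v' G v) = sqrt(b' G v / v' G v)`.
#' The unrooted ratio `b' G b / v' G v` is exposed as attribute
#' `"literal_ratio"` as a secondary diagnostic (for `b = P^-1 G v` it equals
#' `r^2` only when scales align; the rooted correlation is the primary
#' definition).
#'
#' @param P,G phenotypic and genetic covariance matrices (positive definite).
#' @param v economic weights (`v' G v` must be positive).
#' @return scalar accuracy in `[0, 1]` with attribute `literal_ratio`.
#' @export
index_accuracy <- function(P, G, v) {
  P <- as.matrix(P); G <- as.matrix(G)
  b <- index_coefficients(P, G, v)
  vGv <- drop(t(v) %*% G %*% v)
  if (vGv <= 0) stop("v' G v must be positive")
  r2 <- drop(t(b) %*% G %*% v) / vGv
  r <- sqrt(min(max(r2, 0), 1))
  attr(r, "literal_ratio") <- drop(t(b) %*% G %*% b) / vGv
  r
}

#' Economic selection index from estimated breeding values
#'
#' `I = v1 EBV_BW + v2 EBV_BrC6 + v3 EBV_EP - v4 EBV_AFE`, with the weights
#' and trait choices from a [selection_index_spec()]. Animals missing any of
#' the four EBVs are excluded with a warning.
#'
#' @param ebv matrix or data.frame of EBVs whose columns include the four
#'   index traits (rows named/keyed by animal).
#' @param spec a [selection_index_spec()].
#' @return named numeric vector of index values.
#' @export
ebv_index <- function(ebv, spec = selection_index_spec()) {
  ebv <- as.matrix(ebv)
  miss <- setdiff(spec$traits, colnames(ebv))
  if (length(miss)) stop("EBV matrix lacks index trait(s): ", paste(miss, collapse = ", "))
  M <- ebv[, spec$traits, drop = FALSE]
  ok <- stats::complete.cases(M)
  if (any(!ok)) warning(sum(!ok), " animal(s) excluded from the index: missing EBVs")
  M <- M[ok, , drop = FALSE]
  w <- spec$weights
  I <- w[1L] * M[, 1L] + w[2L] * M[, 2L] + w[3L] * M[, 3L] - w[4L] * M[, 4L]
  stats::setNames(as.numeric(I), rownames(M))
}

#' Truncation selection of the top fraction
#'
#' Selects the top `ceiling(p * n)` animals by descending index value, within
#' each sex when `sex` is supplied (the closed-nucleus replacement scheme
#' selects cocks and hens separately). Ties at the cut-off are broken by
#' animal id, so the selected set is deterministic across runs.
#'
#' @param index named numeric vector of index values.
#' @param p selected proportion in `(0, 1]` (default 0.2).
#' @param sex optional vector of sex codes aligned with `index` for within-sex
#'   selection.
#' @return character vector of selected animal ids.
#' @export
truncate_top <- function(index, p = 0.2, sex = NULL) {
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (is.null(names(index))) stop("index values must be named by animal id")
  pick <- function(v) {
    k <- ceiling(p * length(v))
    names(v)[order(-v, names(v))][seq_len(k)]
  }
  if (is.null(sex)) return(pick(index))
  unlist(lapply(split(index, sex), pick), use.names = FALSE)
}
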