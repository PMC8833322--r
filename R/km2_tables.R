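# Published genetic parameters of the Kaimook e-san2 (KM2) synthetic chicken
# nucleus: per-trait variance components, heritabilities, and the genetic /
# phenotypic correlation matrices. These published estimates drive the
# simulator defaults and the analytic identity checks.

km2_trait_names <- c("BW0", "BW4", "BW6", "BW8", "BW10", "BrC6",
                     "AFE", "240EP", "270EP", "300EP", "365EP")

#' KM2 published parameter tables
#'
#' `km2_variance_components`: per-trait additive (`va`), residual (`ve`) and
#' total (`vt`) variances with heritability (`h2`) and its standard error, as
#' printed. Note the printed `va` for 270EP (2.50) is inconsistent with its
#' own row (`vt - ve = 222.50`, and `h2 * vt ≈ 222.7`); the printed value is
#' kept here verbatim, while [km2_sim_truth()] substitutes the internally
#' consistent `vt - ve`.
#'
#' `km2_descriptives`: per-trait record counts, means and dispersion of the
#' recorded population (used for simulator means/effect scales).
#'
#' @format data.frames keyed by `trait`.
#' @name km2_tables
NULL

#' @rdname km2_tables
#' @export
km2_variance_components <- data.frame(
  trait = km2_trait_names,
  va = c(8.77, 1412, 5782, 11485, 12602, 1.10, 86.50, 138.10, 2.50, 303.40, 489.20),
  ve = c(4.89, 2835, 7687, 21059, 32364, 2.77, 234.80, 185.40, 330.20, 448.20, 660.40),
  vt = c(13.66, 4247, 13469, 32544, 44966, 3.87, 321.30, 323.50, 552.70, 751.60, 1149.60),
  h2 = c(0.642, 0.332, 0.429, 0.353, 0.280, 0.284, 0.269, 0.427, 0.403, 0.404, 0.426),
  h2_se = c(0.10, 0.05, 0.04, 0.04, 0.02, 0.03, 0.03, 0.03, 0.02, 0.02, 0.02),
  stringsAsFactors = FALSE
)

#' @rdname km2_tables
#' @export
km2_descriptives <- data.frame(
  trait = km2_trait_names,
  n_records = c(2713, 2713, 2713, 2713, 2713, 2713, 2713, 2710, 2710, 2708, 2700),
  mean = c(37.9, 395.4, 812.3, 1228.8, 1642.4, 27.6, 168.0, 43.0, 55.0, 65.0, 84.0),
  sd = c(4.2, 104.7, 138.7, 220.2, 261.4, 2.3, 21.0, 19.4, 24.2, 28.1, 28.0),
  min = c(26.0, 150.0, 457.0, 700.0, 900.0, 20.3, 120.0, 12.0, 15.0, 23.0, 44.0),
  max = c(50.0, 650.0, 1400.0, 1895.0, 2450.0, 36.0, 199.0, 96.0, 123.0, 146.0, 151.0),
  cv_percent = c(11.1, 26.5, 17.1, 17.9, 15.9, 8.3, 12.5, 45.1, 44.0, 43.2, 33.3),
  stringsAsFactors = FALSE
)

km2_upper <- function(vals) {
  m <- diag(1, 11)
  dimnames(m) <- list(km2_trait_names, km2_trait_names)
  m[upper.tri(m)] <- unlist(vals)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Upper triangle filled column-wise (i.e. pairs in the order
# (1,2),(1,3),(2,3),(1,4),(2,4),(3,4),...) -- build row-wise lists instead
km2_corr_matrix <- function(rows) {
  m <- diag(1, 11)
  dimnames(m) <- list(km2_trait_names, km2_trait_names)
  for (i in seq_along(rows)) {
    vals <- rows[[i]]
    js <- (i + 1L):11L
    m[i, js] <- vals
    m[js, i] <- vals
  }
  m
}

#' @rdname km2_tables
#' @export
km2_genetic_correlations <- km2_corr_matrix(list(
  c(0.22, 0.15, 0.10, 0.08, 0.12, -0.03, -0.15, -0.03, -0.28, -0.29),  # BW0
  c(0.61, 0.51, 0.40, 0.30, -0.10, -0.24, -0.32, -0.43, -0.48),        # BW4
  c(0.91, 0.79, 0.80, -0.18, 0.08, -0.46, -0.49, -0.40),               # BW6
  c(0.86, 0.84, -0.20, 0.14, -0.40, -0.44, -0.32),                     # BW8
  c(0.93, -0.25, 0.15, -0.38, -0.42, -0.35),                           # BW10
  c(-0.27, 0.08, -0.32, -0.35, -0.30),                                 # BrC6
  c(-0.14, -0.29, -0.21, -0.16),                                       # AFE
  c(0.34, 0.22, 0.04),                                                 # 240EP
  c(0.60, 0.40),                                                       # 270EP
  c(0.86)                                                              # 300EP
))

#' @rdname km2_tables
#' @export
km2_phenotypic_correlations <- km2_corr_matrix(list(
  c(0.16, 0.14, 0.10, 0.06, 0.12, 0.01, -0.08, -0.11, -0.20, -0.24),   # BW0
  c(0.58, 0.48, 0.36, 0.24, -0.08, -0.14, -0.25, -0.40, -0.42),        # BW4
  c(0.85, 0.72, 0.72, -0.16, -0.01, -0.40, -0.42, -0.38),              # BW6
  c(0.82, 0.80, -0.21, 0.10, -0.38, -0.40, -0.28),                     # BW8
  c(0.90, -0.22, 0.12, -0.36, -0.40, -0.32),                           # BW10
  c(-0.24, 0.07, -0.33, -0.28, -0.26),                                 # BrC6
  c(-0.14, -0.23, -0.18, -0.12),                                      # AFE
  c(0.33, 0.19, 0.09),                                                 # 240EP
  c(0.54, 0.38),                                                       # 270EP
  c(0.85)                                                              # 300EP
))

#' Internally consistent simulation truth from the KM2 tables
#'
#' Returns per-trait additive and residual variances to be used as simulation
#' truth: the printed values, except that the 270EP additive variance (printed
#' 2.50, inconsistent with its own total and heritability) is replaced by
#' `vt - ve = 222.50`.
#'
#' @return data.frame `trait, va, ve` in the standard trait order.
#' @export
km2_sim_truth <- function() {
  vc <- km2_variance_components
  fix <- vc$trait == "270EP"
  vc$va[fix] <- vc$vt[fix] - vc$ve[fix]
  vc[, c("trait", "va", "ve")]
}
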