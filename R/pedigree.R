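# Pedigree ingestion, validation and relationship algebra: the numerator
# relationship matrix A, inbreeding coefficients, and the sparse A-inverse
# assembled by Henderson's rules with inbreeding.

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0" | toupper(x) == "NA" | toupper(x) == "UNKNOWN"] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "1", "sire", "cock")] <- "M"
  out[x %in% c("f", "female", "2", "dam", "hen")] <- "F"
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) stop("unrecognised sex code(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Assemble, validate and topologically sort a pedigree
#'
#' Takes raw animal/sire/dam records (plus optional sex, generation and hatch
#' set) and returns a `pedigree` object in topological order, i.e. every parent
#' precedes all of its offspring. Unknown parents (coded `NA`, `""` or `"0"`)
#' are treated as unique unrelated founders; no genetic groups are fitted.
#' Parents that are referenced but have no record of their own are added as
#' founder records (with their sex inferred from the role they appear in).
#'
#' Hard failures (errors, not warnings): duplicate animal ids, an animal that
#' is its own ancestor (a parentage cycle; the error names one animal on the
#' cycle), an animal recorded as both a sire and a dam, and a known sire whose
#' record says female (or dam recorded as male).
#'
#' @param data data.frame with columns `animal`, `sire`, `dam` and optionally
#'   `sex` (`"M"`/`"F"`, `"male"`/`"female"` or 1/2), `generation`
#'   (non-negative integer) and `hatch_set`.
#' @param add_founders add records for referenced-but-missing parents
#'   (default `TRUE`); if `FALSE` such references are an error.
#' @return An object of class `pedigree`: a topologically sorted data.frame of
#'   records together with integer parent indices (0 = unknown) used by the
#'   matrix routines. Internal matrix indexing of animals is the row order of
#'   this object.
#' @seealso [relationship_matrix()], [inbreeding()], [a_inverse()]
#' @export
pedigree <- function(data, add_founders = TRUE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("pedigree data is empty")
  need <- setdiff(c("animal", "sire", "dam"), names(data))
  if (length(need)) stop("pedigree data lacks column(s): ", paste(need, collapse = ", "))

  id   <- as.character(data$animal)
  if (anyNA(id) || any(!nzchar(id))) stop("animal ids must be non-missing")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate animal_id: ", dup[1L])
  sire <- normalize_parent(data$sire)
  dam  <- normalize_parent(data$dam)
  sex  <- if (!is.null(data$sex)) normalize_sex(data$sex) else rep(NA_character_, length(id))
  generation <- if (!is.null(data$generation)) suppressWarnings(as.integer(data$generation)) else rep(NA_integer_, length(id))
  hatch_set  <- if (!is.null(data$hatch_set)) as.character(data$hatch_set) else rep(NA_character_, length(id))

  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id))
    stop("animal recorded as its own parent: ",
         id[which((!is.na(sire) & sire == id) | (!is.na(dam) & dam == id))[1L]])

  missing_par <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(missing_par)) {
    if (!add_founders)
      stop("parent id(s) without a record: ", paste(utils::head(missing_par, 5L), collapse = ", "))
    par_sex <- ifelse(missing_par %in% sire, "M", "F")
    id   <- c(missing_par, id)
    sire <- c(rep(NA_character_, length(missing_par)), sire)
    dam  <- c(rep(NA_character_, length(missing_par)), dam)
    sex  <- c(par_sex, sex)
    generation <- c(rep(NA_integer_, length(missing_par)), generation)
    hatch_set  <- c(rep(NA_character_, length(missing_par)), hatch_set)
    message(length(missing_par), " referenced parent(s) added as founder records")
  }

  both <- intersect(sire[!is.na(sire)], dam[!is.na(dam)])
  if (length(both)) stop("animal recorded as both sire and dam: ", both[1L])

  # sex consistency: a known sire must be male, a known dam female
  sire_rows <- match(unique(sire[!is.na(sire)]), id)
  dam_rows  <- match(unique(dam[!is.na(dam)]), id)
  if (any(sex[sire_rows] == "F", na.rm = TRUE))
    stop("sire recorded as female: ", id[sire_rows][which(sex[sire_rows] == "F")[1L]])
  if (any(sex[dam_rows] == "M", na.rm = TRUE))
    stop("dam recorded as male: ", id[dam_rows][which(sex[dam_rows] == "M")[1L]])
  sex[sire_rows][is.na(sex[sire_rows])] <- "M"
  sex[dam_rows][is.na(sex[dam_rows])] <- "F"

  # Kahn topological sort, stable in input order among ready animals
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    j <- ready[1L]
    ready <- ready[-1L]
    order_out <- c(order_out, j)
    for (k in kids[[j]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order_out) < n) {
    on_cycle <- setdiff(seq_len(n), order_out)
    stop("parentage cycle detected involving animal: ", id[on_cycle[1L]])
  }

  id <- id[order_out]; sire <- sire[order_out]; dam <- dam[order_out]
  sex <- sex[order_out]; generation <- generation[order_out]
  hatch_set <- hatch_set[order_out]
  sire_idx <- match(sire, id); sire_idx[is.na(sire_idx)] <- 0L
  dam_idx  <- match(dam, id);  dam_idx[is.na(dam_idx)] <- 0L

  # fill missing generations by pedigree depth (founders = 0)
  if (anyNA(generation)) {
    depth <- integer(n)
    for (i in seq_len(n)) {
      ps <- sire_idx[i]; pd <- dam_idx[i]
      depth[i] <- max(if (ps) depth[ps] + 1L else 0L, if (pd) depth[pd] + 1L else 0L)
    }
    generation[is.na(generation)] <- depth[is.na(generation)]
  }

  df <- data.frame(animal = id, sire = sire, dam = dam, sex = sex,
                   generation = generation, hatch_set = hatch_set,
                   stringsAsFactors = FALSE)
  structure(list(data = df, sire = sire_idx, dam = dam_idx), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(x$sire == 0L & x$dam == 0L)
  cat("Pedigree with", nrow(x$data), "animals (", nf, "founders ),",
      length(unique(x$data$generation)), "generation level(s)\n")
  print(utils::head(x$data), ...)
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) x$data

#' @rdname pedigree
#' @param ped a `pedigree` object.
#' @export
n_animals <- function(ped) nrow(ped$data)

#' @rdname pedigree
#' @export
animal_ids <- function(ped) ped$data$animal

#' Numerator relationship matrix by the tabular method
#'
#' Computes the dense additive (numerator) relationship matrix A recursively:
#' `a_ij = 0.5 (a_{i,sire(j)} + a_{i,dam(j)})` for `i` earlier than `j`, and
#' `a_jj = 1 + 0.5 a_{sire(j),dam(j)}`; an unknown parent contributes 0.
#' Dense and O(n^2) in memory: intended for desk-scale pedigrees and as the
#' test oracle for [a_inverse()]. Production paths use the sparse inverse
#' directly and never invert A.
#'
#' @param ped a [pedigree()] object.
#' @return symmetric matrix with dimnames = animal ids; `diag(A) = 1 + F`.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- n_animals(ped)
  if (n > 6000L)
    stop("relationship_matrix() is dense; pedigree too large (", n,
         " animals). Use a_inverse() / inbreeding() instead.")
  s <- ped$sire; d <- ped$dam
  A <- matrix(0, n, n, dimnames = list(animal_ids(ped), animal_ids(ped)))
  for (j in seq_len(n)) {
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s[j]) A[i, s[j]] else 0
      ad_ <- if (d[j]) A[i, d[j]] else 0
      aij <- 0.5 * (as_ + ad_)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[j, j] <- 1 + if (s[j] && d[j]) 0.5 * A[s[j], d[j]] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients `F_i = 0.5 a_{sire(i),dam(i)}`, computed
#' by the Meuwissen & Luo (1992) algorithm (compiled); founders and animals
#' with an unknown parent have F = 0.
#'
#' @param ped a [pedigree()] object.
#' @return named numeric vector of F in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  F <- ml_inbreeding(ped$sire, ped$dam)
  names(F) <- animal_ids(ped)
  F
}

# Mendelian sampling variances (as proportion of the additive variance):
# 1 with no known parent, 0.75 - 0.25 F_p with one, 0.5 - 0.25 (F_s + F_d)
# with both. Also the diagonal D of A = T D T', so log|A| = sum(log(d)).
mendelian_variances <- function(ped, F = inbreeding(ped)) {
  n <- length(F)
  fs <- rep(-1, n); fd <- rep(-1, n)   # -1 encodes an unknown parent
  hs <- ped$sire > 0L; hd <- ped$dam > 0L
  fs[hs] <- F[ped$sire[hs]]
  fd[hd] <- F[ped$dam[hd]]
  unname(0.5 - 0.25 * (fs + fd))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from pedigree structure by Henderson's rules,
#' accounting for inbreeding: each animal contributes `alpha = 1/d_i` (the
#' reciprocal of its Mendelian-sampling variance, which uses the parents'
#' inbreeding coefficients) to the usual animal/parent positions. Never forms
#' or inverts the dense A.
#'
#' @param ped a [pedigree()] object.
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`) with attributes
#'   `logdet_A` (log-determinant of A, needed by the REML likelihood) and
#'   `F` (the inbreeding coefficients).
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- n_animals(ped)
  F <- inbreeding(ped)
  d <- mendelian_variances(ped, F)
  if (any(d <= 0)) stop("inconsistent pedigree: non-positive Mendelian sampling variance")
  alpha <- 1 / d
  s <- ped$sire; dm <- ped$dam
  i <- seq_len(n)

  ii <- c(i); jj <- c(i); xx <- c(alpha)
  hs <- s > 0L
  hd <- dm > 0L
  ii <- c(ii, i[hs], s[hs], s[hs]);        jj <- c(jj, s[hs], i[hs], s[hs])
  xx <- c(xx, -alpha[hs] / 2, -alpha[hs] / 2, alpha[hs] / 4)
  ii <- c(ii, i[hd], dm[hd], dm[hd]);      jj <- c(jj, dm[hd], i[hd], dm[hd])
  xx <- c(xx, -alpha[hd] / 2, -alpha[hd] / 2, alpha[hd] / 4)
  hb <- hs & hd
  ii <- c(ii, s[hb], dm[hb]);              jj <- c(jj, dm[hb], s[hb])
  xx <- c(xx, alpha[hb] / 4, alpha[hb] / 4)

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(animal_ids(ped), animal_ids(ped)))
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "logdet_A") <- sum(log(d))
  attr(Ainv, "F") <- F
  Ainv
}

#' Read / write pedigree files
#'
#' Delimited text (comma or tab, autodetected on read) with columns
#' `animal,sire,dam,sex,generation,hatch_set`; `"0"` or an empty string marks
#' an unknown parent.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  pedigree(df)
}

#' @rdname read_pedigree
#' @param ped a `pedigree` object.
#' @param sep field separator for writing (default tab).
#' @export
write_pedigree <- function(ped, path, sep = "\t") {
  stopifnot(inherits(ped, "pedigree"))
  df <- ped$data
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (grepl("\t", line1)) "\t" else ","
}
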