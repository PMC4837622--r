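#' Build a pedigree object
#'
#' Constructs a validated, topologically sorted pedigree from vectors of
#' identifiers. Unknown parents are encoded as `NA`, `0` or `""`. After
#' construction every parent precedes its offspring, the pedigree is checked
#' for cycles, missing parents, duplicated identifiers and sex-inconsistent
#' parent usage (a known sire must be male, a known dam female, when sex is
#' recorded).
#'
#' @param id character or integer vector of unique individual identifiers.
#' @param sire,dam parent identifiers (same length as `id`); `NA`, `0` or
#'   empty strings mark unknown parents.
#' @param line,sex,hatch,generation optional per-individual metadata columns
#'   carried along (line label, sex `"male"`/`"female"`, hatch label,
#'   generation number).
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `id`, `sire`, `dam` (character, `NA` = unknown) plus any metadata,
#'   sorted so parents precede offspring, with attributes `n_sires` and
#'   `n_dams` (numbers of distinct individuals used as sire resp. dam).
#' @examples
#' ped <- pedigree(id = c("s1", "d1", "o1"), sire = c(NA, NA, "s1"),
#'                 dam = c(NA, NA, "d1"))
#' attr(ped, "n_sires")
#' @export
pedigree <- function(id, sire, dam, line = NULL, sex = NULL, hatch = NULL,
                     generation = NULL) {
  id   <- as.character(id)
  sire <- .norm_parent(sire)
  dam  <- .norm_parent(dam)
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  missing_par <- setdiff(c(sire, dam), c(id, NA))
  if (length(missing_par))
    stop("parent id(s) absent from pedigree: ",
         paste(missing_par, collapse = ", "))

  df <- data.frame(id = id, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  if (!is.null(line)) df$line <- as.character(line)
  if (!is.null(sex)) df$sex <- as.character(sex)
  if (!is.null(hatch)) df$hatch <- hatch
  if (!is.null(generation)) df$generation <- as.integer(generation)

  ord <- .ped_toposort(df$id, df$sire, df$dam)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  if (!is.null(df$sex)) {
    sx <- df$sex[match(df$sire, df$id)]
    bad <- df$sire[!is.na(sx) & sx != "male"]
    if (length(bad))
      stop("individual(s) used as sire but not male: ",
           paste(unique(bad), collapse = ", "))
    dx <- df$sex[match(df$dam, df$id)]
    bad <- df$dam[!is.na(dx) & dx != "female"]
    if (length(bad))
      stop("individual(s) used as dam but not female: ",
           paste(unique(bad), collapse = ", "))
  }

  attr(df, "n_sires") <- length(unique(stats::na.omit(df$sire)))
  attr(df, "n_dams") <- length(unique(stats::na.omit(df$dam)))
  class(df) <- c("pedigree", "data.frame")
  df
}

.norm_parent <- function(p) {
  p <- as.character(p)
  p[is.na(p) | p == "0" | p == "" | p == "NA"] <- NA_character_
  p
}

## Kahn-style topological sort; reports one individual on a cycle on failure.
.ped_toposort <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    on_cycle <- id[setdiff(seq_len(n), out)][1L]
    stop("pedigree contains a cycle involving individual ", on_cycle)
  }
  out
}

#' Read a pedigree from a delimited text file
#'
#' Expects a header naming at least `id`, `sire` and `dam`; `line`, `sex`,
#' `hatch` and `generation` columns are carried along when present. Unknown
#' parents are encoded as `0` or empty fields. Comma and tab delimiters are
#' both accepted.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [pedigree] object (topologically sorted).
#' @export
load_pedigree <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(raw)))
    stop("pedigree file must have columns id, sire, dam; found: ",
         paste(names(raw), collapse = ", "))
  pedigree(id = raw$id, sire = raw$sire, dam = raw$dam,
           line = raw$line, sex = raw$sex,
           hatch = if (!is.null(raw$hatch))
             utils::type.convert(raw$hatch, as.is = TRUE),
           generation = if (!is.null(raw$generation))
             as.integer(raw$generation))
}

#' Write a pedigree to a delimited text file
#'
#' Emits the same dialect [load_pedigree] reads: header row, unknown parents
#' written as `0`.
#'
#' @param ped a [pedigree].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, sep = ",") {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      attr(x, "n_sires"), "sires,", attr(x, "n_dams"), "dams\n")
  invisible(x)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-individual inbreeding coefficients F from a sorted pedigree.
#' Unknown parents are treated as unrelated, non-inbred founders.
#'
#' @param ped a [pedigree].
#' @return numeric vector of F, in pedigree order, named by id.
#' @export
inbreeding <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  f <- .ml_inbreeding(si, di)
  names(f) <- ped$id
  f
}

## Meuwissen & Luo (1992): trace ancestors of each animal, accumulating
## within-animal L^2 d contributions. si/di are row indices (NA = unknown),
## parents precede offspring.
.ml_inbreeding <- function(si, di) {
  n <- length(si)
  f <- numeric(n)
  d <- numeric(n) # Mendelian sampling variance of each animal, filled lazily
  for (i in seq_len(n)) {
    s <- si[i]; dd <- di[i]
    d[i] <- 0.5 - 0.25 * ((if (is.na(s)) -1 else f[s]) +
                          (if (is.na(dd)) -1 else f[dd]))
    if (is.na(s) || is.na(dd)) {
      f[i] <- 0
      next
    }
    # a_ii = sum_j L_j^2 d_j over i and its ancestors (L_i = 1, halving
    # down the pedigree); F_i = a_ii - 1
    L <- numeric(i)
    L[i] <- 1
    acc <- 0
    for (j in rev(seq_len(i))) {
      if (L[j] == 0) next
      js <- si[j]; jd <- di[j]
      if (!is.na(js)) L[js] <- L[js] + 0.5 * L[j]
      if (!is.na(jd)) L[jd] <- L[jd] + 0.5 * L[j]
      acc <- acc + L[j]^2 * d[j]
    }
    f[i] <- acc - 1
  }
  f
}

#' Additive (numerator) relationship matrix
#'
#' Dense A by the tabular (recursive) method: for individual i with parents
#' s, d (earlier in the order), `a_ii = 1 + 0.5 a_sd` and
#' `a_ij = 0.5 (a_js + a_jd)` for j before i, with unknown parents
#' contributing zero.
#'
#' @param ped a [pedigree].
#' @return symmetric matrix with dimnames = ids; attribute `"F"` holds the
#'   inbreeding coefficients (`diag(A) - 1`).
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' additive_relationship(ped)["s", "o"] # 0.5
#' @export
additive_relationship <- function(ped) {
  .check_sorted(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(s)) 0 else A[s, j]) +
                    (if (is.na(d)) 0 else A[d, j]))
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + (if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d])
  }
  attr(A, "F") <- stats::setNames(diag(A) - 1, ped$id)
  A
}

.check_sorted <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  i <- seq_len(nrow(ped))
  if (any(si >= i, na.rm = TRUE) || any(di >= i, na.rm = TRUE))
    stop("pedigree is not sorted parents-first; rebuild with pedigree()")
  invisible(TRUE)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding-corrected Mendelian-sampling variances
#' (Meuwissen-Luo): for individual i,
#' `d_i = 0.5 - 0.25 (F_s + F_d)` when both parents are known, with an
#' unknown parent contributing F = -1. Never forms dense A.
#'
#' @param ped a [pedigree].
#' @return a symmetric sparse `Matrix::dsCMatrix` with dimnames = ids and
#'   attribute `"F"` (inbreeding coefficients).
#' @export
a_inverse <- function(ped) {
  .check_sorted(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  f <- .ml_inbreeding(si, di)
  fs <- rep(-1, n); fs[!is.na(si)] <- f[si[!is.na(si)]]
  fd <- rep(-1, n); fd[!is.na(di)] <- f[di[!is.na(di)]]
  dms <- 0.5 - 0.25 * (fs + fd)
  if (any(dms <= 0))
    stop("non-positive Mendelian sampling variance; invalid pedigree")
  al <- 1 / dms

  # vectorized triplets (duplicates are summed by sparseMatrix):
  # (i,i) += a; (i,p) and (p,i) -= a/2; (p,p) += a/4; (s,d) and (d,s) += a/4
  ks <- which(!is.na(si)); kd <- which(!is.na(di))
  kb <- which(!is.na(si) & !is.na(di))
  ii <- c(seq_len(n), ks, si[ks], si[ks], kd, di[kd], di[kd],
          si[kb], di[kb])
  jj <- c(seq_len(n), si[ks], ks, si[ks], di[kd], kd, di[kd],
          di[kb], si[kb])
  xx <- c(al, -al[ks] / 2, -al[ks] / 2, al[ks] / 4,
          -al[kd] / 2, -al[kd] / 2, al[kd] / 4, al[kb] / 4, al[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "F") <- stats::setNames(f, ped$id)
  Ainv
}
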