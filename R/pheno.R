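#' Read a phenotype table from a delimited text file
#'
#' One record per bird, keyed by `id`. The ordinal white-striping column
#' `WS` may be coded `NORM`/`MOD`/`SEV` or `1`/`2`/`3`; it is stored as an
#' ordered factor `NORM < MOD < SEV`. All other non-key columns are kept;
#' those that parse as numbers become numeric trait columns. Drip loss is
#' stored raw; any log transform is applied at model-fitting time.
#'
#' @param path file path (comma or tab delimited, header required).
#' @param sep field separator; `NULL` auto-detects.
#' @return a data.frame with `id` character, `WS` ordered factor (when
#'   present), and trait columns.
#' @export
load_phenotypes <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"id" %in% names(tab)) stop("phenotype file must have an id column")
  tab$id <- as.character(tab$id)
  if ("WS" %in% names(tab)) tab$WS <- ws_factor(tab$WS)
  tab
}

#' Coerce white-striping codes to the ordered NORM < MOD < SEV factor
#'
#' @param x vector coded `NORM`/`MOD`/`SEV` or `1`/`2`/`3`.
#' @return ordered factor.
#' @export
ws_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x) || all(x %in% c("1", "2", "3", NA)))
    x <- c("NORM", "MOD", "SEV")[as.integer(x)]
  bad <- setdiff(unique(x), c("NORM", "MOD", "SEV", NA))
  if (length(bad)) stop("unrecognized WS code(s): ",
                        paste(bad, collapse = ", "))
  factor(x, levels = c("NORM", "MOD", "SEV"), ordered = TRUE)
}

#' Incidence table of the ordinal trait
#'
#' Counts and percentages of each white-striping category per group and
#' overall. The denominator in each group is the number of birds with a
#' non-missing score; groups with no scored bird are reported with count 0
#' and `NA` percentages.
#'
#' @param tab phenotype data.frame with a `WS` column.
#' @param by character vector of grouping columns (e.g.
#'   `c("line", "sex")`), or `NULL` for the overall margin only.
#' @return object of class `incidence_table`: a data.frame with one row per
#'   group plus an `overall` row; columns `n_NORM`, `n_MOD`, `n_SEV`, `N`,
#'   `pct_NORM`, `pct_MOD`, `pct_SEV` and `pct_affected`
#'   (`MOD` + `SEV`).
#' @examples
#' tab <- data.frame(WS = c("NORM", "MOD", "SEV", "MOD"))
#' incidence_table(tab)
#' @export
incidence_table <- function(tab, by = NULL) {
  ws <- ws_factor(tab$WS)
  one <- function(w) {
    cnt <- table(w[!is.na(w)])
    N <- sum(cnt)
    pct <- if (N > 0) 100 * as.numeric(cnt) / N else rep(NA_real_, 3)
    data.frame(n_NORM = as.integer(cnt["NORM"]),
               n_MOD = as.integer(cnt["MOD"]),
               n_SEV = as.integer(cnt["SEV"]), N = N,
               pct_NORM = pct[1], pct_MOD = pct[2], pct_SEV = pct[3],
               pct_affected = pct[2] + pct[3])
  }
  out <- NULL
  if (!is.null(by)) {
    if (!all(by %in% names(tab)))
      stop("grouping column(s) not found: ",
           paste(setdiff(by, names(tab)), collapse = ", "))
    key <- interaction(tab[by], drop = FALSE, sep = ":")
    rows <- lapply(levels(key), function(lv) one(ws[key == lv]))
    out <- cbind(group = levels(key), do.call(rbind, rows))
  }
  out <- rbind(out, cbind(group = "overall", one(ws)))
  rownames(out) <- NULL
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Chi-squared comparison of group frequencies per ordinal category
#'
#' For each white-striping category separately, tabulates in-category vs
#' not-in-category against the grouping (Pearson chi-squared without
#' continuity correction, df = g - 1), plus all pairwise group comparisons
#' on the corresponding 2x2 subtables. Expected cell counts below 1 are
#' flagged in the result, not raised as errors.
#'
#' @param tab phenotype data.frame with `WS` and the grouping columns.
#' @param groups character vector of grouping columns (default
#'   `c("line", "sex")`).
#' @return list with elements `overall` (data.frame: category, statistic,
#'   df, p.value, low_expected flag) and `pairwise` (data.frame: category,
#'   group1, group2, statistic, df, p.value, low_expected).
#' @export
chi_square_by_category <- function(tab, groups = c("line", "sex")) {
  ws <- ws_factor(tab$WS)
  key <- droplevels(interaction(tab[groups], drop = TRUE, sep = ":"))
  keep <- !is.na(ws) & !is.na(key)
  ws <- ws[keep]; key <- droplevels(key[keep])
  g <- nlevels(key)
  if (g < 2) stop("need at least 2 groups")
  cats <- levels(ws)
  one_test <- function(inmask, grp) {
    tb <- table(grp, factor(inmask, levels = c(TRUE, FALSE)))
    ct <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
    data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
               p.value = ct$p.value, low_expected = any(ct$expected < 1))
  }
  overall <- do.call(rbind, lapply(cats, function(cc)
    cbind(category = cc, one_test(ws == cc, key))))
  prs <- utils::combn(levels(key), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(cats, function(cc) {
    do.call(rbind, lapply(prs, function(pr) {
      sel <- key %in% pr
      cbind(category = cc, group1 = pr[1], group2 = pr[2],
            one_test((ws == cc)[sel], droplevels(key[sel])))
    }))
  }))
  rownames(overall) <- rownames(pairwise) <- NULL
  list(overall = overall, pairwise = pairwise)
}

#' Optional robust outlier filter for a quantitative trait
#'
#' Off by default in every pipeline entry point. Flags records with
#' `|value - median| > k * MAD` and returns the table with those records
#' set to `NA`; removals are logged in the `"removed"` attribute.
#'
#' @param tab phenotype data.frame.
#' @param trait trait column name.
#' @param k multiplier of the MAD (default 5).
#' @return `tab` with outlying values of `trait` set `NA`; attribute
#'   `removed` is a data.frame of `id` and removed `value`.
#' @export
remove_outliers <- function(tab, trait, k = 5) {
  x <- tab[[trait]]
  med <- stats::median(x, na.rm = TRUE)
  mad_ <- stats::mad(x, na.rm = TRUE)
  bad <- !is.na(x) & abs(x - med) > k * mad_
  removed <- data.frame(id = tab$id[bad], value = x[bad])
  tab[[trait]][bad] <- NA
  attr(tab, "removed") <- removed
  tab
}

#' Fixed-effects model for a trait with white striping nested within line
#'
#' Least-squares fit of `trait ~ hatch + sex + line + line:WS`, the model
#' used for the phenotypic characterization stage: hatch and generation are
#' deliberately confounded (hatch labels differ across generations), and
#' the WS term is nested within line so intra-line category contrasts are
#' estimable. Factors with a single observed level are dropped from the
#' formula. Drip loss should be analysed on the log scale
#' (`log_transform = TRUE`).
#'
#' @param tab phenotype data.frame with `WS`, `hatch`, `sex`, `line` and the
#'   trait column.
#' @param trait trait column name.
#' @param log_transform fit `log(trait)` instead of `trait` (values must be
#'   positive); default `TRUE` when `trait == "DL"`.
#' @return object of class `ws_fit`: list with the underlying `lm` fit, the
#'   trait name, the model frame factors and the formula used.
#' @export
fit_ws_fixed_model <- function(tab, trait,
                               log_transform = identical(trait, "DL")) {
  need <- c("WS", "hatch", "sex", "line", trait)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(y = as.numeric(tab[[trait]]),
                  WS = factor(ws_factor(tab$WS), ordered = FALSE),
                  hatch = factor(tab$hatch), sex = factor(tab$sex),
                  line = factor(tab$line))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (log_transform) {
    if (any(d$y <= 0)) stop("log transform requires positive values")
    d$y <- log(d$y)
  }
  d[] <- lapply(d, function(col) if (is.factor(col)) droplevels(col) else col)
  terms <- c("hatch", "sex", "line")[vapply(
    d[c("hatch", "sex", "line")], nlevels, 1L) > 1]
  ws_term <- if (nlevels(d$line) > 1) "line:WS" else "WS"
  rhs <- paste(c(terms, ws_term), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  fit <- stats::lm(form, data = d)
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  # with line:WS nesting and main line effects, no NA coefficients are
  # expected from treatment contrasts; any NA signals real confounding
  if (length(aliased))
    stop("rank-deficient fit; confounded coefficient(s): ",
         paste(aliased, collapse = ", "))
  structure(list(lm = fit, trait = trait, log_transform = log_transform,
                 data = d, formula = form),
            class = "ws_fit")
}

#' @export
print.ws_fit <- function(x, ...) {
  cat("Fixed-effects WS-within-line fit for", x$trait,
      if (x$log_transform) "(log scale)" else "", "\n")
  print(x$formula)
  cat("n =", nrow(x$data), " residual SD =",
      signif(summary(x$lm)$sigma, 4), "\n")
  invisible(x)
}

#' Least-squares means of WS within line, with Tukey-Kramer comparisons
#'
#' LSMeans for each line x WS cell are computed by averaging model
#' predictions uniformly over the observed hatch and sex levels; standard
#' errors come from the fit's coefficient covariance. All pairwise
#' intra-line comparisons use the studentized-range (Tukey-Kramer)
#' adjustment, appropriate for the unbalanced design, and are condensed
#' into a compact letter display per line (cells sharing a letter do not
#' differ at level `alpha`).
#'
#' @param fit a `ws_fit` from [fit_ws_fixed_model].
#' @param alpha type I error for the letter display (default 0.05).
#' @return data.frame with columns `line`, `WS`, `lsmean`, `se`, `letters`;
#'   attribute `"comparisons"` holds the pairwise table (estimate, SE,
#'   t ratio, Tukey-adjusted p).
#' @export
lsmeans_tukey <- function(fit, alpha = 0.05) {
  lmfit <- fit$lm
  d <- fit$data
  V <- stats::vcov(lmfit)
  beta <- stats::coef(lmfit)
  tt <- stats::terms(lmfit)
  cells <- expand.grid(WS = levels(d$WS), line = levels(d$line),
                       KEEP.OUT.ATTRS = FALSE)
  grid_h <- levels(d$hatch); grid_s <- levels(d$sex)

  # row of the L matrix for one cell: average of model-matrix rows over the
  # uniform hatch x sex grid
  lrow <- function(line, ws) {
    g <- expand.grid(hatch = grid_h, sex = grid_s, stringsAsFactors = FALSE)
    g$line <- line; g$WS <- ws; g$y <- 0
    g$hatch <- factor(g$hatch, levels = grid_h)
    g$sex <- factor(g$sex, levels = grid_s)
    g$line <- factor(g$line, levels = levels(d$line))
    g$WS <- factor(g$WS, levels = levels(d$WS))
    mm <- stats::model.matrix(stats::delete.response(tt), g)
    colMeans(mm)
  }
  L <- t(mapply(lrow, as.character(cells$line), as.character(cells$WS)))
  est <- drop(L %*% beta)
  se <- sqrt(rowSums((L %*% V) * L))
  out <- data.frame(line = cells$line, WS = cells$WS,
                    lsmean = est, se = se, stringsAsFactors = FALSE)

  df <- stats::df.residual(lmfit)
  cmp <- NULL
  out$letters <- ""
  for (ln in levels(d$line)) {
    rows <- which(out$line == ln)
    k <- length(rows)
    pm <- matrix(FALSE, k, k) # significance indicator
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      lc <- L[rows[i], ] - L[rows[j], ]
      sed <- sqrt(drop(t(lc) %*% V %*% lc))
      tval <- (est[rows[i]] - est[rows[j]]) / sed
      padj <- stats::ptukey(abs(tval) * sqrt(2), nmeans = k, df = df,
                            lower.tail = FALSE)
      cmp <- rbind(cmp, data.frame(
        line = ln, contrast = paste(out$WS[rows[i]], "-", out$WS[rows[j]]),
        estimate = est[rows[i]] - est[rows[j]], se = sed,
        t.ratio = tval, p.value = padj))
      pm[i, j] <- pm[j, i] <- padj < alpha
    }
    out$letters[rows] <- .cld_letters(pm, order(-est[rows]))
  }
  attr(out, "comparisons") <- cmp
  attr(out, "alpha") <- alpha
  out
}

## compact letter display: letters = maximal subsets with no significant
## internal pair, enumerated exhaustively (k is small), lettered from the
## largest mean downward
.cld_letters <- function(sig, ord) {
  k <- nrow(sig)
  if (k > 12) stop("letter display supported for up to 12 means")
  subsets <- list()
  for (m in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)
    if (length(members) == 0) next
    ok <- TRUE
    if (length(members) > 1) {
      prs <- utils::combn(members, 2)
      ok <- !any(sig[t(prs)])
    }
    if (ok) subsets[[length(subsets) + 1L]] <- members
  }
  # keep maximal subsets only
  maximal <- Filter(function(s) !any(vapply(subsets, function(t2)
    length(t2) > length(s) && all(s %in% t2), TRUE)), subsets)
  # order letter groups by the rank of their best mean
  pos <- match(seq_len(k), ord)
  maximal <- maximal[order(vapply(maximal, function(s) min(pos[s]), 1))]
  lett <- rep("", k)
  for (a in seq_along(maximal))
    lett[maximal[[a]]] <- paste0(lett[maximal[[a]]], letters[a])
  lett
}
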