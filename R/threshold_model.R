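#' Specify a threshold-linear animal model
#'
#' Trait 1 is either the ordinal white-striping score (`"WS"`, analysed on
#' the liability scale with the first threshold fixed at 0 and liability
#' residual variance fixed at 1) or a quantitative trait; trait 2, when
#' given, is a quantitative trait, making the model bivariate. Fixed
#' effects are an overall mean plus hatch and sex; a common
#' maternal-environment effect can be attached to one quantitative trait
#' (intended for body weight). Records can be restricted to one selection
#' line while the full pedigree is retained (intra-line analysis).
#'
#' @param trait1 `"WS"` for the ordinal trait, or a quantitative trait
#'   column name.
#' @param trait2 quantitative trait column name, or `NULL` for a univariate
#'   model.
#' @param fixed fixed-effect factor columns (default `c("hatch", "sex")`).
#' @param maternal_for trait name (matching `trait1` or `trait2`) that
#'   receives the common maternal-environment effect, or `NULL`.
#' @param lines restrict records to these line labels (`NULL` = all).
#' @param include_line a line fixed effect is not part of the default
#'   genetic model; set `TRUE` to add one.
#' @param intercept include an overall mean (default `TRUE`; switching it
#'   off is useful for validating the sampler against closed-form
#'   shrinkage results).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(trait1 = "WS", trait2 = NULL,
                       fixed = c("hatch", "sex"),
                       maternal_for = NULL, lines = NULL,
                       include_line = FALSE, intercept = TRUE) {
  if (!is.null(maternal_for) &&
      !maternal_for %in% c(trait1, trait2))
    stop("maternal_for must name trait1 or trait2")
  if (!is.null(maternal_for) && identical(maternal_for, "WS"))
    stop("the maternal environment effect attaches to a quantitative trait")
  structure(list(trait1 = trait1, trait2 = trait2, fixed = fixed,
                 maternal_for = maternal_for, lines = lines,
                 include_line = isTRUE(include_line),
                 intercept = isTRUE(intercept)),
            class = "model_spec")
}

#' MCMC schedule for the Gibbs sampler
#'
#' Defaults follow the long single-chain schedule used for the real
#' analysis: 100,000 iterations, 20,000 discarded as burn-in, every 20th
#' kept, retaining 4,000 draws. Desk-scale work uses shorter documented
#' schedules.
#'
#' @param n_iter total iterations.
#' @param burnin discarded initial iterations (`< n_iter`).
#' @param thin thinning interval.
#' @param seed integer seed for the single chain.
#' @return object of class `mcmc_config` with element `n_retained`.
#' @export
mcmc_config <- function(n_iter = 100000L, burnin = 20000L, thin = 20L,
                        seed = 1L) {
  n_iter <- as.integer(n_iter); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin >= n_iter) stop("burnin must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 seed = as.integer(seed),
                 n_retained = (n_iter - burnin) %/% thin),
            class = "mcmc_config")
}

#' Missing-record plan for a trait pair
#'
#' Classifies every pedigree individual by its contribution to the
#' likelihood: both traits, one trait (the other is integrated out by data
#' augmentation), or relationships only (unphenotyped ancestors and
#' relatives).
#'
#' @param ped a [pedigree].
#' @param tab phenotype data.frame.
#' @param spec a [model_spec].
#' @return data.frame with columns `id`, `has_trait1`, `has_trait2`,
#'   `contributes` (one of `"both"`, `"trait1"`, `"trait2"`,
#'   `"pedigree-only"`).
#' @export
handle_missing <- function(ped, tab, spec) {
  tab <- .restrict_lines(tab, spec)
  m <- match(ped$id, tab$id)
  h1 <- !is.na(m) & !is.na(tab[[.t1col(spec)]][m])
  h2 <- if (is.null(spec$trait2)) rep(FALSE, nrow(ped)) else
    !is.na(m) & !is.na(tab[[spec$trait2]][m])
  data.frame(id = ped$id, has_trait1 = h1, has_trait2 = h2,
             contributes = ifelse(h1 & h2, "both",
                           ifelse(h1, "trait1",
                           ifelse(h2, "trait2", "pedigree-only"))))
}

.t1col <- function(spec) if (identical(spec$trait1, "WS")) "WS" else spec$trait1

.restrict_lines <- function(tab, spec) {
  if (is.null(spec$lines)) return(tab)
  if (!"line" %in% names(tab)) stop("no line column to restrict on")
  tab[tab$line %in% spec$lines, , drop = FALSE]
}

## indicator design for one factor set: returns list(fidx = 0-based matrix
## with -1 for reference level, nbeta, labels)
.build_design <- function(df, fixed, intercept = TRUE) {
  nrec <- nrow(df)
  off <- if (intercept) 1L else 0L
  fidx <- matrix(-1L, nrec, off + length(fixed))
  labels <- character(0)
  nb <- 0L
  if (intercept) {
    fidx[, 1] <- 0L
    labels <- "(Intercept)"
    nb <- 1L
  }
  for (k in seq_along(fixed)) {
    f <- droplevels(factor(df[[fixed[k]]]))
    lv <- levels(f)
    if (length(lv) > 1 || !intercept) {
      drop_ref <- intercept # corner constraint only when a mean is present
      code <- as.integer(f) - 1L
      if (drop_ref) {
        fidx[, off + k] <- ifelse(code == 0L, -1L, nb + code - 1L)
        labels <- c(labels, paste0(fixed[k], lv[-1]))
        nb <- nb + length(lv) - 1L
      } else {
        fidx[, off + k] <- nb + code
        labels <- c(labels, paste0(fixed[k], lv))
        nb <- nb + length(lv)
      }
    }
  }
  if (nb == 0L) { # no fixed effects at all: zero-column design
    fidx <- matrix(-1L, nrec, 1)
  }
  list(fidx = fidx, nbeta = nb, labels = labels)
}

#' Run the Gibbs sampler for a threshold-linear animal model
#'
#' Fits the specified (bi)variate animal model by Gibbs sampling: latent
#' liabilities and missing co-trait records are imputed by data
#' augmentation; the free threshold is drawn from its uniform full
#' conditional; location effects (fixed, maternal, breeding values) are
#' drawn from normal full conditionals using the sparse inverse
#' relationship matrix; the genetic covariance is drawn from its
#' inverse-Wishart full conditional; the residual covariance is drawn
#' subject to the liability constraint `sigma2_e1 = 1` via the conditional
#' regression decomposition. Priors: flat for fixed effects and thresholds,
#' inverse-Wishart(dim + 1, 0.1 I) for G, scaled-inverse-chi-squared(1,
#' 0.1) for the maternal variance and the (conditional) residual variances.
#'
#' @param ped a [pedigree].
#' @param tab phenotype data.frame (column `id` plus trait and
#'   fixed-effect columns).
#' @param spec a [model_spec].
#' @param cfg an [mcmc_config].
#' @param fix_G,fix_R,fix_sigma2_c optionally hold a (co)variance component
#'   fixed at the given value for the whole run (used for validation
#'   against deterministic solvers).
#' @param prior_scale multiplier on the base prior scale (0.1) of the
#'   variance-component priors; refitting with, say, 0.1 and 10 quantifies
#'   prior sensitivity.
#' @param verbose print a one-line setup summary.
#' @return object of class `chain_store`: a data.frame with one row per
#'   retained draw and columns `sigma2_g1`, `sigma_g12`, `sigma2_g2`,
#'   `sigma2_e1`, `sigma_e12`, `sigma2_e2`, `sigma2_c`, `t2`, `h2_1`,
#'   `h2_2`, `rg` (univariate models carry `NA` in the bivariate-only
#'   columns). Attributes: `spec`, `cfg`, `seed`, `location_means` (posterior
#'   means of fixed, maternal and breeding-value effects), `n_records`,
#'   `n_clamped`.
#' @export
gibbs_run <- function(ped, tab, spec, cfg = mcmc_config(),
                      fix_G = NULL, fix_R = NULL, fix_sigma2_c = NULL,
                      prior_scale = 1, verbose = FALSE) {
  stopifnot(inherits(ped, "pedigree"), inherits(spec, "model_spec"),
            inherits(cfg, "mcmc_config"))
  tab <- .restrict_lines(tab, spec)
  if (!all(tab$id %in% ped$id))
    stop("phenotyped individual(s) absent from pedigree: ",
         paste(utils::head(setdiff(tab$id, ped$id)), collapse = ", "))
  if (anyDuplicated(tab$id)) stop("multiple records per individual")

  liability <- identical(spec$trait1, "WS")
  nt <- if (is.null(spec$trait2)) 1L else 2L

  y1raw <- if (liability) ws_factor(tab$WS) else as.numeric(tab[[spec$trait1]])
  y2raw <- if (nt == 2) as.numeric(tab[[spec$trait2]]) else NULL
  obs1 <- !is.na(y1raw)
  obs2 <- if (nt == 2) !is.na(y2raw) else rep(FALSE, nrow(tab))
  rec <- obs1 | obs2
  tab <- tab[rec, , drop = FALSE]
  y1raw <- y1raw[rec]; obs1 <- obs1[rec]
  if (nt == 2) { y2raw <- y2raw[rec]; obs2 <- obs2[rec] }
  nrec <- nrow(tab)
  if (nrec == 0) stop("no phenotyped records")

  if (liability) {
    cnt <- table(y1raw)
    if (any(cnt == 0))
      stop("ordinal category with zero observations (",
           paste(names(cnt)[cnt == 0], collapse = ", "),
           "): its threshold is unidentifiable")
  }

  fixed <- spec$fixed
  if (spec$include_line) fixed <- c(fixed, "line")
  miss_fx <- setdiff(fixed, names(tab))
  if (length(miss_fx))
    stop("fixed-effect column(s) missing: ", paste(miss_fx, collapse = ", "))
  des1 <- .build_design(tab, fixed, spec$intercept)
  des2 <- if (nt == 2) des1 else list(fidx = matrix(-1L, 0, 0), nbeta = 0L,
                                      labels = character(0))

  # maternal effect mapping (dam of each record animal)
  mat_trait <- 0L
  dam_idx <- rep(-1L, nrec)
  n_dams <- 0L
  dam_ids <- character(0)
  if (!is.null(spec$maternal_for)) {
    mat_trait <- if (identical(spec$maternal_for, spec$trait1)) 1L else 2L
    dams <- ped$dam[match(tab$id, ped$id)]
    dam_ids <- sort(unique(stats::na.omit(dams)))
    dam_idx <- ifelse(is.na(dams), -1L, match(dams, dam_ids) - 1L)
    n_dams <- length(dam_ids)
  }

  # initial values -------------------------------------------------------
  if (liability) {
    freq <- as.numeric(cnt) / sum(cnt)
    s0 <- sqrt(2) # liability SD guess under h2 = 0.5, sigma2_e = 1
    cum <- cumsum(freq)
    z <- stats::qnorm(cum[1])
    t2_init <- (stats::qnorm(cum[2]) - z) * s0
    mids <- stats::qnorm(c(cum[1] / 2,
                           (cum[1] + cum[2]) / 2,
                           (cum[2] + 1) / 2))
    y1_init <- (mids[as.integer(y1raw)] - z) * s0
    y1_init[is.na(y1_init)] <- 0
    cat1 <- ifelse(is.na(y1raw), -1L, as.integer(y1raw) - 1L)
  } else {
    y1_init <- ifelse(obs1, y1raw, mean(y1raw[obs1]))
    cat1 <- rep(-1L, nrec)
    t2_init <- 0
  }
  y2_pass <- if (nt == 2) ifelse(obs2, y2raw, NaN) else numeric(0)

  beta_init <- function(y, des) {
    if (des$nbeta == 0L) return(numeric(0))
    # least squares on the indicator design
    X <- matrix(0, nrec, des$nbeta)
    for (c in seq_len(ncol(des$fidx))) {
      k <- des$fidx[, c]
      sel <- k >= 0
      X[cbind(which(sel), k[sel] + 1L)] <- 1
    }
    b <- qr.coef(qr(X), y)
    b[is.na(b)] <- 0
    b
  }
  b1 <- beta_init(y1_init, des1)
  b2 <- if (nt == 2) beta_init(ifelse(is.finite(y2_pass), y2_pass,
                                      mean(y2raw[obs2])), des2) else numeric(0)

  v1 <- if (liability) 1 else stats::var(y1raw[obs1])
  v2 <- if (nt == 2) stats::var(y2raw[obs2]) else NA
  G0 <- if (nt == 2) diag(c(v1 / 2 + liability * 0.5, v2 / 2)) else
    matrix(v1 / 2 + liability * 0.5, 1, 1)
  R0 <- if (nt == 2) diag(c(if (liability) 1 else v1 / 2, v2 / 2)) else
    matrix(if (liability) 1 else v1 / 2, 1, 1)
  if (!is.null(fix_G)) G0 <- as.matrix(fix_G)
  if (!is.null(fix_R)) R0 <- as.matrix(fix_R)
  sc0 <- if (mat_trait > 0) {
    if (!is.null(fix_sigma2_c)) fix_sigma2_c else
      0.1 * (if (mat_trait == 2) v2 else v1)
  } else 1

  s0 <- 0.1 * prior_scale
  priors <- list(nu_g = nt + 1, S_g = diag(s0, nt),
                 nu_r = 1, S_r = diag(s0, nt),
                 nu_c = 1, s2_c0 = s0)
  if (nt == 2 && !liability) priors$nu_r <- 3

  Ainv <- a_inverse(ped)
  rec_animal <- match(tab$id, ped$id) - 1L

  if (verbose)
    message(sprintf(
      "gibbs_run: %d records (%d trait1, %d trait2), %d pedigree, %s model",
      nrec, sum(obs1), sum(obs2), nrow(ped),
      if (nt == 2) "bivariate" else "univariate"))

  set.seed(cfg$seed)
  res <- .gibbs_core(methods::as(methods::as(Ainv, "generalMatrix"),
                                 "CsparseMatrix"),
                     nt, liability,
                     cat1, y1_init, obs1, y2_pass, rec_animal,
                     des1$fidx, des1$nbeta,
                     des2$fidx, des2$nbeta,
                     mat_trait, dam_idx, n_dams,
                     cfg$n_iter, cfg$burnin, cfg$thin,
                     priors,
                     list(G = G0, R = R0, sigma2_c = sc0,
                          beta1 = b1, beta2 = b2),
                     list(G = !is.null(fix_G), R = !is.null(fix_R),
                          sigma2_c = !is.null(fix_sigma2_c)),
                     t2_init)

  S <- res$samples
  draws <- data.frame(
    sigma2_g1 = S[, 1], sigma_g12 = S[, 2], sigma2_g2 = S[, 3],
    sigma2_e1 = S[, 4], sigma_e12 = S[, 5], sigma2_e2 = S[, 6],
    sigma2_c = S[, 7], t2 = S[, 8])
  mat2 <- mat_trait == 2L
  mat1 <- mat_trait == 1L
  draws$h2_1 <- draws$sigma2_g1 /
    (draws$sigma2_g1 + draws$sigma2_e1 +
       if (mat1) draws$sigma2_c else 0)
  draws$h2_2 <- if (nt == 2) draws$sigma2_g2 /
    (draws$sigma2_g2 + draws$sigma2_e2 +
       if (mat2) draws$sigma2_c else 0) else NA_real_
  draws$rg <- if (nt == 2)
    draws$sigma_g12 / sqrt(draws$sigma2_g1 * draws$sigma2_g2) else NA_real_

  loc <- list(beta1 = stats::setNames(as.numeric(res$beta1_mean),
                                      des1$labels),
              beta2 = if (nt == 2)
                stats::setNames(as.numeric(res$beta2_mean), des2$labels),
              maternal = if (mat_trait > 0)
                stats::setNames(as.numeric(res$c_mean), dam_ids),
              breeding_values = {
                bv <- as.matrix(res$a_mean)
                rownames(bv) <- ped$id
                colnames(bv) <- c(spec$trait1, spec$trait2)[seq_len(nt)]
                bv
              })

  structure(draws,
            class = c("chain_store", "data.frame"),
            spec = spec, cfg = cfg, seed = cfg$seed,
            n_records = nrec, n_trait1 = sum(obs1),
            n_trait2 = if (nt == 2) sum(obs2) else 0L,
            location_means = loc,
            n_clamped = res$n_clamped)
}

#' @export
print.chain_store <- function(x, ...) {
  cfg <- attr(x, "cfg")
  cat("chain_store:", nrow(x), "retained draws",
      sprintf("(%d iterations, %d burn-in, thin %d, seed %d)\n",
              cfg$n_iter, cfg$burnin, cfg$thin, attr(x, "seed")))
  cat("parameters:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a chain as delimited text
#'
#' One row per retained draw, named columns; a `#`-prefixed header records
#' the schedule and seed.
#'
#' @param chain a `chain_store`.
#' @param path file path.
#' @return `path` (write) or a data.frame (read), invisibly for write.
#' @export
write_chain <- function(chain, path) {
  cfg <- attr(chain, "cfg")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# threshold-linear animal model chain; n_iter=%d burnin=%d thin=%d seed=%d; t1=0, sigma2_e1=1 when liability",
    cfg$n_iter, cfg$burnin, cfg$thin, attr(chain, "seed")), con)
  utils::write.table(as.data.frame(chain), con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#")
}
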