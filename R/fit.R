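#' Macroevolutionary model specifications
#'
#' The four candidate models of moment-arm evolution: a Brownian-motion
#' null (`BM1`), a three-optimum OU (`OU3`, one optimum per lifestyle), and
#' two two-optimum OU models: `OU2_terr` shares an optimum between
#' cursorial and fossorial species (the terrestrial category) and
#' `OU2_over` between cursorial and scansorial species (the overground
#' category). Parameter counts: OU models count their optima plus the
#' adaptive rate, perturbation rate and direct-effect slope; BM1 counts
#' mean, rate and slope.
#'
#' @param name one of `"BM1"`, `"OU3"`, `"OU2_terr"`, `"OU2_over"`.
#' @return a `model_spec` list with `name`, `collapse` (lifestyle ->
#'   optimum mapping, `NULL` for BM1) and `k`.
#' @export
model_spec <- function(name = c("BM1", "OU3", "OU2_terr", "OU2_over")) {
  name <- match.arg(name)
  collapse <- switch(name,
    BM1 = NULL,
    OU3 = c(cursorial = "cursorial", fossorial = "fossorial",
            scansorial = "scansorial"),
    OU2_terr = c(cursorial = "terrestrial", fossorial = "terrestrial",
                 scansorial = "scansorial"),
    OU2_over = c(cursorial = "overground", fossorial = "fossorial",
                 scansorial = "overground"))
  k <- if (name == "BM1") 3L else length(unique(collapse)) + 3L
  structure(list(name = name, collapse = collapse, k = k),
            class = "model_spec")
}

#' Default half-life and stationary-variance grids
#'
#' Log-spaced grids spanning half-lives from effectively instantaneous
#' adaptation (0.001 my) to about the depth of the clade (40 my), and
#' stationary variances from 1e-4 to 1 (squared log-trait units). The
#' stationary-variance grid is denser than the half-life grid because it
#' costs almost nothing (for fixed half-life the variance enters the
#' likelihood as a pure scale) while the support-region resolution depends
#' directly on it.
#'
#' @param n_hl,n_vy number of grid points.
#' @return list with `hl` and `vy` vectors.
#' @export
default_grids <- function(n_hl = 30, n_vy = 60) {
  list(hl = exp(seq(log(0.001), log(40), length.out = n_hl)),
       vy = exp(seq(log(1e-4), log(1), length.out = n_vy)))
}

#' Fit one macroevolutionary model by grid-search profile likelihood
#'
#' For each grid combination of phylogenetic half-life and stationary
#' variance, the regime weight matrix and OU covariance are built, the
#' optima and direct-effect slope estimated by GLS, and the likelihood
#' recorded; the maximum-likelihood grid point supplies the reported
#' regression statistics, and the two-unit support region collects the
#' half-life / stationary-variance range of all grid points within two
#' log-likelihood units of the maximum. `BM1` uses a grand-mean design with
#' Brownian covariance and a closed-form profile MLE of the rate.
#'
#' @param spec a [model_spec()].
#' @param tree ultrametric `phylo` tree.
#' @param painting a `regime_painting` covering every branch (unused for
#'   BM1).
#' @param data data frame with columns `species`, `y` (natural-log trait)
#'   and `x` (natural-log femoral diameter); species must match the tips.
#' @param hl_grid,vy_grid positive grids (defaults [default_grids()]).
#' @param obs_var per-species observation variance added to the diagonal.
#' @param include_slope keep the direct-effect slope in the design
#'   (applies to BM1 as well).
#' @return an object of class `ou_fit`.
#' @export
fit_model <- function(spec, tree, painting = NULL, data,
                      hl_grid = NULL, vy_grid = NULL,
                      obs_var = 0, include_slope = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(hl_grid)) hl_grid <- default_grids()$hl
  if (is.null(vy_grid)) vy_grid <- default_grids()$vy
  if (!all(c("species", "y", "x") %in% names(data)))
    .stop_geom("data must have columns species, y, x")
  if (!setequal(data$species, tree$tip.label))
    .stop_geom("data species must match tree tips exactly")
  data <- data[match(tree$tip.label, data$species), ]
  y <- data$y; x <- data$x
  n <- length(y)
  if (any(!is.finite(y)) || any(!is.finite(x)))
    .stop_geom("non-finite trait values")

  if (spec$name == "BM1") {
    X <- if (include_slope) cbind(mean = 1, b = x) else cbind(mean = 1)
    ta <- ape::vcv(tree)
    g0 <- gls_fit(y, X, ta + diag(rep(max(obs_var, 1e-12), n)))
    s2 <- g0$rss_w / n                       # profile MLE of the BM rate
    V <- s2 * ta + diag(rep(obs_var, n))
    g <- gls_fit(y, X, V)
    ic <- information_criteria(g$logLik, spec$k, n)
    fit <- list(spec = spec, n = n, logLik = g$logLik,
                theta = g$beta["mean"], theta_se = g$se["mean"],
                b = if (include_slope) g$beta[["b"]] else NA_real_,
                b_se = if (include_slope) g$se[["b"]] else NA_real_,
                params = list(alpha = 0, sigma2 = s2, hl = Inf, vy = NA_real_),
                ml_point = c(hl = Inf, vy = NA_real_),
                support = NULL, grid_surface = NULL,
                AICc = ic$AICc, SIC = ic$SIC, coefficients = g$beta,
                se = g$se)
    return(structure(fit, class = "ou_fit"))
  }

  stopifnot(inherits(painting, "regime_painting"))
  if (any(hl_grid <= 0) || any(vy_grid <= 0))
    .stop_geom("grids must be positive")
  optima <- unique(spec$collapse)
  ## a regime painted on no branch (and not at the root) contributes zero
  ## weight everywhere: its optimum is unidentifiable and is dropped
  present <- unique(c(painting$branch_regime,
                      painting$node_state[ape::Ntip(tree) + 1L]))
  present_opt <- unique(spec$collapse[present])
  if (length(present_opt) < length(optima)) {
    warning(sprintf("optimum(s) %s have no painted branches and were dropped",
                    paste(setdiff(optima, present_opt), collapse = ", ")))
    spec$k <- spec$k - (length(optima) - length(present_opt))
    optima <- present_opt
  }
  C <- outer(painting$states, optima,
             function(s, o) as.numeric(spec$collapse[s] == o))
  dimnames(C) <- list(painting$states, optima)
  surface <- matrix(NA_real_, length(hl_grid), length(vy_grid),
                    dimnames = list(signif(hl_grid, 6), signif(vy_grid, 6)))
  best <- list(logLik = -Inf)
  n_fail <- 0
  for (ih in seq_along(hl_grid)) {
    alpha <- log(2) / hl_grid[ih]
    W <- ou_weight_matrix(tree, painting, alpha) %*% C
    X <- if (include_slope) cbind(W, b = x) else W
    A <- ou_covariance(tree, alpha, vy = 1)    # vy enters as a pure scale
    scale_free <- all(obs_var == 0)
    if (scale_free) {
      g1 <- tryCatch(gls_fit(y, X, A), error = function(e) NULL)
      if (is.null(g1)) { n_fail <- n_fail + length(vy_grid); next }
    }
    for (iv in seq_along(vy_grid)) {
      vy <- vy_grid[iv]
      if (scale_free) {
        ## V = vy * A rescales the unit-variance solve:
        ## logL(vy) = logL(A) + rss/2 - (n/2) log vy - rss/(2 vy)
        ll <- g1$logLik + g1$rss_w / 2 - n / 2 * log(vy) -
          g1$rss_w / (2 * vy)
        g <- g1
      } else {
        V <- vy * A + diag(rep(obs_var, n))
        g <- tryCatch(gls_fit(y, X, V), error = function(e) NULL)
        if (is.null(g)) { n_fail <- n_fail + 1; next }
        ll <- g$logLik
      }
      surface[ih, iv] <- ll
      if (ll > best$logLik)
        best <- list(logLik = ll, ih = ih, iv = iv, g = g,
                     alpha = alpha, scale_free = scale_free)
    }
  }
  if (!is.finite(best$logLik))
    .stop_geom("all grid points failed numerically")
  if (n_fail > 0)
    warning(sprintf("%d grid points failed numerically and were excluded", n_fail))
  hl_ml <- hl_grid[best$ih]; vy_ml <- vy_grid[best$iv]
  ## refit at the ML point so SEs use the actual (scaled) covariance
  alpha <- log(2) / hl_ml
  W <- ou_weight_matrix(tree, painting, alpha) %*% C
  X <- if (include_slope) cbind(W, b = x) else W
  V <- ou_covariance(tree, alpha, vy = vy_ml) + diag(rep(obs_var, n))
  g <- gls_fit(y, X, V)
  sup_hl <- .support_interval(hl_grid, apply(surface, 1, max, na.rm = TRUE),
                              best$logLik - 2)
  sup_vy <- .support_interval(vy_grid, apply(surface, 2, max, na.rm = TRUE),
                              best$logLik - 2)
  support <- c(hl_lo = sup_hl[1], hl_hi = sup_hl[2],
               vy_lo = sup_vy[1], vy_hi = sup_vy[2])
  ic <- information_criteria(g$logLik, spec$k, n)
  fit <- list(spec = spec, n = n, logLik = g$logLik,
              theta = g$beta[optima], theta_se = g$se[optima],
              b = if (include_slope) g$beta[["b"]] else NA_real_,
              b_se = if (include_slope) g$se[["b"]] else NA_real_,
              params = ou_params(hl = hl_ml, vy = vy_ml),
              ml_point = c(hl = hl_ml, vy = vy_ml),
              support = support, grid_surface = surface,
              AICc = ic$AICc, SIC = ic$SIC,
              coefficients = g$beta, se = g$se)
  structure(fit, class = "ou_fit")
}

## two-unit support interval of a profile likelihood sampled on a grid:
## boundary crossings are interpolated linearly in log-likelihood vs
## log-parameter, so the interval is not truncated to grid points
.support_interval <- function(grid, prof, cutoff) {
  ok <- is.finite(prof)
  inside <- which(ok & prof >= cutoff)
  if (length(inside) == 0L) return(c(NA_real_, NA_real_))
  lo_i <- min(inside); hi_i <- max(inside)
  lg <- log(grid)
  lo <- grid[lo_i]
  if (lo_i > 1L && is.finite(prof[lo_i - 1L])) {
    f <- (prof[lo_i] - cutoff) / (prof[lo_i] - prof[lo_i - 1L])
    lo <- exp(lg[lo_i] - f * (lg[lo_i] - lg[lo_i - 1L]))
  }
  hi <- grid[hi_i]
  if (hi_i < length(grid) && is.finite(prof[hi_i + 1L])) {
    f <- (prof[hi_i] - cutoff) / (prof[hi_i] - prof[hi_i + 1L])
    hi <- exp(lg[hi_i] + f * (lg[hi_i + 1L] - lg[hi_i]))
  }
  unname(c(lo, hi))
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): logL = %.3f, AICc = %.2f, SIC = %.2f\n",
              x$spec$name, x$n, x$logLik, x$AICc, x$SIC))
  if (!is.null(x$support))
    cat(sprintf("  hl = %.3g my {%.3g; %.3g}, vy = %.3g {%.3g; %.3g}\n",
                x$ml_point["hl"], x$support["hl_lo"], x$support["hl_hi"],
                x$ml_point["vy"], x$support["vy_lo"], x$support["vy_hi"]))
  for (i in seq_along(x$theta))
    cat(sprintf("  theta[%s] = %.3f +/- %.3f\n", names(x$theta)[i],
                x$theta[i], x$theta_se[i]))
  if (!is.na(x$b)) cat(sprintf("  b = %.3f +/- %.3f\n", x$b, x$b_se))
  invisible(x)
}

#' Rank fitted models by AICc
#'
#' @param fits list of [fit_model()] results on identical data.
#' @return data frame sorted ascending by AICc with a `dAICc` column; SIC
#'   is reported alongside.
#' @export
rank_models <- function(fits) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    .stop_geom("fits were computed on different sample sizes")
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$name, character(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    k = vapply(fits, function(f) f$spec$k, numeric(1)),
    SIC = vapply(fits, function(f) f$SIC, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)))
  tab <- tab[order(tab$AICc), ]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  rownames(tab) <- NULL
  tab
}
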