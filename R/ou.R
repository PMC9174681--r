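#' Convert between OU parameterizations
#'
#' The adaptive rate `alpha` (1/my) and perturbation rate `sigma2`
#' (trait^2/my) are reported as the phylogenetic half-life
#' `hl = ln(2)/alpha` (my) and stationary variance `vy = sigma2/(2 alpha)`
#' (trait^2). `alpha = 0` maps to an infinite half-life (Brownian limit).
#'
#' @param alpha,sigma2 natural parameters.
#' @param hl,vy transformed parameters.
#' @return `ou_params()` returns a list with all four quantities.
#' @export
ou_params <- function(alpha = NULL, sigma2 = NULL, hl = NULL, vy = NULL) {
  if (is.null(alpha) && !is.null(hl)) alpha <- if (is.infinite(hl)) 0 else log(2) / hl
  if (is.null(alpha)) .stop_geom("supply alpha or hl")
  if (alpha < 0) .stop_geom("alpha must be >= 0")
  if (is.null(sigma2) && !is.null(vy)) {
    if (alpha == 0) .stop_geom("vy is undefined at alpha = 0; supply sigma2")
    sigma2 <- 2 * alpha * vy
  }
  if (is.null(sigma2) || sigma2 <= 0) .stop_geom("sigma2 must be > 0")
  list(alpha = alpha, sigma2 = sigma2,
       hl = if (alpha == 0) Inf else log(2) / alpha,
       vy = if (alpha == 0) NA_real_ else sigma2 / (2 * alpha))
}

## per-tip root-to-tip segment table: t0, t1 (heights from root), edge index
.tip_paths <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  parent_edge <- integer(ntip + ape::Nnode(tree))
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  lapply(seq_len(ntip), function(i) {
    node <- i; edges <- integer(0)
    while (node != root) {
      e <- parent_edge[node]
      edges <- c(e, edges)
      node <- tree$edge[e, 1L]
    }
    data.frame(edge = edges,
               t0 = depth[tree$edge[edges, 1L]],
               t1 = depth[tree$edge[edges, 2L]])
  })
}

#' OU regime weight matrix
#'
#' For tip `i` and regime `r`, the weight is the fraction of the expected
#' trait value contributed by time spent evolving toward optimum `r`:
#' the sum over root-to-tip segments painted `r` of
#' `exp(-alpha (T - t_end)) - exp(-alpha (T - t_start))`, where `T` is the
#' tip depth and times are heights above the root. The residual ancestral
#' weight `exp(-alpha T)` is merged into the column of the regime painted
#' at the root, so every row sums to one.
#'
#' @param tree `phylo` tree.
#' @param painting a [consensus_painting()] (or any `regime_painting`).
#' @param alpha adaptive rate, >= 0.
#' @return n_tips x n_regimes matrix, rows named by tip, summing to 1.
#' @export
ou_weight_matrix <- function(tree, painting, alpha) {
  stopifnot(inherits(painting, "regime_painting"))
  if (alpha < 0) .stop_geom("alpha must be >= 0")
  states <- painting$states
  if (length(painting$branch_regime) != nrow(tree$edge) ||
      anyNA(painting$branch_regime))
    .stop_geom("painting must assign a regime to every branch")
  ntip <- ape::Ntip(tree)
  paths <- .tip_paths(tree)
  depth <- ape::node.depth.edgelength(tree)
  root_state <- painting$node_state[ntip + 1L]
  W <- matrix(0, ntip, length(states),
              dimnames = list(tree$tip.label, states))
  for (i in seq_len(ntip)) {
    pth <- paths[[i]]
    Ti <- depth[i]
    w <- exp(-alpha * (Ti - pth$t1)) - exp(-alpha * (Ti - pth$t0))
    reg <- painting$branch_regime[pth$edge]
    for (s in unique(reg)) W[i, s] <- sum(w[reg == s])
    W[i, root_state] <- W[i, root_state] + exp(-alpha * Ti)
  }
  W
}

#' OU trait covariance on an ultrametric tree
#'
#' `V[i,j] = vy exp(-alpha d_ij) (1 - exp(-2 alpha t_a))` with `d_ij` the
#' patristic distance and `t_a` the shared time of tips i and j. With
#' `alpha = 0` the Brownian limit `V = sigma2 t_a` is used and `sigma2`
#' must be supplied.
#'
#' @param tree ultrametric `phylo` tree.
#' @param alpha adaptive rate, >= 0.
#' @param vy stationary variance (ignored at `alpha = 0`).
#' @param sigma2 Brownian rate, required when `alpha = 0`.
#' @return n x n covariance matrix in tip order.
#' @export
ou_covariance <- function(tree, alpha, vy = NULL, sigma2 = NULL) {
  ta <- ape::vcv(tree)
  T_ <- diag(ta)
  if (max(T_) > 0 && diff(range(T_)) / max(T_) > 1e-6)
    .stop_geom("tree is not ultrametric (tip-depth spread %.3g)",
               diff(range(T_)))
  if (alpha < 0) .stop_geom("alpha must be >= 0")
  if (alpha == 0) {
    if (is.null(sigma2)) .stop_geom("sigma2 required in the Brownian limit")
    return(sigma2 * ta)
  }
  if (is.null(vy) || vy <= 0) .stop_geom("vy must be > 0")
  T0 <- max(T_)
  vy * exp(-2 * alpha * (T0 - ta)) * (1 - exp(-2 * alpha * ta))
}

#' Generalized least squares with known covariance
#'
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, coefficient covariance
#' `(X' V^-1 X)^-1`, and the multivariate-normal log-likelihood at the
#' estimate. Solved through the Cholesky factor of `V`.
#'
#' @param y response vector.
#' @param X design matrix (named columns).
#' @param V positive-definite covariance matrix.
#' @return list with `beta`, `se`, `vcov`, `logLik`, `residuals`, `rss_w`
#'   (whitened residual sum of squares).
#' @export
gls_fit <- function(y, X, V) {
  n <- length(y)
  if (!is.matrix(X)) X <- as.matrix(X)
  ch <- tryCatch(chol(V), error = function(e)
    .stop_geom("covariance matrix is not positive definite"))
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    .stop_geom("design is rank deficient after whitening (collinear: %s)",
               paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  XtX <- crossprod(Xw)
  vc <- chol2inv(chol(XtX))
  dimnames(vc) <- list(colnames(X), colnames(X))
  logdetV <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi) + logdetV + rss)
  list(beta = stats::setNames(as.numeric(beta), colnames(X)),
       se = stats::setNames(sqrt(diag(vc)), colnames(X)),
       vcov = vc, logLik = ll,
       residuals = as.numeric(y - X %*% beta), rss_w = rss)
}

#' Small-sample information criteria
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`; `SIC = -2 logL + k ln(n)`.
#'
#' @param logL maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size; AICc requires `n - k - 1 > 0`.
#' @return list with `AICc` and `SIC`.
#' @export
information_criteria <- function(logL, k, n) {
  if (n - k - 1 <= 0)
    .stop_geom("AICc undefined: n - k - 1 = %g <= 0", n - k - 1)
  list(AICc = -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1),
       SIC = -2 * logL + k * log(n))
}
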