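#' Construct an Mk lifestyle model
#'
#' Continuous-time Markov model of lifestyle evolution over the three
#' regimes, with an all-rates-different generator by default.
#'
#' @param Q 3 x 3 generator (1/my): non-negative off-diagonals, zero row sums.
#' @param root_prior probability vector over states at the root (default
#'   flat).
#' @param states state labels, in declared order.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(Q, root_prior = NULL, states = lifestyle_states()) {
  Q <- .check_rates(Q, states)
  if (is.null(root_prior)) root_prior <- rep(1 / length(states), length(states))
  if (length(root_prior) != length(states) || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8)
    .stop_geom("root_prior must be a probability vector over %d states",
               length(states))
  structure(list(states = states, Q = Q,
                 root_prior = stats::setNames(as.numeric(root_prior), states)),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk model over", paste(x$states, collapse = ", "), "\n")
  print(round(x$Q, 5))
  invisible(x)
}

## validate a tip-prior matrix against the tree, return rows in tip order
.check_tip_priors <- function(tree, tip_priors, states) {
  if (!is.matrix(tip_priors)) tip_priors <- as.matrix(tip_priors)
  if (is.null(rownames(tip_priors)) ||
      !all(tree$tip.label %in% rownames(tip_priors)))
    .stop_geom("tip_priors must have rownames covering every tip label")
  tip_priors <- tip_priors[tree$tip.label, , drop = FALSE]
  if (ncol(tip_priors) != length(states))
    .stop_geom("tip_priors needs one column per state")
  if (!is.null(colnames(tip_priors)) && !all(colnames(tip_priors) == states))
    tip_priors <- tip_priors[, states, drop = FALSE]
  if (any(tip_priors < 0) || any(abs(rowSums(tip_priors) - 1) > 1e-6))
    .stop_geom("tip_priors rows must be probability vectors")
  tip_priors
}

## postorder partial (conditional) likelihoods with log-scaling;
## returns list(L = matrix nodes x states, logscale = scalar, P = per-edge
## transition matrices)
.mk_prune <- function(tree, tip_priors, Q, states) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + ape::Nnode(tree)
  P <- lapply(tree$edge.length, function(t) ape::matexpo(Q * t))
  L <- matrix(1, nnode, length(states))
  L[seq_len(ntip), ] <- tip_priors
  logscale <- 0
  ## postorder: reverse of preorder edge walk
  for (e in rev(.preorder_edges(tree))) {
    from <- tree$edge[e, 1L]; to <- tree$edge[e, 2L]
    contrib <- as.numeric(P[[e]] %*% L[to, ])
    L[from, ] <- L[from, ] * contrib
    m <- max(L[from, ])
    if (m < 1e-150 && m > 0) { L[from, ] <- L[from, ] / m; logscale <- logscale + log(m) }
  }
  list(L = L, logscale = logscale, P = P)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree `phylo` tree.
#' @param tip_priors matrix of per-tip state prior probabilities (rows named
#'   by tip label, columns in state order); hard data are indicator rows.
#' @param Q generator matrix.
#' @param root_prior probability vector at the root (default flat).
#' @param states state labels.
#' @return log-likelihood of the tip data.
#' @export
mk_likelihood <- function(tree, tip_priors, Q,
                          root_prior = NULL, states = lifestyle_states()) {
  Q <- .check_rates(Q, states)
  tp <- .check_tip_priors(tree, tip_priors, states)
  if (is.null(root_prior)) root_prior <- rep(1 / length(states), length(states))
  pr <- .mk_prune(tree, tp, Q, states)
  root <- ape::Ntip(tree) + 1L
  log(sum(root_prior * pr$L[root, ])) + pr$logscale
}

#' Maximum-likelihood fit of the all-rates-different Mk model
#'
#' Optimizes the six off-diagonal rates on the log scale with bounded
#' multi-start BFGS, starting from a Pagel-style guess of one expected
#' change per total tree length.
#'
#' @inheritParams mk_likelihood
#' @param n_starts number of optimization starts (perturbed initials).
#' @param lower,upper rate bounds, 1/my.
#' @return an [mk_model()] with attributes `logLik` and `convergence`.
#' @export
fit_mk <- function(tree, tip_priors, root_prior = NULL,
                   states = lifestyle_states(), n_starts = 3,
                   lower = 1e-6, upper = 100) {
  tp <- .check_tip_priors(tree, tip_priors, states)
  hard <- apply(tp, 1, function(r) states[which.max(r)])
  if (length(unique(hard)) < 2L)
    warning("degenerate data: fewer than 2 distinct observed states; rates driven to the lower bound")
  ns <- length(states)
  off <- which(row(diag(ns)) != col(diag(ns)))
  build_Q <- function(logr) {
    Q <- matrix(0, ns, ns)
    Q[off] <- exp(logr)
    diag(Q) <- -rowSums(Q)
    dimnames(Q) <- list(states, states)
    Q
  }
  negll <- function(logr) {
    v <- -mk_likelihood(tree, tp, build_Q(logr), root_prior, states)
    if (!is.finite(v)) 1e10 else v
  }
  q0 <- length(states) / sum(tree$edge.length)
  best <- NULL
  for (k in seq_len(n_starts)) {
    init <- log(q0) + if (k == 1) rep(0, length(off)) else
      stats::rnorm(length(off), 0, 1)
    opt <- stats::optim(init, negll, method = "L-BFGS-B",
                        lower = log(lower), upper = log(upper),
                        control = list(maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  out <- mk_model(build_Q(best$par), root_prior, states)
  attr(out, "logLik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Marginal posterior state probabilities at every node
#'
#' Standard up-down (inside-outside) recursion: the independent analytical
#' check for stochastic-map node-state frequencies.
#'
#' @inheritParams mk_likelihood
#' @return matrix (tips + internal nodes) x states of posterior
#'   probabilities; rows sum to 1.
#' @export
node_marginals <- function(tree, tip_priors, Q, root_prior = NULL,
                           states = lifestyle_states()) {
  Q <- .check_rates(Q, states)
  tp <- .check_tip_priors(tree, tip_priors, states)
  if (is.null(root_prior)) root_prior <- rep(1 / length(states), length(states))
  pr <- .mk_prune(tree, tp, Q, states)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + ape::Nnode(tree)
  D <- matrix(0, nnode, length(states))
  root <- ntip + 1L
  D[root, ] <- root_prior
  for (e in .preorder_edges(tree)) {
    from <- tree$edge[e, 1L]; to <- tree$edge[e, 2L]
    ## above-contribution at `from` excluding the subtree below `to`
    sibs <- which(tree$edge[, 1L] == from)
    sibs <- sibs[sibs != e]
    above <- D[from, ]
    for (se in sibs)
      above <- above * as.numeric(pr$P[[se]] %*% pr$L[tree$edge[se, 2L], ])
    D[to, ] <- as.numeric(above %*% pr$P[[e]])
    if (max(D[to, ]) > 0) D[to, ] <- D[to, ] / max(D[to, ])
  }
  M <- D * pr$L
  M / rowSums(M)
}

#' Sample stochastic character maps
#'
#' Draws full lifestyle histories conditional on the tip data and a fixed
#' (typically ML) Mk model. Node states are sampled root-to-tips from their
#' exact conditional distributions (forward-filtering backward-sampling on
#' the pruning partials); each branch history is then drawn conditioned on
#' its endpoint states by uniformization, which samples the number of
#' Poissonized jumps and the jump chain exactly, without discretization.
#'
#' @param tree `phylo` tree.
#' @param tip_priors per-tip state priors (see [mk_likelihood()]).
#' @param model an [mk_model()].
#' @param n_maps number of maps.
#' @param seed optional integer seed.
#' @param max_jumps cap on jumps per branch when sampling the bridge.
#' @return list of `simmap` trees.
#' @export
sample_simmap <- function(tree, tip_priors, model, n_maps = 1000,
                          seed = NULL, max_jumps = 1e5) {
  stopifnot(inherits(model, "mk_model"))
  states <- model$states
  tp <- .check_tip_priors(tree, tip_priors, states)
  if (!is.null(seed)) set.seed(seed)
  pr <- .mk_prune(tree, tp, model$Q, states)
  root <- ape::Ntip(tree) + 1L
  eord <- .preorder_edges(tree)
  ns <- length(states)
  Om <- max(-diag(model$Q))
  Rmat <- if (Om > 0) diag(ns) + model$Q / Om else diag(ns)
  ## power cache for the uniformized jump chain
  Rpow <- list(diag(ns), Rmat)
  getRpow <- function(n) { # R^n, 0-indexed
    while (length(Rpow) < n + 1L)
      Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% Rmat
    Rpow[[n + 1L]]
  }
  root_w <- model$root_prior * pr$L[root, ]
  if (sum(root_w) <= 0) .stop_geom("data have zero likelihood under the model")
  maps_out <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(ape::Ntip(tree) + ape::Nnode(tree))
    node_state[root] <- sample.int(ns, 1L, prob = root_w)
    maps <- vector("list", nrow(tree$edge))
    for (e in eord) {
      from <- tree$edge[e, 1L]; to <- tree$edge[e, 2L]
      w <- pr$P[[e]][node_state[from], ] * pr$L[to, ]
      node_state[to] <- sample.int(ns, 1L, prob = w)
      maps[[e]] <- .sample_bridge(node_state[from], node_state[to],
                                  tree$edge.length[e],
                                  pr$P[[e]][node_state[from], node_state[to]],
                                  Om, Rmat, getRpow, states, max_jumps, e)
    }
    maps_out[[m]] <- .as_simmap(tree, maps, states)
  }
  maps_out
}

## endpoint-conditioned CTMC path on one branch, by uniformization
.sample_bridge <- function(a, b, t, p_ab, Om, Rmat, getRpow, states,
                           max_jumps, edge_id) {
  if (Om == 0 || t == 0) {
    if (a != b) .stop_geom("impossible endpoint pair on a zero-rate branch %d", edge_id)
    return(stats::setNames(t, states[a]))
  }
  ## sample the number of uniformized jumps
  u <- stats::runif(1) * p_ab
  n <- -1L; acc <- 0; lpois <- -Om * t; logfact <- 0
  repeat {
    n <- n + 1L
    if (n > 0) logfact <- logfact + log(n)
    term <- exp(lpois + n * log(Om * t) - logfact) * getRpow(n)[a, b]
    acc <- acc + term
    if (acc >= u || n >= max_jumps) break
  }
  if (n >= max_jumps)
    .stop_geom("uniformization cap exceeded on branch %d", edge_id)
  if (n == 0L) return(stats::setNames(t, states[a]))
  ## jump chain conditioned on endpoints
  seq_states <- integer(n + 1L)
  seq_states[1L] <- a; seq_states[n + 1L] <- b
  if (n > 1L) for (k in 2:n) {
    prev <- seq_states[k - 1L]
    w <- Rmat[prev, ] * getRpow(n + 1L - k)[, b]
    seq_states[k] <- sample.int(length(states), 1L, prob = w)
  }
  times <- sort(stats::runif(n, 0, t))
  bounds <- c(0, times, t)
  dur <- diff(bounds)
  ## collapse virtual (self) jumps
  st <- seq_states
  keep_states <- st[1L]; keep_dur <- dur[1L]
  for (k in 2:length(st)) {
    if (st[k] == st[k - 1L]) keep_dur[length(keep_dur)] <- keep_dur[length(keep_dur)] + dur[k]
    else { keep_states <- c(keep_states, st[k]); keep_dur <- c(keep_dur, dur[k]) }
  }
  stats::setNames(keep_dur, states[keep_states])
}

#' Prune stochastic character maps to a species subset
#'
#' Drops tips from each map, dissolving unbranched internal nodes and
#' concatenating their segment lists so state durations are conserved along
#' every retained path.
#'
#' @param maps a `simmap` or list of them.
#' @param keep_species character vector of tip labels to retain.
#' @return pruned map(s), same shape as the input.
#' @export
prune_simmap <- function(maps, keep_species) {
  single <- inherits(maps, "phylo")
  if (single) maps <- list(maps)
  tips <- maps[[1L]]$tip.label
  if (!all(keep_species %in% tips))
    .stop_geom("unknown species: %s",
               paste(setdiff(keep_species, tips), collapse = ", "))
  drop <- setdiff(tips, keep_species)
  out <- lapply(maps, function(m) {
    if (length(drop) == 0L) return(m)
    phytools::drop.tip.simmap(m, drop)
  })
  if (single) out[[1L]] else out
}

#' Rename a tip across a tree or a set of maps
#'
#' @param tree_or_maps a `phylo`/`simmap` or list of them.
#' @param old,new existing and replacement labels.
#' @return renamed object(s).
#' @export
rename_tip <- function(tree_or_maps, old, new) {
  single <- inherits(tree_or_maps, "phylo")
  xs <- if (single) list(tree_or_maps) else tree_or_maps
  for (x in xs) {
    if (!old %in% x$tip.label) .stop_geom("tip '%s' not present", old)
    if (new %in% x$tip.label) .stop_geom("tip '%s' already present", new)
  }
  xs <- lapply(xs, function(x) {
    x$tip.label[x$tip.label == old] <- new
    x
  })
  if (single) xs[[1L]] else xs
}

#' Collapse stochastic maps into a consensus regime painting
#'
#' Tallies node-state frequencies across maps, assigns each node its most
#' frequent state (ties broken by declared state order, with a warning), and
#' paints every branch with the state of its parent node.
#'
#' @param maps list of `simmap` trees sharing topology and labels.
#' @param states state labels in declared (tie-break) order.
#' @return an object of class `regime_painting`: list with `tree`,
#'   `states`, `node_state` (per node), `branch_regime` (per edge),
#'   `support` (node x state frequency matrix).
#' @export
consensus_painting <- function(maps, states = lifestyle_states()) {
  if (inherits(maps, "phylo")) maps <- list(maps)
  ref <- maps[[1L]]
  for (m in maps)
    if (!identical(m$edge, ref$edge) || !identical(m$tip.label, ref$tip.label))
      .stop_geom("maps must share topology and tip labels")
  nnode <- ape::Ntip(ref) + ape::Nnode(ref)
  counts <- matrix(0, nnode, length(states), dimnames = list(NULL, states))
  for (m in maps) {
    ns <- simmap_node_states(m)
    counts[cbind(seq_len(nnode), match(ns, states))] <-
      counts[cbind(seq_len(nnode), match(ns, states))] + 1
  }
  support <- counts / length(maps)
  mx <- apply(support, 1, max)
  tied <- rowSums(support == mx) > 1L
  if (any(tied))
    warning(sprintf("tie at node(s) %s broken by declared state order",
                    paste(which(tied), collapse = ", ")))
  node_state <- states[apply(support, 1, which.max)]
  branch_regime <- node_state[ref$edge[, 1L]]
  structure(list(tree = ref, states = states, node_state = node_state,
                 branch_regime = branch_regime, support = support),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting over", length(x$branch_regime), "branches:\n")
  print(table(x$branch_regime))
  invisible(x)
}
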