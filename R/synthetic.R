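#' Lifestyle state labels
#'
#' Declared regime order used throughout: ties and serializations follow it.
#' @export
lifestyle_states <- function() c("cursorial", "fossorial", "scansorial")

#' Simulate an ultrametric pure-birth tree
#'
#' Pure-birth (Yule) topology with branch lengths rescaled so that every
#' root-to-tip path equals `depth_my`, standing in for a dated ultrametric
#' phylogeny in million years.
#'
#' @param n_tips number of tips, >= 2.
#' @param depth_my root-to-tip depth, my.
#' @param seed optional integer seed (RNG state is used as-is when `NULL`).
#' @return an `ape::phylo` tree, ultrametric to machine precision.
#' @export
simulate_tree <- function(n_tips, depth_my = 35.78, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2) .stop_geom("n_tips must be >= 2")
  if (depth_my <= 0) .stop_geom("depth_my must be positive")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(as.integer(n_tips), birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (depth_my / depth)
  tr$tip.label <- sprintf("sp%03d", seq_len(as.integer(n_tips)))
  tr
}

#' Default all-rates-different lifestyle transition matrix (1/my)
#'
#' Mild asymmetric rates producing a handful of lifestyle transitions over
#' a 35 my radiation, rooted in the cursorial state.
#' @return 3 x 3 generator with zero row sums.
#' @export
default_mk_rates <- function() {
  s <- lifestyle_states()
  Q <- matrix(c(-0.05, 0.03, 0.02,
                0.010, -0.025, 0.015,
                0.010, 0.005, -0.015), 3, 3, byrow = TRUE,
              dimnames = list(s, s))
  Q
}

.check_rates <- function(Q, states) {
  if (!is.matrix(Q) || nrow(Q) != length(states) || ncol(Q) != length(states))
    .stop_geom("rate matrix must be %d x %d", length(states), length(states))
  off <- Q; diag(off) <- 0
  if (any(off < 0)) .stop_geom("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8)) .stop_geom("rate-matrix rows must sum to zero")
  dimnames(Q) <- list(states, states)
  Q
}

#' Simulate lifestyle histories along a tree
#'
#' Runs a continuous-time Markov chain with generator `mk_rates` down every
#' branch, recording the full piecewise-constant state history. The result
#' is a phytools-compatible stochastic character map (`simmap`), so the true
#' history can be handled by the same machinery as sampled maps.
#'
#' @param tree `phylo` tree (branch lengths in my).
#' @param mk_rates 3 x 3 generator, rows summing to zero, states in
#'   [lifestyle_states()] order.
#' @param root_state state label at the root.
#' @param seed optional integer seed.
#' @return a `simmap` tree; tip states are available via [simmap_tip_states()].
#' @export
simulate_lifestyles <- function(tree, mk_rates = default_mk_rates(),
                                root_state = "cursorial", seed = NULL) {
  states <- lifestyle_states()
  Q <- .check_rates(mk_rates, states)
  if (!root_state %in% states) .stop_geom("unknown root_state '%s'", root_state)
  if (!is.null(seed)) set.seed(seed)
  n_node <- ape::Nnode(tree) + ape::Ntip(tree)
  node_state <- character(n_node)
  root <- ape::Ntip(tree) + 1L
  node_state[root] <- root_state
  maps <- vector("list", nrow(tree$edge))
  ## process edges in an order where parents precede children
  eord <- .preorder_edges(tree)
  for (e in eord) {
    from <- tree$edge[e, 1L]; to <- tree$edge[e, 2L]
    t_total <- tree$edge.length[e]
    s <- node_state[from]
    seg_states <- character(0); seg_dur <- numeric(0)
    t_left <- t_total
    repeat {
      rate <- -Q[s, s]
      w <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (w >= t_left) {
        seg_states <- c(seg_states, s); seg_dur <- c(seg_dur, t_left)
        break
      }
      seg_states <- c(seg_states, s); seg_dur <- c(seg_dur, w)
      t_left <- t_left - w
      p <- Q[s, ]; p[s] <- 0
      s <- sample(states, 1L, prob = p)
    }
    maps[[e]] <- stats::setNames(seg_dur, seg_states)
    node_state[to] <- s
  }
  .as_simmap(tree, maps, states)
}

## edge indices ordered so that each edge's parent node was already visited
.preorder_edges <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  out <- integer(0)
  stack <- which(tree$edge[, 1L] == root)
  while (length(stack)) {
    e <- stack[1L]; stack <- stack[-1L]
    out <- c(out, e)
    stack <- c(which(tree$edge[, 1L] == tree$edge[e, 2L]), stack)
  }
  out
}

## assemble a phytools-compatible simmap object from per-edge maps
.as_simmap <- function(tree, maps, states) {
  mapped <- matrix(0, nrow(tree$edge), length(states),
                   dimnames = list(apply(tree$edge, 1, paste, collapse = ","),
                                   states))
  for (e in seq_along(maps)) {
    m <- maps[[e]]
    for (s in unique(names(m))) mapped[e, s] <- sum(m[names(m) == s])
  }
  tree$maps <- maps
  tree$mapped.edge <- mapped
  class(tree) <- c("simmap", class(tree))
  tree
}

#' Tip states of a stochastic character map
#' @param smap a `simmap` tree.
#' @return named character vector of states at the tips.
#' @export
simmap_tip_states <- function(smap) {
  ns <- simmap_node_states(smap)
  stats::setNames(ns[seq_len(ape::Ntip(smap))], smap$tip.label)
}

#' Node states implied by a stochastic character map
#' @param smap a `simmap` tree.
#' @return character vector over all nodes (tips first, then internal).
#' @export
simmap_node_states <- function(smap) {
  n_all <- ape::Ntip(smap) + ape::Nnode(smap)
  ns <- character(n_all)
  root <- ape::Ntip(smap) + 1L
  for (e in seq_len(nrow(smap$edge))) {
    m <- smap$maps[[e]]
    if (smap$edge[e, 1L] == root) ns[root] <- names(m)[1L]
    ns[smap$edge[e, 2L]] <- names(m)[length(m)]
  }
  ns
}

#' Simulate a Brownian covariate at the tips
#'
#' Brownian motion along the tree for the log femoral-diameter covariate.
#'
#' @param tree `phylo` tree.
#' @param sigma2_x BM rate (trait^2 per my), >= 0.
#' @param root_x root value.
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_covariate_bm <- function(tree, sigma2_x = 0.02, root_x = 0,
                                  seed = NULL) {
  if (sigma2_x < 0) .stop_geom("sigma2_x must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n_all <- ape::Ntip(tree) + ape::Nnode(tree)
  val <- numeric(n_all)
  val[ape::Ntip(tree) + 1L] <- root_x
  for (e in .preorder_edges(tree)) {
    from <- tree$edge[e, 1L]; to <- tree$edge[e, 2L]
    val[to] <- val[from] +
      stats::rnorm(1, 0, sqrt(sigma2_x * tree$edge.length[e]))
  }
  stats::setNames(val[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Simulate a trait under a regime-painted OU process
#'
#' Exact Gaussian transition sampling per painted branch segment: over a
#' segment of duration `dt` in regime with optimum `theta`,
#' `y -> theta + (y - theta) e^(-alpha dt) + N(0, vy (1 - e^(-2 alpha dt)))`
#' with stationary variance `vy = sigma2 / (2 alpha)`; `alpha = 0` reduces
#' to Brownian motion. A direct-effect covariate is added at the tips as
#' `b * x`.
#'
#' @param tree `phylo` tree.
#' @param history `simmap` covering every branch (true or sampled).
#' @param ou_true list with `alpha` (1/my, >= 0), `sigma2` (trait^2/my, > 0),
#'   `theta` (named vector of optima per regime, log-cm), `b` (slope), and
#'   optionally `root` (root value; defaults to the root regime's optimum).
#' @param x named tip covariate vector (may be zero).
#' @param seed optional integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_trait_ou <- function(tree, history, ou_true, x = NULL, seed = NULL) {
  if (is.null(ou_true$alpha) || ou_true$alpha < 0)
    .stop_geom("ou_true$alpha must be >= 0")
  if (is.null(ou_true$sigma2) || ou_true$sigma2 <= 0)
    .stop_geom("ou_true$sigma2 must be > 0")
  if (!is.null(seed)) set.seed(seed)
  a <- ou_true$alpha; s2 <- ou_true$sigma2; th <- ou_true$theta
  n_all <- ape::Ntip(tree) + ape::Nnode(tree)
  val <- numeric(n_all)
  root <- ape::Ntip(tree) + 1L
  root_regime <- simmap_node_states(history)[root]
  val[root] <- if (!is.null(ou_true$root)) ou_true$root else th[[root_regime]]
  for (e in .preorder_edges(tree)) {
    y <- val[tree$edge[e, 1L]]
    m <- history$maps[[e]]
    for (k in seq_along(m)) {
      dt <- m[k]; regime <- names(m)[k]
      if (a > 0) {
        mu <- th[[regime]] + (y - th[[regime]]) * exp(-a * dt)
        v <- s2 / (2 * a) * (1 - exp(-2 * a * dt))
      } else {
        mu <- y; v <- s2 * dt
      }
      y <- stats::rnorm(1, mu, sqrt(v))
    }
    val[tree$edge[e, 2L]] <- y
  }
  y_tip <- stats::setNames(val[seq_len(ape::Ntip(tree))], tree$tip.label)
  if (!is.null(x) && !is.null(ou_true$b))
    y_tip <- y_tip + ou_true$b * x[names(y_tip)]
  y_tip
}
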