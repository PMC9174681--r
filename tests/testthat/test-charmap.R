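test_that("pruning likelihood reproduces the two-state closed form", {
  ## cherry with both tips in state 1; rates only between states 1 and 2,
  ## symmetric at q: P(stay) = (1 + exp(-2 q t)) / 2
  s <- lifestyle_states()
  q <- 0.07
  Q <- matrix(0, 3, 3, dimnames = list(s, s))
  Q[1, 2] <- q; Q[2, 1] <- q; diag(Q) <- -rowSums(Q)
  tr <- ape::read.tree(text = "(A:4,B:6);")
  tp <- indicator_priors(c(A = "cursorial", B = "cursorial"))
  stay <- function(t) (1 + exp(-2 * q * t)) / 2
  leave <- function(t) (1 - exp(-2 * q * t)) / 2
  manual <- log((stay(4) * stay(6) + leave(4) * leave(6) + 0) / 3)
  expect_equal(mk_likelihood(tr, tp, Q), manual, tolerance = 1e-12)
})

test_that("zero rates reduce the likelihood to the prior product", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tp <- rbind(A = c(0.7, 0.2, 0.1), B = c(0.5, 0.5, 0), C = c(1, 0, 0))
  colnames(tp) <- lifestyle_states()
  manual <- log(sum(rep(1 / 3, 3) * apply(tp, 2, prod)))
  expect_equal(mk_likelihood(tr, tp, matrix(0, 3, 3)), manual)
})

test_that("likelihood is invariant to child order and matches phytools", {
  tr <- simulate_tree(25, 30, seed = 41)
  h <- sim_regimes_balanced(tr, min_count = 2)
  ts <- simmap_tip_states(h)
  tp <- indicator_priors(ts)
  Q <- default_mk_rates()
  ll <- mk_likelihood(tr, tp, Q)
  rot <- ape::rotate(tr, node = 27)
  expect_equal(mk_likelihood(rot, tp, Q), ll, tolerance = 1e-10)
  tsf <- stats::setNames(factor(ts, levels = lifestyle_states()), names(ts))
  ref <- phytools::fitMk(tr, tsf, pi = rep(1 / 3, 3), fixedQ = Q)
  expect_equal(ll, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("ML rate fitting recovers the overall change rate and beats truth", {
  set.seed(77)
  tr <- simulate_tree(200, 35.78)
  s <- lifestyle_states()
  Q <- matrix(c(-0.09, 0.05, 0.04, 0.03, -0.07, 0.04, 0.02, 0.05, -0.07),
              3, 3, byrow = TRUE, dimnames = list(s, s))
  h <- simulate_lifestyles(tr, Q)
  tp <- indicator_priors(simmap_tip_states(h))
  fit <- fit_mk(tr, tp, n_starts = 2)
  off <- row(Q) != col(Q)
  expect_lt(abs(sum(fit$Q[off]) - sum(Q[off])) / sum(Q[off]), 0.5)
  expect_gte(attr(fit, "logLik"), mk_likelihood(tr, tp, Q) - 1e-6)
})

test_that("rate fitting is equivariant under state relabelling", {
  tr <- simulate_tree(40, 30, seed = 43)
  h <- sim_regimes_balanced(tr, min_count = 5)
  tp <- indicator_priors(simmap_tip_states(h))
  f1 <- fit_mk(tr, tp, n_starts = 1)
  perm <- c(2, 1, 3)                      # swap the first two states
  tp2 <- tp[, perm]; colnames(tp2) <- lifestyle_states()
  f2 <- fit_mk(tr, tp2, n_starts = 1)
  expect_equal(unname(f2$Q[perm, perm]), unname(f1$Q), tolerance = 1e-3)
})

test_that("degenerate single-state data drive rates to the lower bound", {
  tr <- simulate_tree(15, 10, seed = 44)
  tp <- indicator_priors(stats::setNames(rep("cursorial", 15), tr$tip.label))
  expect_warning(fit <- fit_mk(tr, tp, n_starts = 1), "degenerate")
  ## rates leaving the observed state are identifiable and go to the floor;
  ## rates between unobserved states are flat directions of the likelihood
  expect_lt(max(fit$Q["cursorial", c("fossorial", "scansorial")]), 1e-4)
})

test_that("map sampling is seed-deterministic and conserves durations", {
  tr <- simulate_tree(8, 25, seed = 45)
  h <- sim_regimes_balanced(tr, min_count = 1)
  tp <- indicator_priors(simmap_tip_states(h))
  mod <- mk_model(default_mk_rates())
  m1 <- sample_simmap(tr, tp, mod, n_maps = 5, seed = 9)
  m2 <- sample_simmap(tr, tp, mod, n_maps = 5, seed = 9)
  expect_identical(lapply(m1, `[[`, "maps"), lapply(m2, `[[`, "maps"))
  for (m in m1)
    expect_lt(max(abs(vapply(m$maps, sum, numeric(1)) - tr$edge.length)), 1e-9)
})

test_that("zero-rate models give constant maps", {
  tr <- simulate_tree(6, 10, seed = 46)
  tp <- indicator_priors(stats::setNames(rep("fossorial", 6), tr$tip.label))
  mod <- mk_model(matrix(0, 3, 3), root_prior = c(0, 1, 0))
  maps <- sample_simmap(tr, tp, mod, n_maps = 20, seed = 10)
  for (m in maps)
    expect_true(all(vapply(m$maps, function(seg)
      identical(names(seg), "fossorial"), logical(1))))
})

test_that("pruning maps conserves per-path state durations", {
  tr <- simulate_tree(10, 30, seed = 47)
  h <- sim_regimes_balanced(tr, min_count = 1)
  tp <- indicator_priors(simmap_tip_states(h))
  mod <- mk_model(default_mk_rates())
  maps <- sample_simmap(tr, tp, mod, n_maps = 3, seed = 11)
  expect_identical(prune_simmap(maps, tr$tip.label)[[1]]$maps, maps[[1]]$maps)
  keep <- tr$tip.label[1:5]
  pruned <- prune_simmap(maps, keep)
  ## per-tip root-to-tip time in each state is untouched by pruning
  path_durations <- function(smap, tip) {
    e <- which(smap$edge[, 2] == which(smap$tip.label == tip))
    tot <- stats::setNames(numeric(3), lifestyle_states())
    node <- which(smap$tip.label == tip)
    root <- ape::Ntip(smap) + 1L
    while (node != root) {
      e <- which(smap$edge[, 2] == node)
      seg <- smap$maps[[e]]
      for (s in names(seg)) tot[s] <- tot[s] + sum(seg[names(seg) == s])
      node <- smap$edge[e, 1]
    }
    tot
  }
  for (tip in keep)
    expect_equal(path_durations(pruned[[1]], tip),
                 path_durations(maps[[1]], tip), tolerance = 1e-8)
  ## dropping one tip of a cherry merges the two branch lengths
  tr2 <- ape::read.tree(text = "((A:2,B:2):3,C:5);")
  h2 <- simulate_lifestyles(tr2, matrix(0, 3, 3), seed = 1)
  p2 <- prune_simmap(h2, c("A", "C"))
  expect_equal(sort(unname(p2$edge.length)), c(5, 5))
  expect_error(prune_simmap(maps, c("nope")), "unknown species")
})

test_that("tip renaming is reversible and guards against collisions", {
  tr <- simulate_tree(5, 10, seed = 48)
  r1 <- rename_tip(tr, "sp001", "P_cuvieri")
  expect_true("P_cuvieri" %in% r1$tip.label)
  expect_identical(rename_tip(r1, "P_cuvieri", "sp001")$tip.label,
                   tr$tip.label)
  expect_error(rename_tip(tr, "sp001", "sp002"), "already present")
  expect_error(rename_tip(tr, "ghost", "x"), "not present")
  expect_true(grepl("P_cuvieri", ape::write.tree(r1)))
})

test_that("consensus painting takes parent-node states with ordered tie-break", {
  tr <- simulate_tree(7, 20, seed = 49)
  h <- sim_regimes_balanced(tr, min_count = 1)
  p1 <- consensus_painting(list(h, h, h))
  expect_identical(p1$node_state, simmap_node_states(h))
  expect_identical(p1$branch_regime, p1$node_state[tr$edge[, 1]])
  expect_true(all(abs(rowSums(p1$support) - 1) < 1e-12))
  ## engineered 50/50 tie at the root
  h2 <- h
  for (e in which(tr$edge[, 1] == ape::Ntip(tr) + 1L))
    h2$maps[[e]] <- stats::setNames(sum(h2$maps[[e]]), "scansorial")
  hx <- h
  for (e in which(tr$edge[, 1] == ape::Ntip(tr) + 1L))
    hx$maps[[e]] <- stats::setNames(sum(hx$maps[[e]]), "cursorial")
  expect_warning(ptie <- consensus_painting(list(h2, hx)), "tie")
  expect_identical(ptie$node_state[ape::Ntip(tr) + 1L], "cursorial")
})
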