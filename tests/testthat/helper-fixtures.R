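## shared fixture builders; everything is generated in code at test time

indicator_priors <- function(tip_states, states = lifestyle_states()) {
  m <- t(vapply(tip_states, function(s) as.numeric(states == s),
                numeric(length(states))))
  dimnames(m) <- list(names(tip_states), states)
  m
}

## true history collapsed to one regime per branch (parent-node painting),
## plus a branch-constant history consistent with that painting
painting_and_history <- function(history) {
  paint <- consensus_painting(history)
  ph <- history
  for (e in seq_along(ph$maps))
    ph$maps[[e]] <- stats::setNames(sum(ph$maps[[e]]), paint$branch_regime[e])
  list(painting = paint, history = ph)
}

## lifestyle history conditioned on every regime reaching min_count tips
sim_regimes_balanced <- function(tree, mk_rates = default_mk_rates(),
                                 min_count = 8) {
  repeat {
    h <- simulate_lifestyles(tree, mk_rates)
    counts <- table(factor(simmap_tip_states(h), levels = lifestyle_states()))
    if (all(counts >= min_count)) return(h)
  }
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

default_ou_truth <- function() {
  list(alpha = log(2) / 2, sigma2 = 2 * (log(2) / 2) * 0.02,
       theta = c(cursorial = 0.38, fossorial = 0.30, scansorial = 0.59),
       b = 1)
}
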