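#' @title Eight-state IP3 receptor subunit scheme
#'
#' @description Each IP3R channel is a cluster of `n_subunits` identical,
#' independent subunits. A subunit carries one IP3 site, one activating
#' Ca site and one inhibitory Ca site, giving eight states encoded as the
#' integer `4*i + 2*j + k` with `i` = IP3 bound, `j` = activating Ca bound,
#' `k` = inhibitory Ca bound. The subunit is *active* in state 6 (IP3 and
#' activating Ca bound, inhibitory site free) and the channel conducts when
#' all of its subunits are active. Binding rates are linear in the local
#' IP3 and Ca concentrations; the IP3 site kinetics depend on the state of
#' the inhibitory site (and vice versa), which produces the characteristic
#' bell-shaped steady-state open probability in Ca.
#'
#' @name ip3r
NULL

# index of the conducting (active) subunit state
IP3R_ACTIVE_STATE <- 6L

# per-state transition table: for each of the 8 states, the 3 reachable
# states (toggle IP3 site, toggle activating site, toggle inhibitory site)
# and the corresponding rates given (ca, ip3).
ip3r_transition_table <- function(ca, ip3, params) {
  s <- 0:7
  i <- s %/% 4L
  j <- (s %/% 2L) %% 2L
  k <- s %% 2L
  b1 <- params$ip3r_a1 * params$ip3r_d1
  b2 <- params$ip3r_a2 * params$ip3r_d2
  b3 <- params$ip3r_a3 * params$ip3r_d3
  b4 <- params$ip3r_a4 * params$ip3r_d4
  b5 <- params$ip3r_a5 * params$ip3r_d5
  r_ip3 <- ifelse(i == 0L,
                  ip3 * ifelse(k == 0L, params$ip3r_a1, params$ip3r_a3),
                  ifelse(k == 0L, b1, b3))
  r_act <- ifelse(j == 0L, ca * params$ip3r_a5, b5)
  r_inh <- ifelse(k == 0L,
                  ca * ifelse(i == 1L, params$ip3r_a2, params$ip3r_a4),
                  ifelse(i == 1L, b2, b4))
  list(target = cbind(s + ifelse(i == 0L, 4L, -4L),
                      s + ifelse(j == 0L, 2L, -2L),
                      s + ifelse(k == 0L, 1L, -1L)),
       rate = cbind(r_ip3, r_act, r_inh))
}

#' Infinitesimal generator of the subunit Markov scheme
#'
#' @param ca Cytosolic Ca concentration, uM.
#' @param ip3 IP3 concentration, uM.
#' @param params An `astro_params` object.
#' @return 8x8 rate matrix `Q` with `Q[s, s']` the transition rate from
#'   state `s` to `s'` (states 0..7 in row/column order) and rows summing
#'   to zero.
#' @export
ip3r_rate_matrix <- function(ca, ip3, params) {
  tab <- ip3r_transition_table(ca, ip3, params)
  Q <- matrix(0, 8, 8, dimnames = list(0:7, 0:7))
  for (s in 1:8) {
    for (m in 1:3) Q[s, tab$target[s, m] + 1L] <- tab$rate[s, m]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the subunit scheme at clamped inputs
#'
#' Solves the null space of the transposed generator (the balance
#' equations) with the normalization constraint.
#'
#' @inheritParams ip3r_rate_matrix
#' @return Numeric vector of length 8 summing to 1; element `s + 1` is the
#'   stationary probability of subunit state `s`.
#' @export
ip3r_stationary <- function(ca, ip3, params) {
  Q <- ip3r_rate_matrix(ca, ip3, params)
  A <- rbind(t(Q), rep(1, 8))
  b <- c(rep(0, 8), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

#' Mean-field open probability of a channel
#'
#' @inheritParams ip3r_rate_matrix
#' @return Probability that all subunits of a channel are simultaneously
#'   active at the stationary distribution.
#' @export
ip3r_open_probability <- function(ca, ip3, params) {
  ip3r_stationary(ca, ip3, params)[IP3R_ACTIVE_STATE + 1L]^params$n_subunits
}

#' Advance the stochastic channel states by one step
#'
#' Each subunit advances independently by at most one Markov transition
#' drawn from its current state's exit rates (linear in the local Ca and
#' IP3). All continuous fields of the state are untouched. Uses the current
#' R random-number stream.
#'
#' @param state A `compartment_state` (see [compartment_state()]).
#' @param params An `astro_params` object.
#' @param dt Time step, s. Per-step transition probabilities must stay
#'   small; any subunit exit probability above 0.1 signals that `dt` is too
#'   large for the given rates and is an error.
#' @return The state with updated `subunits`.
#' @export
ip3r_transition_step <- function(state, params, dt) {
  stopifnot(inherits(state, "compartment_state"), dt > 0)
  sub <- state$subunits
  tab <- ip3r_transition_table(state$ca_cyt, state$ip3, params)
  idx <- sub + 1L
  r1 <- tab$rate[idx, 1] * dt
  r2 <- tab$rate[idx, 2] * dt
  r3 <- tab$rate[idx, 3] * dt
  ptot <- r1 + r2 + r3
  if (any(ptot > 0.1))
    stop("per-step transition probability exceeds 0.1; dt too large for the gating rates")
  u <- stats::runif(length(sub))
  new <- sub
  take1 <- u < r1
  take2 <- !take1 & u < r1 + r2
  take3 <- !take1 & !take2 & u < ptot
  new[take1] <- tab$target[idx, 1][take1]
  new[take2] <- tab$target[idx, 2][take2]
  new[take3] <- tab$target[idx, 3][take3]
  state$subunits <- new
  state
}

#' Number of open (conducting) channels
#'
#' @param subunits Integer vector of subunit states, grouped by channel.
#' @param params An `astro_params` object.
#' @return Count of channels whose subunits are all active.
#' @export
n_open_channels <- function(subunits, params) {
  m <- matrix(subunits == IP3R_ACTIVE_STATE,
              nrow = params$n_subunits)
  sum(colSums(m) == params$n_subunits)
}

#' Sample subunit states from the stationary distribution
#'
#' @inheritParams ip3r_rate_matrix
#' @param params An `astro_params` object.
#' @return Integer vector of length `n_ip3r * n_subunits` (uses the current
#'   R random-number stream).
#' @export
sample_ip3r_states <- function(ca, ip3, params) {
  pi <- ip3r_stationary(ca, ip3, params)
  n <- params$n_ip3r * params$n_subunits
  sample(0:7, n, replace = TRUE, prob = pi)
}
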