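# Stochastic gene-expression module: a two-state (telegraph) switching
# model per gene copy plus mRNA birth-death, advanced over one exchange
# window by tau-leaping with rates frozen at the window start.  Gene-copy
# switching is Bernoulli per copy (at most one flip per copy per window);
# mRNA births and deaths are Poisson, deaths truncated at the current count.

AVOGADRO <- 6.02214076e23

#' Convert molecule counts to concentration and back
#'
#' `mpc_to_nM` maps molecules-per-cell to nM given the compartment volume;
#' `nM_to_mpc` is the inverse, rounding to the nearest integer when
#' `integer = TRUE` (stochastic state) and exact otherwise (reporting).
#'
#' @param count molecules per cell (mpc).
#' @param volume compartment volume in liters.
#' @param conc concentration in nM.
#' @param integer round the inverse to an integer count.
#' @return numeric vector.
#' @export
mpc_to_nM <- function(count, volume) {
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  count / (AVOGADRO * volume) * 1e9
}

#' @rdname mpc_to_nM
#' @export
nM_to_mpc <- function(conc, volume, integer = TRUE) {
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  x <- conc * AVOGADRO * volume / 1e9
  if (integer) round(x) else x
}

#' Transcription-rate regulation factors for one gene
#'
#' Activators combine as an OR-gate saturating sum,
#' `u = sum((x/B)^A) / (1 + sum((x/B)^A))` over activator entries (0 with
#' no activators); repressors multiply, `w = prod(1 / (1 + (x/B)^A))`.
#' The effective transcription rate per active gene copy is
#' `(k_const + k_max * u) * w`, which reduces to the constitutive rate with
#' no regulators and saturates at `k_const + k_max`.
#'
#' @param conc regulator concentrations (nM) at window start.
#' @param hill unsigned Hill coefficients.
#' @param halfmax half-maximal concentrations (nM).
#' @param role `"activator"` or `"repressor"` per entry.
#' @return list with `u` (activation) and `w` (repression) multipliers.
#' @export
regulation_factor <- function(conc, hill, halfmax, role) {
  stopifnot(length(conc) == length(hill), length(hill) == length(halfmax),
            length(role) == length(conc))
  act <- role == "activator"
  u <- if (any(act)) {
    s <- sum((conc[act] / halfmax[act])^hill[act])
    s / (1 + s)
  } else 0
  w <- if (any(!act)) prod(1 / (1 + (conc[!act] / halfmax[!act])^hill[!act])) else 1
  list(u = u, w = w)
}

#' Effective per-active-copy transcription rates for all genes
#'
#' @param genes gene bundle data frame from a `compiled_model`.
#' @param regulation long-form regulation entries (gene, regulator, hill,
#'   halfmax, role).
#' @param state named species state vector (nM).
#' @return numeric vector of rates (mpc/s per active copy), one per gene.
#' @keywords internal
transcription_rates <- function(genes, regulation, state) {
  rates <- genes$k_transcription_const
  if (nrow(regulation)) {
    for (g in unique(regulation$gene)) {
      i <- match(g, genes$gene)
      if (is.na(i)) next
      e <- regulation[regulation$gene == g, ]
      f <- regulation_factor(unname(state[e$regulator]), e$hill, e$halfmax, e$role)
      rates[i] <- (genes$k_transcription_const[i] +
                     genes$k_transcription_max[i] * f$u) * f$w
    }
  }
  rates
}

#' Advance gene on/off states over one window
#'
#' Each copy evolves as an independent two-state Markov chain; the window
#' update samples the copy's end state from the exact two-state propagator:
#' an inactive copy is active at the end of the window with probability
#' `f * (1 - exp(-(k_act + k_inact) * dt))` and an active copy inactive
#' with probability `(1 - f) * (1 - exp(-(k_act + k_inact) * dt))`, where
#' `f = k_act / (k_act + k_inact)`.  End-state sampling keeps the telegraph
#' stationary occupancy exact for any window length (a single
#' switch-probability leap would bias it at asymmetric rates).
#'
#' @param active integer vector of active copies per gene.
#' @param copies integer vector of total copies per gene.
#' @param k_act,k_inact switching rates (1/s) per gene.
#' @param dt window length in seconds.
#' @return updated integer vector of active copies.
#' @export
step_gene_states <- function(active, copies, k_act, k_inact, dt) {
  stopifnot(dt >= 0, all(active >= 0), all(active <= copies))
  if (dt == 0) return(active)
  n <- length(active)
  ksum <- k_act + k_inact
  relax <- ifelse(ksum > 0, 1 - exp(-ksum * dt), 0)
  f <- ifelse(ksum > 0, k_act / ksum, 0)
  p_on <- f * relax          # inactive -> active over the window
  p_off <- (1 - f) * relax   # active -> inactive over the window
  act <- stats::rbinom(n, copies - active, p_on)
  deact <- stats::rbinom(n, active, p_off)
  active + act - deact
}

#' Advance mRNA copy numbers over one window
#'
#' Births are Poisson with mean `active * rate_per_copy * dt`; deaths are
#' Poisson with mean `k_deg * mrna * dt`, truncated at the current count so
#' counts never go negative.
#'
#' @param mrna integer vector of mRNA counts (mpc).
#' @param active integer vector of active copies.
#' @param rate_per_copy effective transcription rates (mpc/s per active copy).
#' @param k_deg mRNA degradation rates (1/s).
#' @param dt window length in seconds.
#' @return updated integer vector of counts.
#' @export
step_mrna_counts <- function(mrna, active, rate_per_copy, k_deg, dt) {
  stopifnot(dt >= 0, all(mrna >= 0))
  if (dt == 0) return(mrna)
  n <- length(mrna)
  births <- stats::rpois(n, active * rate_per_copy * dt)
  deaths <- pmin(stats::rpois(n, k_deg * mrna * dt), mrna)
  mrna + births - deaths
}

#' Draw an initial stochastic gene-expression state
#'
#' Active copies are Bernoulli per copy at the telegraph stationary
#' occupancy `k_act / (k_act + k_off)`; initial mRNA counts are Poisson
#' around the omics means, so every simulated cell starts from a different
#' expression state as in burst-like expression.
#'
#' @param genes gene bundle data frame.
#' @return list with integer vectors `active` and `mrna`.
#' @export
init_gene_state <- function(genes) {
  list(active = stats::rbinom(nrow(genes), genes$gene_copy_number, genes$f_active),
       mrna = stats::rpois(nrow(genes), genes$mrna_mpc))
}
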