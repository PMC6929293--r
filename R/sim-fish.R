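#' FISH simulation specification
#'
#' Parameters of the synthetic FISH experiment: per-group true gain fraction,
#' cohort shape, and the two imaging artefact rates. `probe_dropout` is the
#' per-probe probability that hybridisation fails in a cell and the probe
#' yields no signal (e.g. a sectioned or partially imaged nucleus);
#' `spurious_signal` is the per-probe probability of one extra apparent
#' copy. Both artefacts are applied independently of the cell's true gain
#' state, so the analysability rule removes affected cells from the
#' denominator without biasing the mosaicism estimator.
#'
#' @param pi_gain True fraction of cells carrying a unique SNCA gain.
#' @param cells_per_case Cells scored per case.
#' @param n_cases Number of cases in the group.
#' @param probe_dropout Per-copy dropout probability.
#' @param spurious_signal Per-probe extra-signal probability.
#' @param group Group label carried into the output.
#' @param region,cell_type Labels carried into the output.
#' @return A list of class `fish_sim_spec`.
#' @export
fish_sim_spec <- function(pi_gain, cells_per_case = 100, n_cases = 10,
                          probe_dropout = 0, spurious_signal = 0,
                          group = "group", region = "CC",
                          cell_type = "neuron") {
  probs <- c(pi_gain, probe_dropout, spurious_signal)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  structure(
    list(pi_gain = pi_gain, cells_per_case = cells_per_case,
         n_cases = n_cases, probe_dropout = probe_dropout,
         spurious_signal = spurious_signal, group = group, region = region,
         cell_type = cell_type),
    class = "fish_sim_spec"
  )
}

#' Simulate FISH count tables with probe artefacts
#'
#' Per cell the true SNCA copy number is 3 with probability `pi_gain`, else
#' 2; the reference probe is always 2 copies. Observed signal counts apply
#' per-probe dropout and spurious extra signals. Cells violating the
#' analysability rule — fewer than 2 observed copies of either probe, or
#' more than 2 copies of both — are excluded from the denominator, mirroring
#' how sectioning artefacts are handled when scoring slides. A unique gain is
#' then an analysable cell with more than 2 SNCA signals and exactly 2
#' reference signals.
#'
#' @param spec A [fish_sim_spec()].
#' @param seed Optional seed.
#' @return A tibble with one row per case: `case_id`, `group`, `region`,
#'   `cell_type`, `n_cells`, `n_analysed`, `n_gain`.
#' @export
simulate_fish_counts <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fish_sim_spec"))
  with_seed_or_stream(seed, {
    purrr::map_dfr(seq_len(spec$n_cases), function(case) {
      m <- spec$cells_per_case
      true_snca <- ifelse(runif(m) < spec$pi_gain, 3L, 2L)
      true_ref <- rep(2L, m)
      obs_snca <- true_snca * rbinom(m, 1, 1 - spec$probe_dropout) +
        rbinom(m, 1, spec$spurious_signal)
      obs_ref <- true_ref * rbinom(m, 1, 1 - spec$probe_dropout) +
        rbinom(m, 1, spec$spurious_signal)
      analysable <- obs_snca >= 2 & obs_ref >= 2 & !(obs_snca > 2 & obs_ref > 2)
      gain <- analysable & obs_snca > 2 & obs_ref == 2
      tibble(
        case_id = sprintf("%s_case%02d", spec$group, case),
        group = spec$group,
        region = spec$region,
        cell_type = spec$cell_type,
        n_cells = m,
        n_analysed = sum(analysable),
        n_gain = sum(gain)
      )
    })
  })
}
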