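## Synthetic multi-study genotype-count datasets with the statistical
## structure the analysis pipeline assumes.

#' Define a simulation scenario
#'
#' Describes a multi-study case-control genotyping study to be simulated by
#' [simulate_dataset()]. The defaults emulate the structure of a typical
#' Asian ARMS2-A69S meta-analysis: six studies, control risk-allele
#' frequencies around 0.33-0.39, a stronger allelic effect in neovascular AMD
#' (OR 3.09) than in PCV (OR 2.13), with two studies lacking a neovascular
#' AMD arm, and per-group sample sizes matching the real studies.
#'
#' All per-study arguments are recycled to `n_studies`. A group size of 0
#' omits that group from the study.
#'
#' @param n_studies Number of studies.
#' @param control_freq Per-study control risk-allele frequency in (0, 1).
#' @param n_neovascular_amd,n_pcv,n_control Per-study group sizes (subjects).
#' @param or_neovascular_amd,or_pcv True allelic odds ratio per subtype.
#' @param tau Between-study standard deviation of the log allelic OR
#'   (log-normal spread); 0 gives a common effect.
#' @param hwe_in_controls If `TRUE` (default) control genotypes follow exact
#'   Hardy-Weinberg proportions; if `FALSE` they are perturbed by an
#'   inbreeding coefficient of 0.1 (heterozygote deficit), useful for
#'   exercising the HWE test's power.
#' @param seed Default random seed used by [simulate_dataset()].
#' @return A validated list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_studies = 6,
                                control_freq = c(0.35, 0.39, 0.33, 0.39,
                                                 0.33, 0.38),
                                n_neovascular_amd = c(0, 0, 100, 405, 50, 181),
                                n_pcv = c(109, 72, 100, 509, 60, 198),
                                n_control = c(85, 93, 189, 1336, 138, 203),
                                or_neovascular_amd = 3.09,
                                or_pcv = 2.13,
                                tau = 0,
                                hwe_in_controls = TRUE,
                                seed = 1L) {
  stopifnot(n_studies >= 1, tau >= 0,
            all(control_freq > 0), all(control_freq < 1),
            or_neovascular_amd > 0, or_pcv > 0,
            all(n_neovascular_amd >= 0), all(n_pcv >= 0), all(n_control >= 0))
  sc <- list(
    n_studies = as.integer(n_studies),
    control_freq = rep_len(control_freq, n_studies),
    n_neovascular_amd = rep_len(as.integer(n_neovascular_amd), n_studies),
    n_pcv = rep_len(as.integer(n_pcv), n_studies),
    n_control = rep_len(as.integer(n_control), n_studies),
    or_neovascular_amd = or_neovascular_amd,
    or_pcv = or_pcv,
    tau = tau,
    hwe_in_controls = isTRUE(hwe_in_controls),
    seed = as.integer(seed)
  )
  structure(sc, class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(paste0("Simulation scenario: %d studies, control freq %s,\n",
                     "  allelic OR %.2f (neovascular AMD) / %.2f (PCV), ",
                     "tau = %g, seed = %d\n"),
              x$n_studies,
              paste(sprintf("%.2f", x$control_freq), collapse = "/"),
              x$or_neovascular_amd, x$or_pcv, x$tau, x$seed))
  invisible(x)
}

## HWE genotype probabilities (gg, gt, tt) at risk-allele frequency p,
## optionally perturbed by an inbreeding coefficient f (heterozygote deficit).
hwe_probs <- function(p, f = 0) {
  q <- 1 - p
  c(gg = q^2 + f * p * q, gt = 2 * p * q * (1 - f), tt = p^2 + f * p * q)
}

## Case risk-allele frequency implied by an allelic OR and the control
## frequency, on the per-allele odds scale.
case_freq_from_or <- function(or, p_control) {
  odds <- or * p_control / (1 - p_control)
  odds / (1 + odds)
}

#' Simulate a multi-study genotype-count dataset
#'
#' For each study, control genotype probabilities are Hardy-Weinberg
#' proportions at the study's control risk-allele frequency; each case
#' group's allele frequency is derived from the subtype's true allelic odds
#' ratio via the odds transformation
#' \eqn{p_{case} = OR \cdot odds_{ctrl} / (1 + OR \cdot odds_{ctrl})}
#' (so cases are also in HWE, consistent with a multiplicative allelic
#' model); genotype counts are drawn multinomially. When `tau > 0` each
#' study's log OR is drawn from a normal distribution around the scenario
#' value before the transformation.
#'
#' Randomness is consumed through per-study sub-streams seeded
#' deterministically from the global seed, so a fixed seed gives
#' byte-identical output and appending a study leaves earlier studies'
#' draws unchanged.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed; defaults to the scenario's.
#' @return An `snp_dataset` with study ids `sim_01`, `sim_02`, ...
#' @examples
#' ds <- simulate_dataset(simulation_scenario(seed = 42))
#' snp_meta(ds, "pcv")
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  seed <- as.integer(seed)
  f <- if (scenario$hwe_in_controls) 0 else 0.1
  rows <- vector("list", scenario$n_studies)
  for (i in seq_len(scenario$n_studies)) {
    ## per-study sub-stream: earlier studies unaffected by later ones
    set.seed((seed + 1009L * i) %% .Machine$integer.max)
    p_ctl <- scenario$control_freq[i]
    draw <- function(n, probs) {
      if (n == 0) return(NULL)
      as.integer(stats::rmultinom(1, n, probs))
    }
    log_or_amd <- log(scenario$or_neovascular_amd) +
      if (scenario$tau > 0) stats::rnorm(1, 0, scenario$tau) else 0
    log_or_pcv <- log(scenario$or_pcv) +
      if (scenario$tau > 0) stats::rnorm(1, 0, scenario$tau) else 0
    groups <- list(
      neovascular_amd = draw(scenario$n_neovascular_amd[i],
                             hwe_probs(case_freq_from_or(exp(log_or_amd),
                                                         p_ctl))),
      pcv = draw(scenario$n_pcv[i],
                 hwe_probs(case_freq_from_or(exp(log_or_pcv), p_ctl))),
      control = draw(scenario$n_control[i], hwe_probs(p_ctl, f))
    )
    groups <- Filter(Negate(is.null), groups)
    rows[[i]] <- data.frame(
      study_id = sprintf("sim_%02d", i),
      year = 2000L + i,
      ethnicity = "simulated",
      phenotype = names(groups),
      n_gg = vapply(groups, `[`, integer(1), 1),
      n_gt = vapply(groups, `[`, integer(1), 2),
      n_tt = vapply(groups, `[`, integer(1), 3),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  as_snp_dataset(do.call(rbind, rows))
}
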