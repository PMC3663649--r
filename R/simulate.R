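#' Default generator settings for the CSP titration experiments
#'
#' Conditions emulating the three CSP titrations of a weak peptide/DNA
#' binder observed at 0.3 mM receptor: a methylated-peptide titration to
#' 30 mM, a short-duplex DNA titration to 1.2 mM, and an MLA-peptide
#' titration to 4 mM. Receptor concentration is the stated sample condition;
#' the schedules and noise levels are documented assumptions (stock
#' concentrations limit the reachable ligand excess). Saturation CSPs are a
#' fixed, plausible amide set spanning 0.05-0.25 ppm.
#'
#' @param experiment `"csp_peptide"`, `"csp_dna"` or `"csp_mla"`.
#' @return list with `experiment`, `kd` (mol/L), `receptor_total` (mol/L),
#'   `schedule` (mol/L, includes 0), `csp_max` (named, ppm), `noise_sd`
#'   (ppm), `x_weight`, and `split_angle_deg` (how a combined CSP is split
#'   between 1H and 15N when emitting peak lists).
#' @export
csp_defaults <- function(experiment = c("csp_peptide", "csp_dna",
                                        "csp_mla")) {
  experiment <- match.arg(experiment)
  base <- list(
    experiment = experiment,
    receptor_total = 0.3e-3,
    csp_max = c(`18` = 0.22, `21` = 0.25, `44` = 0.18, `46` = 0.12,
                `49` = 0.08, `74` = 0.05),
    x_weight = 0.2,
    split_angle_deg = 35
  )
  pars <- switch(experiment,
    csp_peptide = list(kd = 17e-3,
                       schedule = c(0, 0.5, 1, 2, 4, 8, 16, 30) * 1e-3,
                       noise_sd = 0.004),
    csp_dna = list(kd = 150e-6,
                   schedule = c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.2) * 1e-3,
                   noise_sd = 0.004),
    csp_mla = list(kd = 11e-3,
                   schedule = c(0, 0.25, 0.5, 1, 2, 4) * 1e-3,
                   noise_sd = 0.003))
  c(base, pars)
}

#' Simulate a CSP titration dataset
#'
#' Generates per-residue combined-CSP curves from the depletion-corrected
#' fast-exchange model, \eqn{\Delta\delta_r(i) = \Delta\delta_{max,r}
#' [PL]_i/P_0 + \epsilon}, with Gaussian noise of sd `noise_sd` (the free
#' point stays exactly zero), and the matching synthetic Sparky-style peak
#' lists: each residue's perturbation is split between the 1H and 15N
#' dimensions at a fixed angle so that the combined CSP with weight
#' `x_weight` reproduces the curve value.
#'
#' Identical `(spec, seed)` give identical output; different seeds share the
#' identical noiseless means.
#'
#' @param spec generator spec from [csp_defaults()] (fields may be
#'   overridden).
#' @param seed integer RNG seed.
#' @return list with `curves` (data frame `residue_id`, `point_index`,
#'   `ligand_total`, `csp`), `peaks` (list of peak-list data frames, one per
#'   titration point), `spec`, `seed`.
#' @export
simulate_csp_titration <- function(spec = csp_defaults(), seed = 1L) {
  stopifnot(spec$schedule[1] == 0, !is.unsorted(spec$schedule))
  check_positive(spec$noise_sd, "noise_sd", allow_zero = TRUE)
  set.seed(seed)
  fb <- solve_1to1_complex(spec$receptor_total, spec$schedule, spec$kd) /
    spec$receptor_total
  resid <- names(spec$csp_max)
  curves <- expand.grid(residue_id = resid,
                        point_index = seq_along(spec$schedule) - 1L,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  curves$ligand_total <- spec$schedule[curves$point_index + 1L]
  mean_csp <- spec$csp_max[curves$residue_id] * fb[curves$point_index + 1L]
  noise <- stats::rnorm(nrow(curves), sd = spec$noise_sd)
  curves$csp <- pmax(mean_csp + noise, 0)
  curves$csp[curves$point_index == 0L] <- 0

  # synthetic free-state amide shifts: fixed plausible values per residue
  free_h <- 7.5 + 0.25 * seq_along(resid)
  free_x <- 112 + 2.5 * seq_along(resid)
  names(free_h) <- names(free_x) <- resid
  ang <- spec$split_angle_deg * pi / 180
  peaks <- lapply(seq_along(spec$schedule), function(i) {
    csp_i <- curves$csp[curves$point_index == i - 1L]
    names(csp_i) <- curves$residue_id[curves$point_index == i - 1L]
    data.frame(
      residue_id = as.integer(resid),
      residue_name = "GLY",
      shift_h = free_h[resid] + csp_i[resid] * cos(ang),
      shift_x = free_x[resid] + csp_i[resid] * sin(ang) / spec$x_weight,
      row.names = NULL
    )
  })
  list(curves = curves, peaks = peaks, spec = spec, seed = seed)
}

#' Default generator settings for the nucleosome line-shape titration
#'
#' Emulates a methyl-TROSY titration of a 116 uM two-site receptor
#' (nucleosome) with a reader domain to 2.7 molar equivalents in the
#' intermediate-fast exchange regime: microscopic Kd 1.5 uM, koff 500 1/s,
#' bound-state shift +0.35 ppm in 13C at a 900 MHz field, R2 8 (mobile free
#' tail) and 40 1/s (rigidified bound state), 2% multiplicative peak-height
#' noise. Ratios beyond the stoichiometric point are included so that the
#' titration constrains both populations and the saturated position.
#'
#' @return list with `kd`, `koff` (1/s), `receptor_total` (mol/L), `ratios`,
#'   `offsets_ppm` (free, bound), `r2` (1/s), `noise_frac`, `acquisition`.
#' @export
exchange_defaults <- function() {
  list(
    kd = 1.5e-6, koff = 500, receptor_total = 116e-6,
    ratios = c(0, 0.5, 1, 1.8, 2.7),
    offsets_ppm = c(21.3, 21.65), r2 = c(8, 40),
    noise_frac = 0.02,
    acquisition = acquisition_params(field_mhz = 900, nucleus = "13C",
                                     sw_ppm = 2, n_points = 512L,
                                     carrier_ppm = 21.475, lb_hz = 2)
  )
}

#' Simulate an exchange line-shape titration
#'
#' Simulates one trace per molar ratio with [titration_lineshapes()] and
#' applies multiplicative Gaussian noise, point-wise
#' \eqn{I (1 + \epsilon)} with sd `noise_frac`.
#'
#' @param spec generator spec from [exchange_defaults()].
#' @param seed integer RNG seed.
#' @return list with `traces` (list of `"spectrum_trace"`), `ratios`,
#'   `receptor_total`, `manifest` (data frame `ratio`,
#'   `receptor_total_M`), `spec`, `seed`.
#' @export
simulate_exchange_titration <- function(spec = exchange_defaults(),
                                        seed = 1L) {
  check_positive(spec$noise_frac, "noise_frac", allow_zero = TRUE)
  set.seed(seed)
  traces <- titration_lineshapes(spec$kd, spec$koff, spec$receptor_total,
                                 spec$ratios, spec$offsets_ppm, spec$r2,
                                 spec$acquisition)
  traces <- lapply(traces, function(tr) {
    tr$intensity <- tr$intensity *
      (1 + stats::rnorm(nrow(tr), sd = spec$noise_frac))
    tr
  })
  list(traces = traces, ratios = spec$ratios,
       receptor_total = spec$receptor_total,
       manifest = data.frame(ratio = spec$ratios,
                             receptor_total_M = spec$receptor_total),
       spec = spec, seed = seed)
}

#' Default generator settings for the EMSA titration
#'
#' Emulates a gel-shift titration of 0.375 uM nucleosome (3 pmol in 8 uL)
#' with 0, 0.5, 1, 2 and 3 molar equivalents of binder at microscopic Kd
#' 0.5 uM: species fractions from the two-equivalent-site binomial model,
#' 5% truncated-at-zero Gaussian fraction noise, and a uniform 0.8-1.2
#' per-lane loading factor.
#'
#' @return list with `kd`, `receptor_total` (mol/L), `equivalents`,
#'   `noise_sd` (fraction units), `loading_range`.
#' @export
emsa_defaults <- function() {
  list(kd = 0.5e-6, receptor_total = amount_to_molar(3, 8),
       equivalents = c(0, 0.5, 1, 2, 3),
       noise_sd = 0.05, loading_range = c(0.8, 1.2))
}

#' Simulate an EMSA lane-density table
#'
#' Species fractions from [solve_two_site()] at each equivalents step are
#' perturbed by truncated-at-zero Gaussian noise and rescaled by a random
#' per-lane loading factor, emulating densitometry of an intercalator-stained
#' native gel.
#'
#' @param spec generator spec from [emsa_defaults()].
#' @param seed integer RNG seed.
#' @return data frame with columns `lane_id`, `equivalents`, `density_free`,
#'   `density_b1`, `density_b2`; the receptor concentration, spec and seed
#'   are attached as attributes.
#' @export
simulate_emsa_titration <- function(spec = emsa_defaults(), seed = 1L) {
  check_positive(spec$noise_sd, "noise_sd", allow_zero = TRUE)
  set.seed(seed)
  ms <- solve_two_site(spec$receptor_total,
                       spec$equivalents * spec$receptor_total, spec$kd)
  f <- cbind(ms$f0, ms$f1, ms$f2)
  noisy <- pmax(f + matrix(stats::rnorm(length(f), sd = spec$noise_sd),
                           ncol = 3), 0)
  loading <- stats::runif(nrow(f), spec$loading_range[1],
                          spec$loading_range[2])
  d <- 100 * noisy * loading
  out <- data.frame(lane_id = seq_len(nrow(f)),
                    equivalents = spec$equivalents,
                    density_free = d[, 1], density_b1 = d[, 2],
                    density_b2 = d[, 3])
  attr(out, "receptor_total") <- spec$receptor_total
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}
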