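#' Combined chemical shift perturbation
#'
#' Combines the proton and heteronucleus shift changes of a residue into a
#' single scalar, \eqn{\Delta\delta = \sqrt{\Delta\delta_H^2 +
#' (w\,\Delta\delta_X)^2}}, with the conventional downweighting `w` of the
#' heteronucleus. The default weight 0.2 is the usual amide 15N scaling;
#' use [csp_weight()] to pick the 13C variant (0.3).
#'
#' @param delta_h proton shift change, ppm (vectorised).
#' @param delta_x heteronucleus (15N or 13C) shift change, ppm.
#' @param x_weight heteronucleus weight, dimensionless, > 0.
#' @return combined CSP in ppm; invariant to the sign of either change.
#' @examples
#' combined_csp(0.03, 0.2, 0.2)  # 0.05
#' @export
combined_csp <- function(delta_h, delta_x, x_weight = 0.2) {
  check_positive(x_weight, "x_weight")
  sqrt(delta_h^2 + (x_weight * delta_x)^2)
}

#' Default heteronucleus CSP weight
#'
#' @param nucleus `"15N"` or `"13C"`.
#' @return conventional weight: 0.2 for 15N, 0.3 for 13C.
#' @export
csp_weight <- function(nucleus = c("15N", "13C")) {
  nucleus <- match.arg(nucleus)
  c(`15N` = 0.2, `13C` = 0.3)[[nucleus]]
}

#' Per-residue CSP between two peak lists
#'
#' Computes the combined CSP of every residue present in both the free-state
#' and the bound-point peak list (matched by `residue_id`). Both inputs are
#' peak-list data frames as returned by [read_peak_list()].
#'
#' @param free peak list of the free state.
#' @param bound_point peak list at one titration point.
#' @param x_weight heteronucleus weight passed to [combined_csp()].
#' @return data frame with columns `residue_id`, `residue_name`, `csp`.
#' @export
compute_csp <- function(free, bound_point, x_weight = 0.2) {
  for (df in list(free, bound_point)) {
    if (!all(c("residue_id", "shift_h", "shift_x") %in% names(df))) {
      stop("peak lists need columns residue_id, shift_h, shift_x")
    }
  }
  m <- merge(free, bound_point, by = "residue_id",
             suffixes = c("_free", "_bound"))
  if (nrow(m) == 0L) {
    stop("residue mismatch: no residue_id shared between the two peak lists")
  }
  if ("residue_name_free" %in% names(m) &&
      any(m$residue_name_free != m$residue_name_bound)) {
    bad <- m$residue_id[m$residue_name_free != m$residue_name_bound]
    stop("residue mismatch: residue_id ", paste(bad, collapse = ", "),
         " has different residue names in the two peak lists")
  }
  data.frame(
    residue_id = m$residue_id,
    residue_name = if ("residue_name_free" %in% names(m))
      m$residue_name_free else NA_character_,
    csp = combined_csp(m$shift_h_bound - m$shift_h_free,
                       m$shift_x_bound - m$shift_x_free, x_weight)
  )
}

#' Significance threshold for CSPs: trimmed mean + n sigma
#'
#' The customary cutoff for calling a residue significantly perturbed:
#' the trimmed mean of all observed CSPs plus `n_sigma` standard deviations.
#' By default the standard deviation is computed on the trimmed set as well;
#' set `sigma_on = "full"` to use the untrimmed vector.
#'
#' @param csps numeric vector of CSP magnitudes, ppm; at least 3 values.
#' @param trim_fraction fraction trimmed from each tail, in \[0, 0.5).
#' @param n_sigma number of standard deviations above the trimmed mean.
#' @param sigma_on `"trimmed"` (default) or `"full"`.
#' @return threshold in ppm.
#' @examples
#' csp_threshold(c(0.01, 0.02, 0.02, 0.03, 0.5))
#' @export
csp_threshold <- function(csps, trim_fraction = 0.10, n_sigma = 2,
                          sigma_on = c("trimmed", "full")) {
  sigma_on <- match.arg(sigma_on)
  if (length(csps) < 3L) stop("need at least 3 CSP values, got ", length(csps))
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)")
  }
  s <- sort(csps)
  k <- floor(length(s) * trim_fraction)
  trimmed <- if (k > 0) s[(k + 1):(length(s) - k)] else s
  sigma <- if (sigma_on == "trimmed") stats::sd(trimmed) else stats::sd(csps)
  if (is.na(sigma)) sigma <- 0  # single surviving value
  mean(trimmed) + n_sigma * sigma
}

#' Restrict CSP curves to points below a ligand-concentration cutoff
#'
#' Drops titration points whose total ligand concentration exceeds
#' `max_ligand`; the free (zero-ligand) point is always retained. Used to fit
#' only the initial interval of a weak-binding titration.
#'
#' @param curves CSP curve data frame (columns `residue_id`, `ligand_total`,
#'   `csp`, as consumed by [fit_csp()]).
#' @param max_ligand cutoff, mol/L.
#' @return the restricted curve data frame.
#' @export
truncate_series <- function(curves, max_ligand) {
  check_positive(max_ligand, "max_ligand")
  keep <- curves$ligand_total <= max_ligand | curves$ligand_total == 0
  out <- curves[keep, , drop = FALSE]
  n_pts <- length(unique(out$ligand_total))
  if (n_pts < 3L) {
    stop("fewer than 3 titration points survive the cutoff (",
         n_pts, " left)")
  }
  rownames(out) <- NULL
  out
}
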