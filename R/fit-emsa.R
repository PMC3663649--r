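#' Species fractions from EMSA lane densities
#'
#' Normalises the integrated band densities of the free, singly bound (+1)
#' and doubly bound (+2) species in each lane to fractions. Equal detection
#' response per particle across bands is assumed (intercalator staining of
#' the same DNA in every species); an optional per-band response correction
#' divides each density by its response factor first.
#'
#' @param lanes data frame with columns `density_free`, `density_b1`,
#'   `density_b2` (one row per lane).
#' @param response optional length-3 positive vector of per-band response
#'   factors.
#' @return numeric matrix with columns `f0`, `f1`, `f2`; rows sum to 1.
#' @export
lane_fractions <- function(lanes, response = c(1, 1, 1)) {
  d <- as.matrix(lanes[, c("density_free", "density_b1", "density_b2")])
  if (any(d < 0)) stop("band densities must be >= 0")
  check_positive(response, "response")
  d <- sweep(d, 2, response, "/")
  tot <- rowSums(d)
  if (any(tot <= 0)) {
    stop("all-zero lane at row ", paste(which(tot <= 0), collapse = ", "))
  }
  out <- d / tot
  colnames(out) <- c("f0", "f1", "f2")
  out
}

#' Fit EMSA band fractions to the 2:1 binding model
#'
#' Fits the microscopic per-site \eqn{K_D} of a receptor with two equivalent
#' independent ligand sites to a titration of lane densities. For each lane,
#' total ligand is `equivalents * receptor_total`; predicted species
#' fractions come from [solve_two_site()] (binomial in the site occupancy),
#' and the residual sum of squares over observed minus predicted fractions is
#' minimised over \eqn{\log K_D}. Fitting normalised fractions rather than
#' raw densities removes lane-loading nuisance factors, so the fit is
#' invariant to a common rescaling of any lane.
#'
#' @param lanes data frame with columns `equivalents`, `density_free`,
#'   `density_b1`, `density_b2`.
#' @param receptor_total receptor (nucleosome) concentration in the lane,
#'   mol/L; see [amount_to_molar()] for pmol/volume presets.
#' @param response optional per-band response correction, see
#'   [lane_fractions()].
#' @param kd_bounds search interval, mol/L.
#' @return object of class `"emsa_fit"`: list with `kd_micro`, `ci95`,
#'   `rss`, `df`, observed and predicted fractions. Supports [coef()],
#'   [confint()], [predict()], [plot()], [print()], [residuals()].
#' @examples
#' lanes <- simulate_emsa_titration(emsa_defaults(), seed = 1)
#' fit <- fit_emsa(lanes, receptor_total = attr(lanes, "receptor_total"))
#' coef(fit)
#' @export
fit_emsa <- function(lanes, receptor_total, response = c(1, 1, 1),
                     kd_bounds = c(1e-10, 1e-3)) {
  stopifnot(all(c("equivalents", "density_free", "density_b1",
                  "density_b2") %in% names(lanes)))
  check_positive(receptor_total, "receptor_total")
  if (any(lanes$equivalents < 0)) stop("equivalents must be >= 0")
  if (nrow(lanes) < 3L) stop("need at least 3 lanes")
  if (max(lanes$equivalents) < 0.5) {
    stop("titration does not constrain kd: all equivalents below 0.5")
  }
  f_obs <- lane_fractions(lanes, response)
  lig <- lanes$equivalents * receptor_total

  pred_at <- function(kd) {
    ms <- solve_two_site(receptor_total, lig, kd)
    cbind(f0 = ms$f0, f1 = ms$f1, f2 = ms$f2)
  }
  rss_at <- function(kd) sum((f_obs - pred_at(kd))^2)

  grid <- exp(seq(log(kd_bounds[1]), log(kd_bounds[2]), length.out = 25L))
  vals <- vapply(grid, rss_at, numeric(1))
  i <- which.min(vals)
  opt <- stats::optimize(function(lk) rss_at(exp(lk)),
                         log(c(grid[max(i - 1L, 1L)],
                               grid[min(i + 1L, length(grid))])),
                         tol = 1e-10)
  kd <- exp(opt$minimum)
  rss <- rss_at(kd)
  # per lane the 3 fractions sum to 1, so 2 independent observations each
  df <- 2L * nrow(lanes) - 1L
  ci <- profile_ci_1d(rss_at, kd, rss, df)

  structure(list(
    kd_micro = kd, ci95 = ci, rss = rss, df = df,
    fractions_observed = f_obs, fractions_predicted = pred_at(kd),
    lanes = lanes, receptor_total = receptor_total, rss_at = rss_at
  ), class = "emsa_fit")
}

#' @export
print.emsa_fit <- function(x, ...) {
  cat("2:1 EMSA band-density fit (two equivalent sites)\n")
  cat(sprintf("  microscopic Kd: %.4g M (%.4g uM)\n",
              x$kd_micro, 1e6 * x$kd_micro))
  cat(sprintf("  95%% CI: %.3g - %.3g uM; RSS %.4g on %d lanes\n",
              1e6 * x$ci95[1], 1e6 * x$ci95[2], x$rss, nrow(x$lanes)))
  invisible(x)
}

#' @export
coef.emsa_fit <- function(object, ...) c(kd_micro = object$kd_micro)

#' @export
confint.emsa_fit <- function(object, parm = "kd_micro", level = 0.95, ...) {
  profile_ci_1d(object$rss_at, object$kd_micro, object$rss, object$df,
                level = level)
}

#' @export
residuals.emsa_fit <- function(object, ...) {
  object$fractions_observed - object$fractions_predicted
}

#' Predicted species fractions from an EMSA fit
#' @param object an `"emsa_fit"`.
#' @param equivalents optional molar-equivalents vector; defaults to the
#'   fitted lanes.
#' @param ... unused.
#' @return data frame with `equivalents`, `f0`, `f1`, `f2`.
#' @export
predict.emsa_fit <- function(object, equivalents = NULL, ...) {
  if (is.null(equivalents)) equivalents <- object$lanes$equivalents
  ms <- solve_two_site(object$receptor_total,
                       equivalents * object$receptor_total, object$kd_micro)
  data.frame(equivalents = equivalents, f0 = ms$f0, f1 = ms$f1, f2 = ms$f2)
}

#' @export
plot.emsa_fit <- function(x, ...) {
  eq <- x$lanes$equivalents
  grid <- seq(0, max(eq), length.out = 100)
  pred <- predict(x, grid)
  cols <- c(f0 = "blue", f1 = "darkgreen", f2 = "red")
  plot(NA, xlim = range(eq), ylim = c(0, 1),
       xlab = "molar equivalents", ylab = "species fraction",
       main = sprintf("EMSA 2:1 fit, Kd = %.3g uM", 1e6 * x$kd_micro), ...)
  for (sp in names(cols)) {
    graphics::points(eq, x$fractions_observed[, sp], col = cols[sp],
                     pch = 16)
    graphics::lines(grid, pred[[sp]], col = cols[sp])
  }
  graphics::legend("right", legend = c("free", "+1", "+2"),
                   col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}
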