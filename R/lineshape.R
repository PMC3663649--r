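#' Acquisition parameters for a simulated 1D trace
#'
#' Bundles the spectral axis metadata used by the line-shape simulator. The
#' default axis is the 13C dimension at a 900 MHz (1H) field, appropriate for
#' a methyl-group trace; the 13C frequency is derived from the field with the
#' gyromagnetic ratio 0.2513222 (226.19 MHz at 900 MHz).
#'
#' @param field_mhz 1H spectrometer frequency, MHz.
#' @param nucleus `"13C"`, `"1H"` or `"15N"` — the axis nucleus.
#' @param sw_ppm sweep width, ppm; must cover both state offsets plus several
#'   linewidths.
#' @param n_points number of complex time-domain points; a power of two
#'   >= 256.
#' @param carrier_ppm centre of the spectral window, ppm.
#' @param lb_hz exponential line-broadening applied before Fourier transform,
#'   Hz.
#' @return list of class `"acquisition_params"`; includes the derived
#'   `frequency_mhz` of the axis nucleus and the dwell time `dwell_s`.
#' @export
acquisition_params <- function(field_mhz = 900, nucleus = "13C",
                               sw_ppm = 2, n_points = 512L,
                               carrier_ppm = 21.475, lb_hz = 2) {
  check_positive(field_mhz, "field_mhz")
  check_positive(sw_ppm, "sw_ppm")
  check_positive(lb_hz, "lb_hz", allow_zero = TRUE)
  n_points <- as.integer(n_points)
  if (n_points < 256L || bitwAnd(n_points, n_points - 1L) != 0L) {
    stop("n_points must be a power of two >= 256, got ", n_points)
  }
  gamma <- c(`1H` = 1, `13C` = 226.19 / 900, `15N` = 0.101329)
  if (!nucleus %in% names(gamma)) stop("unknown nucleus: ", nucleus)
  freq <- field_mhz * gamma[[nucleus]]
  structure(list(
    field_mhz = field_mhz, nucleus = nucleus, sw_ppm = sw_ppm,
    n_points = n_points, carrier_ppm = carrier_ppm, lb_hz = lb_hz,
    frequency_mhz = freq, dwell_s = 1 / (sw_ppm * freq)
  ), class = "acquisition_params")
}

#' Pseudo-first-order exchange rates from the binding equilibrium
#'
#' Links the site-binding equilibrium to the two-state exchange matrix: the
#' observed tail site leaves the bound state at `koff` and enters it at
#' \eqn{k_{on}[L]_{free} = k_{off}\,x/K_D}. The implied equilibrium bound
#' population \eqn{x/(K_D + x)} equals the site occupancy \eqn{\theta} from
#' [solve_two_site()].
#'
#' @param kd microscopic site dissociation constant, mol/L.
#' @param koff dissociation rate, 1/s.
#' @param free_ligand free ligand concentration, mol/L (>= 0).
#' @return list with `k_free_to_bound`, `k_bound_to_free` (1/s) and the
#'   implied `p_bound`.
#' @export
pseudo_first_order_rates <- function(kd, koff, free_ligand) {
  check_positive(kd, "kd")
  check_positive(koff, "koff")
  check_positive(free_ligand, "free_ligand", allow_zero = TRUE)
  list(k_free_to_bound = koff * free_ligand / kd,
       k_bound_to_free = koff,
       p_bound = free_ligand / (kd + free_ligand))
}

#' Two-state exchange evolution matrix
#'
#' Builds the complex 2x2 evolution operator for transverse magnetisation of
#' a spin exchanging between two chemical states: diagonal terms
#' \eqn{i\Omega_j - R_{2,j} - k_{out,j}} (precession, relaxation, exchange
#' out), off-diagonal terms the exchange in-flux. The kinetic part has zero
#' column sums, so total population is conserved by construction.
#'
#' @param offsets_ppm length-2 vector of state offsets (free, bound), ppm.
#' @param r2 length-2 vector of transverse relaxation rates, 1/s.
#' @param k_free_to_bound,k_bound_to_free exchange rates, 1/s.
#' @param acquisition an [acquisition_params()] object (supplies carrier and
#'   nucleus frequency for the ppm-to-rad/s conversion).
#' @return complex 2x2 matrix.
#' @export
evolution_matrix <- function(offsets_ppm, r2, k_free_to_bound,
                             k_bound_to_free, acquisition) {
  stopifnot(length(offsets_ppm) == 2L, length(r2) == 2L)
  check_positive(r2, "r2")
  check_positive(k_free_to_bound, "k_free_to_bound", allow_zero = TRUE)
  check_positive(k_bound_to_free, "k_bound_to_free", allow_zero = TRUE)
  omega <- 2 * pi * (offsets_ppm - acquisition$carrier_ppm) *
    acquisition$frequency_mhz  # ppm * MHz -> Hz, then rad/s
  matrix(c(1i * omega[1] - r2[1] - k_free_to_bound, k_free_to_bound,
           k_bound_to_free, 1i * omega[2] - r2[2] - k_bound_to_free),
         nrow = 2)
}

# eigendecomposition of a complex 2x2, robust to the no-exchange block case.
# Returns NULL at (near-)degeneracy so callers can fall back to stepping.
eigen_2x2 <- function(L) {
  a <- L[1, 1]; b <- L[1, 2]; cc <- L[2, 1]; d <- L[2, 2]
  mu <- (a + d) / 2
  disc <- sqrt(((a - d) / 2)^2 + b * cc)
  lambda <- c(mu + disc, mu - disc)
  scale <- max(Mod(a), Mod(d), 1e-300)
  if (Mod(b) + Mod(cc) < 1e-14 * scale) {
    # block-diagonal: two independent oscillators
    return(list(values = c(a, d), vectors = diag(2),
                inverse = diag(2)))
  }
  if (Mod(disc) < 1e-9 * scale) return(NULL)
  V <- if (Mod(b) >= Mod(cc)) {
    cbind(c(b, lambda[1] - a), c(b, lambda[2] - a))
  } else {
    cbind(c(lambda[1] - d, cc), c(lambda[2] - d, cc))
  }
  det <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  if (Mod(det) < 1e-12 * max(Mod(V))^2) return(NULL)
  Vinv <- matrix(c(V[2, 2], -V[2, 1], -V[1, 2], V[1, 1]), 2) / det
  list(values = lambda, vectors = V, inverse = Vinv)
}

#' Simulate the FID of an exchanging two-state spin
#'
#' Propagates the initial transverse magnetisation under the evolution matrix
#' and returns the observable FID (sum over state components) at `n_points`
#' uniformly spaced times. Propagation is by exact eigendecomposition of the
#' 2x2 operator (the FID is a sum of two complex exponentials); at an
#' exceptional (degenerate) point it falls back to exact stepwise propagation
#' with the closed-form 2x2 matrix exponential.
#'
#' @param evolution complex 2x2 matrix from [evolution_matrix()].
#' @param initial_magnetization length-2 vector of state populations; must
#'   sum to 1 so that FID(0) = 1.
#' @param dwell sampling interval, s.
#' @param n_points number of time points.
#' @return complex vector of length `n_points`.
#' @export
simulate_fid <- function(evolution, initial_magnetization, dwell, n_points) {
  check_positive(dwell, "dwell")
  m0 <- initial_magnetization
  stopifnot(length(m0) == 2L)
  if (abs(sum(m0) - 1) > 1e-9) {
    stop("initial_magnetization must sum to 1 (normalized FID)")
  }
  t <- (seq_len(n_points) - 1) * dwell
  e <- eigen_2x2(evolution)
  if (!is.null(e)) {
    if (any(Re(e$values) > 1e-8)) {
      stop("divergent propagation: evolution matrix has a positive real ",
           "eigenvalue; check R2 and exchange rates")
    }
    w <- as.vector(colSums(e$vectors) * (e$inverse %*% m0))
    return(w[1] * exp(e$values[1] * t) + w[2] * exp(e$values[2] * t))
  }
  # degenerate fallback: P = exp(L*dwell) via the analytic 2x2 exponential
  mu <- (evolution[1, 1] + evolution[2, 2]) / 2
  disc <- sqrt(((evolution[1, 1] - evolution[2, 2]) / 2)^2 +
                 evolution[1, 2] * evolution[2, 1])
  if (any(Re(c(mu + disc, mu - disc)) > 1e-8)) {
    stop("divergent propagation: evolution matrix has a positive real ",
         "eigenvalue; check R2 and exchange rates")
  }
  z <- disc * dwell
  sinhc <- if (Mod(z) < 1e-8) 1 + z^2 / 6 else sinh(z) / z
  P <- exp(mu * dwell) *
    (cosh(z) * diag(2) + sinhc * dwell * (evolution - mu * diag(2)))
  fid <- complex(n_points)
  m <- as.complex(m0)
  for (k in seq_len(n_points)) {
    fid[k] <- sum(m)
    m <- P %*% m
  }
  fid
}

#' Fourier-transform an FID into a 1D spectral trace
#'
#' Applies exponential apodization (`lb_hz`), halves the first point, zero
#' fills twice, Fourier transforms, and returns the real-part spectrum on a
#' ppm axis. Intensities are scaled so that the integral of the spectrum (in
#' Hz units) equals FID(0) when no apodization beyond R2 is applied.
#'
#' @param fid complex FID vector.
#' @param acquisition an [acquisition_params()] object.
#' @return data frame of class `"spectrum_trace"` with columns `ppm`
#'   (ascending) and `intensity`; the acquisition parameters are attached as
#'   attribute `"acquisition"`.
#' @export
spectrum_from_fid <- function(fid, acquisition) {
  n <- length(fid)
  dwell <- acquisition$dwell_s
  t <- (seq_len(n) - 1) * dwell
  x <- fid * exp(-pi * acquisition$lb_hz * t)
  x[1] <- x[1] / 2
  nz <- 2L * n
  xz <- c(x, complex(nz - n))
  X <- stats::fft(xz)
  f <- (seq_len(nz) - 1) / (nz * dwell)
  nyq <- 1 / (2 * dwell)
  f[f >= nyq] <- f[f >= nyq] - 2 * nyq
  ppm <- acquisition$carrier_ppm + f / acquisition$frequency_mhz
  ord <- order(ppm)
  out <- data.frame(ppm = ppm[ord], intensity = 2 * dwell * Re(X)[ord])
  attr(out, "acquisition") <- acquisition
  class(out) <- c("spectrum_trace", "data.frame")
  out
}

#' Integral of a spectral trace in Hz units
#' @param trace a `"spectrum_trace"`.
#' @return numeric integral \eqn{\sum I \, \Delta f}.
#' @export
trace_integral <- function(trace) {
  acq <- attr(trace, "acquisition")
  df_hz <- (trace$ppm[2] - trace$ppm[1]) * acq$frequency_mhz
  sum(trace$intensity) * df_hz
}

# precomputed constants for repeated spectrum evaluation on one grid
trace_engine <- function(acquisition) {
  n <- acquisition$n_points
  dwell <- acquisition$dwell_s
  t <- (seq_len(n) - 1) * dwell
  nz <- 2L * n
  f <- (seq_len(nz) - 1) / (nz * dwell)
  nyq <- 1 / (2 * dwell)
  f[f >= nyq] <- f[f >= nyq] - 2 * nyq
  ppm <- acquisition$carrier_ppm + f / acquisition$frequency_mhz
  list(acq = acquisition, t = t, apod = exp(-pi * acquisition$lb_hz * t),
       pad = complex(nz - n), ord = order(ppm), dwell = dwell)
}

# intensity vectors (sorted-ppm grid) for a titration, minimal allocation;
# same maths as titration_lineshapes() + spectrum_from_fid().
lineshape_intensities <- function(kd, koff, receptor_total, ratios,
                                  offsets_ppm, r2, eng) {
  acq <- eng$acq
  omega <- 2 * pi * (offsets_ppm - acq$carrier_ppm) * acq$frequency_mhz
  lapply(ratios, function(r) {
    # two-site mass balance, stable root (same arithmetic as solve_two_site)
    l0 <- r * receptor_total
    bq <- kd + 2 * receptor_total - l0
    x <- 2 * kd * l0 / (bq + sqrt(bq^2 + 4 * kd * l0))
    theta <- x / (kd + x)
    kfb <- koff * x / kd
    a <- 1i * omega[1] - r2[1] - kfb
    d <- 1i * omega[2] - r2[2] - koff
    mu <- (a + d) / 2
    disc <- sqrt(((a - d) / 2)^2 + kfb * koff)
    if (Mod(disc) < 1e-9 * max(Mod(a), Mod(d))) {
      L <- matrix(c(a, kfb, koff, d), 2)
      fid <- simulate_fid(L, c(1 - theta, theta), eng$dwell,
                          acq$n_points)
    } else {
      lambda <- c(mu + disc, mu - disc)
      if (any(Re(lambda) > 1e-8)) stop("divergent propagation")
      m0 <- c(1 - theta, theta)
      if (kfb == 0 && koff == 0) {
        w <- m0
      } else {
        # L = [[a, koff], [kfb, d]]: eigenvector (b, lambda - a) with
        # b = L[1,2] = koff, or (lambda - d, c) with c = L[2,1] = kfb
        V <- if (koff >= kfb) {
          cbind(c(koff, lambda[1] - a), c(koff, lambda[2] - a))
        } else {
          cbind(c(lambda[1] - d, kfb), c(lambda[2] - d, kfb))
        }
        det <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
        Vinv <- matrix(c(V[2, 2], -V[2, 1], -V[1, 2], V[1, 1]), 2) / det
        w <- as.vector(colSums(V) * (Vinv %*% m0))
      }
      fid <- w[1] * exp(lambda[1] * eng$t) + w[2] * exp(lambda[2] * eng$t)
    }
    x <- fid * eng$apod
    x[1] <- x[1] / 2
    (2 * eng$dwell * Re(stats::fft(c(x, eng$pad))))[eng$ord]
  })
}

#' Simulate a titration series of exchange line shapes
#'
#' For each ligand:receptor molar ratio, solves the two-equivalent-site mass
#' balance ([solve_two_site()]), converts the free ligand concentration to
#' pseudo-first-order exchange rates, and simulates one 1D trace. The
#' zero-ratio trace reproduces the free-state spectrum.
#'
#' @param kd microscopic site dissociation constant, mol/L.
#' @param koff dissociation rate, 1/s.
#' @param receptor_total two-site receptor (nucleosome) concentration, mol/L.
#' @param ratios ligand:receptor molar ratios; must include 0.
#' @param offsets_ppm state offsets (free, bound), ppm.
#' @param r2 transverse relaxation rates (free, bound), 1/s.
#' @param acquisition an [acquisition_params()] object.
#' @return list of `"spectrum_trace"` objects, one per ratio, in order.
#' @export
titration_lineshapes <- function(kd, koff, receptor_total, ratios,
                                 offsets_ppm = c(21.3, 21.65),
                                 r2 = c(8, 40),
                                 acquisition = acquisition_params()) {
  check_positive(kd, "kd")
  check_positive(koff, "koff")
  check_positive(receptor_total, "receptor_total")
  if (!any(ratios == 0)) stop("ratios must include 0 (free reference)")
  lapply(ratios, function(r) {
    ms <- solve_two_site(receptor_total, r * receptor_total, kd)
    rates <- pseudo_first_order_rates(kd, koff, ms$free_ligand)
    L <- evolution_matrix(offsets_ppm, r2, rates$k_free_to_bound,
                          rates$k_bound_to_free, acquisition)
    m0 <- c(1 - ms$occupancy, ms$occupancy)
    fid <- simulate_fid(L, m0, acquisition$dwell_s, acquisition$n_points)
    spectrum_from_fid(fid, acquisition)
  })
}

#' Peak positions of a list of traces
#'
#' Returns the position of the global maximum of each trace, refined by
#' three-point parabolic interpolation around the maximum sample.
#'
#' @param traces list of `"spectrum_trace"` objects.
#' @param ratios optional vector labelling the traces (returned alongside).
#' @return data frame with columns `ratio` (if given) and `ppm`.
#' @export
peak_positions <- function(traces, ratios = NULL) {
  pos <- vapply(traces, function(tr) {
    y <- tr$intensity
    if (max(y) - min(y) <= 0) stop("flat trace: no unique maximum")
    i <- which.max(y)
    if (i == 1L || i == length(y)) return(tr$ppm[i])
    dx <- tr$ppm[2] - tr$ppm[1]
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    shift <- if (denom == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
    tr$ppm[i] + shift * dx
  }, numeric(1))
  if (is.null(ratios)) data.frame(ppm = pos)
  else data.frame(ratio = ratios, ppm = pos)
}
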