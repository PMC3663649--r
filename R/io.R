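AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Read a Sparky-style peak list
#'
#' Parses a whitespace-delimited table with a header line and rows of the
#' form `assignment w1 w2`, where the assignment encodes one-letter residue
#' name, residue number and the two atoms, e.g. `G46N-H` or `V35CG1-HG1`.
#' `w1` is the heteronucleus (15N/13C) shift and `w2` the 1H shift, in ppm.
#'
#' @param path file path.
#' @return data frame with columns `residue_id`, `residue_name`, `atom_x`,
#'   `atom_h`, `shift_x`, `shift_h`.
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("empty peak list: ", path)
  rows <- lines[-1L]  # drop header
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed peak-list rows (need 3 fields) at line ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  assign <- vapply(parts, `[[`, character(1), 1L)
  m <- regmatches(assign,
                  regexec("^([A-Z])([0-9]+)([A-Z][A-Z0-9]*)-([A-Z][A-Z0-9]*)$",
                          assign))
  ok <- lengths(m) == 5L
  if (any(!ok)) {
    stop("unparseable assignment token(s): ",
         paste(assign[!ok], collapse = ", "), " at line ",
         paste(which(!ok) + 1L, collapse = ", "), " of ", path)
  }
  if (anyDuplicated(assign)) {
    stop("duplicate assignment(s) in ", path, ": ",
         paste(unique(assign[duplicated(assign)]), collapse = ", "))
  }
  get <- function(i) vapply(m, `[[`, character(1), i)
  letter <- get(2)
  if (any(!letter %in% names(AA3))) {
    stop("unknown residue letter: ",
         paste(unique(letter[!letter %in% names(AA3)]), collapse = ", "))
  }
  shift_x <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  shift_h <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  if (anyNA(shift_x) || anyNA(shift_h)) {
    stop("non-numeric shift value at line ",
         paste(which(is.na(shift_x) | is.na(shift_h)) + 1L, collapse = ", "),
         " of ", path)
  }
  data.frame(
    residue_id = as.integer(get(3)),
    residue_name = unname(AA3[letter]),
    atom_x = get(4), atom_h = get(5),
    shift_x = shift_x, shift_h = shift_h
  )
}

#' Write a Sparky-style peak list
#'
#' @param peaks data frame with columns `residue_id`, `residue_name` (or a
#'   one-letter code derivable from it), `shift_x`, `shift_h` and optionally
#'   `atom_x`/`atom_h` (default `N`/`H`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  letter <- names(AA3)[match(peaks$residue_name, AA3)]
  letter[is.na(letter)] <- "G"
  atom_x <- if ("atom_x" %in% names(peaks)) peaks$atom_x else "N"
  atom_h <- if ("atom_h" %in% names(peaks)) peaks$atom_h else "H"
  rows <- sprintf("%s%d%s-%s %10.4f %10.4f", letter, peaks$residue_id,
                  atom_x, atom_h, peaks$shift_x, peaks$shift_h)
  writeLines(c(" Assignment         w1         w2", rows), path)
  invisible(path)
}

#' Write a 1D spectral trace as two-column text
#'
#' Acquisition metadata (and optionally the generator seed) is stored in
#' `# key: value` header comments so that a round-trip preserves it.
#'
#' @param trace a `"spectrum_trace"` data frame.
#' @param path output file path.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, seed = NULL) {
  acq <- attr(trace, "acquisition")
  hdr <- c(
    sprintf("# field_mhz: %.6g", acq$field_mhz),
    sprintf("# nucleus: %s", acq$nucleus),
    sprintf("# sw_ppm: %.6g", acq$sw_ppm),
    sprintf("# n_points: %d", acq$n_points),
    sprintf("# carrier_ppm: %.6g", acq$carrier_ppm),
    sprintf("# lb_hz: %.6g", acq$lb_hz),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  body <- sprintf("%.8f %.10e", trace$ppm, trace$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 1D spectral trace written by [write_trace()]
#' @param path file path.
#' @return a `"spectrum_trace"` data frame with the acquisition attribute
#'   restored.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([a-z_]+):\\s*(.+)$", hdr))
  meta <- stats::setNames(vapply(kv, `[[`, character(1), 3L),
                          vapply(kv, `[[`, character(1), 2L))
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != 2L)) stop("malformed trace row in ", path)
  out <- data.frame(
    ppm = as.numeric(vapply(parts, `[[`, character(1), 1L)),
    intensity = as.numeric(vapply(parts, `[[`, character(1), 2L))
  )
  if (all(c("field_mhz", "nucleus", "sw_ppm", "n_points", "carrier_ppm",
            "lb_hz") %in% names(meta))) {
    attr(out, "acquisition") <- acquisition_params(
      field_mhz = as.numeric(meta["field_mhz"]),
      nucleus = meta[["nucleus"]],
      sw_ppm = as.numeric(meta["sw_ppm"]),
      n_points = as.integer(meta["n_points"]),
      carrier_ppm = as.numeric(meta["carrier_ppm"]),
      lb_hz = as.numeric(meta["lb_hz"]))
  }
  if ("seed" %in% names(meta)) attr(out, "seed") <- as.integer(meta["seed"])
  class(out) <- c("spectrum_trace", "data.frame")
  out
}

#' Read/write CSP curve tables (TSV)
#'
#' Columns: `residue_id`, `point_index`, `ligand_total_M`, `csp_ppm`.
#' @param path file path.
#' @return for `read_curves`, a curve data frame with the column names used
#'   by [fit_csp()] (`ligand_total`, `csp`).
#' @export
read_curves <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("residue_id", "point_index", "ligand_total_M", "csp_ppm")
  if (!all(need %in% names(d))) {
    stop("curve table must have columns ", paste(need, collapse = ", "))
  }
  data.frame(residue_id = as.character(d$residue_id),
             point_index = d$point_index,
             ligand_total = d$ligand_total_M, csp = d$csp_ppm)
}

#' @rdname read_curves
#' @param curves curve data frame (columns `residue_id`, `point_index`,
#'   `ligand_total`, `csp`).
#' @export
write_curves <- function(curves, path) {
  out <- data.frame(residue_id = curves$residue_id,
                    point_index = if ("point_index" %in% names(curves))
                      curves$point_index else
                      match(curves$ligand_total,
                            sort(unique(curves$ligand_total))) - 1L,
                    ligand_total_M = curves$ligand_total,
                    csp_ppm = curves$csp)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write EMSA lane tables (TSV)
#'
#' Columns: `lane_id`, `equivalents`, `density_free`, `density_b1`,
#' `density_b2`.
#' @param path file path.
#' @export
read_lanes <- function(path) {
  d <- utils::read.delim(path)
  need <- c("lane_id", "equivalents", "density_free", "density_b1",
            "density_b2")
  if (!all(need %in% names(d))) {
    stop("lane table must have columns ", paste(need, collapse = ", "))
  }
  d
}

#' @rdname read_lanes
#' @param lanes lane data frame.
#' @export
write_lanes <- function(lanes, path) {
  utils::write.table(lanes[, c("lane_id", "equivalents", "density_free",
                               "density_b1", "density_b2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a trace manifest (TSV: file, ratio, receptor_total_M)
#' @param path file path.
#' @export
read_manifest <- function(path) {
  d <- utils::read.delim(path)
  need <- c("file", "ratio", "receptor_total_M")
  if (!all(need %in% names(d))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  d
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' One schema shared by all fitters: model name, point estimates, intervals,
#' flags and diagnostics, plus seed and package version for provenance.
#'
#' @param fit a `"csp_fit"`, `"exchange_fit"` or `"emsa_fit"` object (or a
#'   plain named list for the avidity report).
#' @param path output path.
#' @param seed optional seed to record.
#' @return the report list, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  report <- if (inherits(fit, "csp_fit")) {
    ci <- tryCatch(confint(fit), error = function(e) c(NA, NA))
    list(model = "csp_isotherm_1to1",
         estimate = list(kd_M = fit$kd),
         interval95 = list(kd_M = unname(ci)),
         csp_max_ppm = as.list(fit$csp_max),
         diagnostics = list(rmsd_ppm = fit$sigma, rss = fit$rss,
                            n_points = fit$n_points,
                            n_residues = fit$n_residues),
         flags = if (is.infinite(ci[2])) "kd_upper_open" else character(0))
  } else if (inherits(fit, "exchange_fit")) {
    list(model = "exchange_lineshape_1to2",
         estimate = list(kd_M = fit$kd, koff_per_s = fit$koff,
                         delta_omega_ppm = fit$delta_omega_ppm,
                         r2_free = fit$r2_free, r2_bound = fit$r2_bound),
         interval95 = list(kd_M = unname(fit$interval95_kd),
                           koff_per_s = unname(fit$interval95_koff)),
         diagnostics = list(chi2 = fit$chi2, df = fit$df),
         flags = fit$flags)
  } else if (inherits(fit, "emsa_fit")) {
    list(model = "emsa_2to1",
         estimate = list(kd_micro_M = fit$kd_micro),
         interval95 = list(kd_micro_M = unname(fit$ci95)),
         diagnostics = list(rss = fit$rss, n_lanes = nrow(fit$lanes)),
         flags = if (is.infinite(fit$ci95[2])) "kd_upper_open"
                 else character(0))
  } else {
    fit
  }
  report$seed <- seed
  report$package_version <- as.character(utils::packageVersion("bindfit"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(report)
}
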