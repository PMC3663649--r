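#' Run a configured analysis step
#'
#' Config-driven entry point dispatching to the package's generators and
#' fitters. The config (a JSON file or an equivalent named list) declares the
#' subcommand, input paths, explicit concentration units, model options, seed
#' and output directory. Concentration units must always be declared — there
#' is no unit inference.
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate`}{`experiment` one of `csp_peptide`, `csp_dna`,
#'     `csp_mla`, `lineshape_nucleosome`, `emsa`; writes the synthetic
#'     dataset in the formats the fitters read.}
#'   \item{`fit-csp`}{`curves` path (TSV) + `receptor_total`
#'     (`{value, unit}`); optional `max_ligand` (`{value, unit}`) applies
#'     [truncate_series()].}
#'   \item{`fit-lineshape`}{`manifest` path (TSV listing trace files,
#'     ratios, receptor concentration in mol/L); optional `interval`
#'     (logical).}
#'   \item{`fit-emsa`}{`lanes` path (TSV) + either `receptor_total`
#'     (`{value, unit}`) or `nucleosome_pmol` + `load_volume_ul`.}
#'   \item{`avidity`}{`kd_tail`, `kd_dna`, `kd_complex` each
#'     `{value, unit}`; reports the effective concentration, fold
#'     enhancement and complex lifetime (if `koff` given).}
#' }
#'
#' Every run writes a JSON report (shared schema), a log recording the seed
#' and the md5 digest of the resolved config, and any data products into
#' `out_dir`.
#'
#' @param config path to a JSON config file, or a named list.
#' @param seed optional integer overriding the config seed.
#' @param out_dir output directory (created if missing); defaults to the
#'   config's `out_dir` or a temporary directory.
#' @return invisibly, a list with the report and output paths.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  if (is.null(cfg$subcommand)) stop("config must declare a subcommand")
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  seed <- as.integer(seed)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("bindfit_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  conc <- function(field, what = field) {
    x <- cfg[[field]]
    if (is.null(x$value) || is.null(x$unit)) {
      stop(what, " must be given as {value, unit} (explicit units required)")
    }
    to_molar(x$value, x$unit)
  }

  report_path <- file.path(out_dir, "report.json")
  report <- switch(cfg$subcommand,
    simulate = pipeline_simulate(cfg, seed, out_dir),
    `fit-csp` = {
      curves <- read_curves(resolve_path(cfg$curves))
      if (!is.null(cfg$max_ligand)) {
        curves <- truncate_series(curves, conc("max_ligand"))
      }
      fit <- fit_csp(curves, receptor_total = conc("receptor_total"))
      write_curves(cbind(predict(fit),
                         point_index = NA),
                   file.path(out_dir, "fitted_curves.tsv"))
      write_fit_report(fit, report_path, seed)
    },
    `fit-lineshape` = {
      man <- read_manifest(resolve_path(cfg$manifest))
      base <- dirname(resolve_path(cfg$manifest))
      traces <- lapply(file.path(base, man$file), read_trace)
      fit <- fit_exchange(traces, man$ratio, man$receptor_total_M[1],
                          interval = isTRUE(cfg$interval))
      sims <- predict(fit)
      for (j in seq_along(sims)) {
        write_trace(sims[[j]],
                    file.path(out_dir, sprintf("bestfit_trace_%02d.txt", j)))
      }
      write_fit_report(fit, report_path, seed)
    },
    `fit-emsa` = {
      lanes <- read_lanes(resolve_path(cfg$lanes))
      n0 <- if (!is.null(cfg$receptor_total)) conc("receptor_total")
            else if (!is.null(cfg$nucleosome_pmol)) {
              amount_to_molar(cfg$nucleosome_pmol, cfg$load_volume_ul)
            } else stop("fit-emsa needs receptor_total or nucleosome_pmol ",
                        "+ load_volume_ul")
      fit <- fit_emsa(lanes, receptor_total = n0)
      obs <- as.data.frame(fit$fractions_observed)
      names(obs) <- paste0("obs_", names(obs))
      prd <- as.data.frame(fit$fractions_predicted)
      names(prd) <- paste0("pred_", names(prd))
      utils::write.table(cbind(equivalents = lanes$equivalents, obs, prd),
                         file.path(out_dir, "fractions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_fit_report(fit, report_path, seed)
    },
    avidity = {
      ceff <- effective_concentration(conc("kd_tail"), conc("kd_dna"),
                                      conc("kd_complex"))
      fe <- fold_enhancement(conc("kd_tail"), conc("kd_complex"))
      rep <- list(model = "avidity",
                  estimate = list(
                    effective_concentration_M = ceff,
                    fold_enhancement = fe$ratio,
                    nearest_power_of_ten = fe$nearest_power_of_ten))
      if (!is.null(cfg$koff)) {
        rep$estimate$lifetime_s <- complex_lifetime(cfg$koff)
      }
      write_fit_report(rep, report_path, seed)
    },
    stop("unknown subcommand: ", cfg$subcommand)
  )

  cfg_used <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(cfg, cfg_used, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(
    sprintf("subcommand: %s", cfg$subcommand),
    sprintf("seed: %d", seed),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_used))),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("bindfit"))),
    sprintf("flags: %s",
            paste(unlist(report$flags), collapse = ", "))
  ), file.path(out_dir, "run.log"))
  invisible(list(report = report, out_dir = out_dir,
                 report_path = report_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_path <- function(p) {
  if (is.null(p)) stop("required input path missing from config")
  if (!file.exists(p)) stop("input file does not exist: ", p)
  p
}

pipeline_simulate <- function(cfg, seed, out_dir) {
  exp <- cfg$experiment %||% stop("simulate needs an experiment field")
  rep <- pipeline_simulate_impl(exp, cfg, seed, out_dir)
  write_fit_report(rep, file.path(out_dir, "report.json"), seed)
}

pipeline_simulate_impl <- function(exp, cfg, seed, out_dir) {
  if (exp %in% c("csp_peptide", "csp_dna", "csp_mla")) {
    spec <- utils::modifyList(csp_defaults(exp),
                              cfg$override %||% list())
    sim <- simulate_csp_titration(spec, seed)
    write_curves(sim$curves, file.path(out_dir, "curves.tsv"))
    for (i in seq_along(sim$peaks)) {
      write_peak_list(sim$peaks[[i]],
                      file.path(out_dir, sprintf("peaks_%02d.list", i - 1L)))
    }
    list(model = "simulate_csp", experiment = exp, seed = seed,
         truth = list(kd_M = spec$kd))
  } else if (exp == "lineshape_nucleosome") {
    spec <- utils::modifyList(exchange_defaults(), cfg$override %||% list())
    sim <- simulate_exchange_titration(spec, seed)
    files <- sprintf("trace_%02d.txt", seq_along(sim$traces))
    for (j in seq_along(sim$traces)) {
      write_trace(sim$traces[[j]], file.path(out_dir, files[j]), seed)
    }
    man <- cbind(file = files, sim$manifest)
    write_manifest(man, file.path(out_dir, "manifest.tsv"))
    list(model = "simulate_lineshape", experiment = exp, seed = seed,
         truth = list(kd_M = spec$kd, koff_per_s = spec$koff))
  } else if (exp == "emsa") {
    spec <- utils::modifyList(emsa_defaults(), cfg$override %||% list())
    lanes <- simulate_emsa_titration(spec, seed)
    write_lanes(lanes, file.path(out_dir, "lanes.tsv"))
    list(model = "simulate_emsa", experiment = exp, seed = seed,
         truth = list(kd_M = spec$kd))
  } else {
    stop("unknown experiment: ", exp)
  }
}
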