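#' Pipeline run configuration
#'
#' Describes one end-to-end run: either paths to a cohort CSV and a
#' growth-standard CSV, or a simulation block for a synthetic cohort. The
#' configuration is plain data (paths, numbers, names) and round-trips
#' losslessly through JSON.
#'
#' @param cohort_csv,standard_csv input paths (set \code{simulate} to
#'   \code{NULL} when using them).
#' @param simulate named list of [sim_config()] arguments (e.g.
#'   \code{n_children}, rates, \code{truth = "jecs"}); used when no cohort
#'   CSV is given.
#' @param models which models to fit: subset of
#'   \code{c("lms", "polynomial")}.
#' @param edf_grid data frame of edf triples for the LMS fit.
#' @param height_ps,bp_ps table percentile sets (probabilities).
#' @param out_dir output directory.
#' @param seed integer seed for the simulation.
#' @param log_level "info" or "quiet".
#' @return object of class \code{run_config}.
#' @export
run_config <- function(cohort_csv = NULL, standard_csv = NULL,
                       simulate = list(), models = c("lms", "polynomial"),
                       edf_grid = default_edf_grid(),
                       height_ps = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90,
                                     0.95),
                       bp_ps = c(0.50, 0.90, 0.95, 0.99),
                       out_dir = tempfile("bpcentile_run_"),
                       seed = 1L, log_level = "info") {
  if (is.null(cohort_csv) && is.null(simulate)) {
    stop("either a cohort CSV or a simulation block is required",
         call. = FALSE)
  }
  edf_grid <- as.data.frame(edf_grid)
  if (!nrow(edf_grid)) stop("edf_grid must be non-empty", call. = FALSE)
  models <- match.arg(models, c("lms", "polynomial"), several.ok = TRUE)
  structure(list(cohort_csv = cohort_csv, standard_csv = standard_csv,
                 simulate = simulate, models = models,
                 edf_grid = edf_grid, height_ps = height_ps,
                 bp_ps = bp_ps, out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Write / read a run configuration (JSON)
#'
#' @param config a [run_config()].
#' @param path JSON path.
#' @return \code{path} invisibly (write); a \code{run_config} (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$edf_grid <- as.list(config$edf_grid)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configurations requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$edf_grid <- as.data.frame(x$edf_grid)
  if (is.list(x$simulate) && !length(x$simulate)) x$simulate <- list()
  do.call(run_config, x)
}

#' Run the full reference-value pipeline
#'
#' Orchestrates the analysis end to end: simulate or load the cohort,
#' apply the triplicate selection rule, compute height Z-scores, run the
#' exclusion cascade with flow accounting, fit the requested models per
#' sex and outcome, build reference tables, and emit diagnostics. All
#' artifacts are written under \code{config$out_dir} together with a
#' provenance manifest (configuration, seed, package version, and an MD5
#' hash of every output file). Identical configuration and seed give
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the cohort, analyzed sets, flow
#'   accounting, fitted models, reference tables and manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) {
    if (!identical(config$log_level, "quiet")) message("[bpcentile] ", ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, ...)

  standard <- stage("standard", {
    if (!is.null(config$standard_csv)) read_growth_standard(config$standard_csv)
    else synthetic_growth_standard()
  })

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      say("loading cohort from ", config$cohort_csv)
      read_cohort(config$cohort_csv)
    } else {
      args <- config$simulate
      args$seed <- config$seed
      args$standard <- standard
      cfg <- do.call(sim_config, args)
      say("simulating cohort of ", cfg$n_children, " children")
      generate_cohort(cfg)
    }
  })

  cohort <- stage("selection", select_cohort(cohort))
  write_cohort(cohort, outfile("cohort.csv"))
  say("selection: SBP accepted ", sum(cohort$sbp_status == "accepted"),
      ", DBP accepted ", sum(cohort$dbp_status == "accepted"))

  excl <- stage("exclusions", apply_exclusions(cohort, standard))
  jsonlite::write_json(list(sbp = as.list(excl$flow$sbp),
                            dbp = as.list(excl$flow$dbp),
                            reasons = excl$reasons),
                       outfile("flow.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(format_flow(excl$flow), outfile("flow.txt"))
  utils::write.csv(excl$sbp_set, outfile("analyzed_sbp.csv"),
                   row.names = FALSE)
  utils::write.csv(excl$dbp_set, outfile("analyzed_dbp.csv"),
                   row.names = FALSE)
  say("analyzed: SBP ", excl$flow$sbp[["analyzed"]], " / DBP ",
      excl$flow$dbp[["analyzed"]])

  summ <- stage("summary", cohort_summary(excl$sbp_set, excl$dbp_set))
  utils::write.csv(as.data.frame(summ), outfile("cohort_summary.csv"),
                   row.names = FALSE)

  sets <- list(SBP = excl$sbp_set, DBP = excl$dbp_set)
  models <- list(); tables <- list()
  for (oc in names(sets)) {
    for (sx in intersect(c("boy", "girl"), unique(sets[[oc]]$sex))) {
      dat <- sets[[oc]][sets[[oc]]$sex == sx, c("zht", "bp")]
      key <- paste(sx, oc, sep = "_")
      if ("lms" %in% config$models) {
        say("fitting LMS model for ", key, " (n = ", nrow(dat), ")")
        fit <- stage(paste0("fit_lms_", key),
                     fit_lms(dat, config$edf_grid, sex = sx,
                             outcome = oc))
        models[[paste0("lms_", key)]] <- fit
        write_lms_model(fit, outfile(paste0("lms_", key)))
        tab <- stage(paste0("table_lms_", key),
                     build_reference_table(fit, config$height_ps,
                                           config$bp_ps,
                                           allow_extrapolation = TRUE))
        tables[[paste0("lms_", key)]] <- tab
        r <- z_residuals(fit)$z
        utils::write.csv(qq_coordinates(r),
                         outfile(paste0("qq_lms_", key, ".csv")),
                         row.names = FALSE)
        utils::write.csv(residual_density(r),
                         outfile(paste0("density_lms_", key, ".csv")),
                         row.names = FALSE)
        utils::write.csv(fitcurve_data(fit, dat, config$bp_ps),
                         outfile(paste0("fitcurve_lms_", key, ".csv")),
                         row.names = FALSE)
      }
      if ("polynomial" %in% config$models) {
        say("fitting polynomial model for ", key)
        fit <- stage(paste0("fit_poly_", key),
                     fit_bp_polynomial(dat, sex = sx, outcome = oc))
        models[[paste0("poly_", key)]] <- fit
        tab <- stage(paste0("table_poly_", key),
                     build_reference_table(fit, config$height_ps,
                                           config$bp_ps))
        tables[[paste0("poly_", key)]] <- tab
      }
    }
  }
  polys <- models[grep("^poly_", names(models))]
  if (length(polys)) {
    write_poly_coefficients(polys, outfile("poly_coefficients.csv"))
  }
  if (length(tables)) {
    for (nm in names(tables)) {
      write_reference_table(tables[[nm]],
                            outfile(paste0("table_", nm, ".csv")),
                            outfile(paste0("table_", nm, "_long.csv")))
    }
  }
  if ("lms" %in% config$models && "polynomial" %in% config$models) {
    cmp <- list()
    for (key in sub("^lms_", "", grep("^lms_", names(tables),
                                      value = TRUE))) {
      a <- tables[[paste0("lms_", key)]]
      b <- tables[[paste0("poly_", key)]]
      if (!is.null(a) && !is.null(b)) {
        d <- compare_tables(a, b)
        cmp[[key]] <- list(max_abs = d$max_abs, mean_abs = d$mean_abs)
      }
    }
    jsonlite::write_json(cmp, outfile("model_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  cfg_path <- outfile("config.json")
  write_run_config(config, cfg_path)
  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   outfile("provenance.json"))
  manifest <- list(
    package = "bpcentile",
    version = as.character(utils::packageVersion("bpcentile")),
    seed = config$seed,
    config = "config.json",
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, outfile("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  say("run complete: ", length(files), " artifacts in ", config$out_dir)

  invisible(list(cohort = cohort, sbp_set = excl$sbp_set,
                 dbp_set = excl$dbp_set, flow = excl$flow,
                 summary = summ, models = models, tables = tables,
                 manifest = outfile("provenance.json"),
                 out_dir = config$out_dir))
}
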