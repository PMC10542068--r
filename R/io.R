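#' Read release curves from CSV
#'
#' Expects comma-separated UTF-8 with a header and the columns `time_h` and
#' `conc_mg_gae_per_kg`; optional grouping columns `simulant`,
#' `temperature_C` and `replicate` split the file into one curve per group.
#' Rows are sorted by time within each group; duplicate (group, time) rows
#' and negative or non-numeric cells are rejected with the offending row
#' numbers.
#'
#' @param path CSV file path.
#' @return A named list of [release_curve()] objects.
#' @seealso [write_release_csv()]
#' @export
read_release_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_h", "conc_mg_gae_per_kg")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric '%s' in data row(s) %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    df[[col]] <- v
  }
  neg <- which(df$conc_mg_gae_per_kg < 0)
  if (length(neg))
    stop("negative concentration in data row(s) ",
         paste(neg, collapse = ", "), call. = FALSE)

  group_cols <- intersect(c("simulant", "temperature_C", "replicate"),
                          names(df))
  key <- if (length(group_cols))
    interaction(lapply(df[group_cols], function(v) factor(v, exclude = NULL)),
                drop = TRUE, sep = "_") else
    factor(rep("curve", nrow(df)))

  dup <- duplicated(data.frame(key, df$time_h))
  if (any(dup))
    stop("duplicate (group, time) in data row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)

  curves <- lapply(levels(key), function(k) {
    g <- df[key == k, , drop = FALSE]
    g <- g[order(g$time_h), , drop = FALSE]
    release_curve(
      g$time_h, g$conc_mg_gae_per_kg, time_unit = "h",
      simulant = if ("simulant" %in% group_cols) g$simulant[1] else
        NA_character_,
      temperature = if ("temperature_C" %in% group_cols) g$temperature_C[1]
        else NA,
      replicate = if ("replicate" %in% group_cols) g$replicate[1] else NA)
  })
  stats::setNames(curves, levels(key))
}

#' Write release curves to CSV
#'
#' Long format with columns `time_h`, `conc_mg_gae_per_kg`, `simulant`,
#' `temperature_C`, `replicate`; round-trips through
#' [read_release_csv()].
#'
#' @param curves A [release_curve()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curves, path) {
  if (inherits(curves, "release_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report table
#'
#' Aggregates fit results by (simulant, temperature): mean and sample SD of
#' the fitted D in the 10^-14 m^2/s display convention, alpha in 10^-4, and
#' mean R^2, one row per condition, written as CSV. A JSON sidecar
#' (`<path>.json`) records the seed, options and a content hash so a rerun
#' can be verified byte-for-byte.
#'
#' @param results Nonempty list of `fit_result` objects from
#'   [fit_diffusion()].
#' @param path Output CSV path.
#' @param seed Seed to record in the sidecar.
#' @param options List of run options to record.
#' @return The aggregated data frame, invisibly.
#' @export
write_fit_report <- function(results, path, seed = NA, options = list()) {
  if (inherits(results, "fit_result")) results <- list(results)
  if (!length(results)) stop("'results' is empty", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "fit_result")))

  df <- data.frame(
    simulant = vapply(results, function(r) as.character(r$simulant),
                      character(1)),
    temperature_C = vapply(results, function(r) as.numeric(r$temperature),
                           numeric(1)),
    D = vapply(results, function(r) r$D_hat, numeric(1)),
    alpha = vapply(results, function(r) r$alpha_used, numeric(1)),
    r2 = vapply(results, function(r) r$r_squared, numeric(1)),
    model = vapply(results, function(r) r$model_used, character(1)),
    converged = vapply(results, function(r) r$converged, logical(1)))

  key <- interaction(df$simulant, df$temperature_C, drop = TRUE)
  agg <- do.call(rbind, lapply(levels(key), function(k) {
    g <- df[key == k, , drop = FALSE]
    data.frame(
      simulant = g$simulant[1],
      temperature_C = g$temperature_C[1],
      n = nrow(g),
      D_mean_1e14 = mean(g$D) * 1e14,
      D_sd_1e14 = if (nrow(g) > 1) stats::sd(g$D) * 1e14 else NA_real_,
      alpha_mean_1e4 = mean(g$alpha) * 1e4,
      r2_mean = mean(g$r2),
      model = g$model[1],
      all_converged = all(g$converged))
  }))
  agg <- agg[order(agg$simulant, agg$temperature_C), , drop = FALSE]
  utils::write.csv(format(agg, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)

  meta <- list(seed = seed, options = options,
               n_results = length(results),
               table_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(agg)
}

#' Read a run configuration file
#'
#' YAML configuration driving [run_release_study()]. Recognised fields:
#' `seed` (required), `scenarios` (subset of the preset names),
#' `n_replicates`, `noise_cv`, `n_roots`, `plateau_points`, `output_dir`.
#' Geometry/partition overrides: either `K_FS` with `thickness`, `V_film`,
#' `V_simulant`, or `alpha` directly -- never both.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set 'seed'", call. = FALSE)
  if (!is.null(cfg$K_FS) && !is.null(cfg$alpha))
    stop("config must set at most one of 'K_FS' and 'alpha'", call. = FALSE)
  defaults <- list(scenarios = names(release_scenarios()),
                   n_replicates = NULL, noise_cv = NULL, n_roots = 12L,
                   plateau_points = 3L, output_dir = ".")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  unknown <- setdiff(cfg$scenarios, names(release_scenarios()))
  if (length(unknown))
    stop("unknown scenario(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Simulate, fit and report in one pass
#'
#' The full pipeline behind the command-line interface: generate the
#' synthetic study for the configured scenarios, fit every curve with the
#' scenario's own alpha, and write `curves.csv`, `fit_report.csv` and the
#' JSON sidecar into the output directory. Deterministic: the same
#' configuration yields byte-identical outputs.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @return Invisibly, a list with `curves`, `fits` and the aggregated
#'   report table.
#' @export
run_release_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  scs <- release_scenarios()[config$scenarios]
  curves <- generate_study(config$seed, scenarios = scs,
                           n_replicates = config$n_replicates,
                           noise_cv = config$noise_cv)
  by_name <- rep(config$scenarios,
                 times = vapply(scs, function(s)
                   if (is.null(config$n_replicates)) s$n_replicates
                   else as.integer(config$n_replicates), integer(1)))
  fits <- lapply(seq_along(curves), function(i) {
    sc <- scs[[by_name[i]]]
    fit_diffusion(curves[[i]], scenario_geometry(sc),
                  alpha = sc$alpha_true, n_roots = config$n_roots,
                  plateau_points = config$plateau_points)
  })
  names(fits) <- names(curves)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_release_csv(curves, file.path(config$output_dir, "curves.csv"))
  report <- write_fit_report(
    fits, file.path(config$output_dir, "fit_report.csv"),
    seed = config$seed,
    options = unclass(config)[c("scenarios", "n_replicates", "noise_cv",
                                "n_roots", "plateau_points")])
  invisible(list(curves = curves, fits = fits, report = report))
}
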