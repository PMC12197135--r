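#' Pipeline run configuration
#'
#' Exactly one input source per run: either a long-format landmark CSV
#' (`input_csv`) or simulation (`simulate = TRUE` with a phantom spec and
#' deformation parameters).
#'
#' @param input_csv Path to a long-format landmark CSV, or `NULL`.
#' @param simulate If `TRUE`, generate the study with [simulate_study()].
#' @param spec,params Simulation inputs (see [phantom_spec()],
#'   [deformation_params()]); used only when `simulate = TRUE`.
#' @param out_dir Output directory for the report bundle.
#' @param sd_mode `"sample"` or `"population"` SD convention.
#' @param repeat_stat `"pairwise"` or `"centroid"` repeatability statistic.
#' @param n_repeat_replicates Number of simulated fiducial re-placements of
#'   the baseline scan used for the repeatability report (simulation runs
#'   only).
#' @param strict Strict missing-landmark policy (see [displacement()]).
#' @param seed Integer seed overriding `params$seed`.
#' @param verbose Log progress to the console as well as the run log.
#' @return A `run_config` object.
#' @export
run_config <- function(input_csv = NULL, simulate = is.null(input_csv),
                       spec = phantom_spec(), params = deformation_params(),
                       out_dir = "results",
                       sd_mode = c("sample", "population"),
                       repeat_stat = c("pairwise", "centroid"),
                       n_repeat_replicates = 3L,
                       strict = TRUE, seed = NULL, verbose = FALSE) {
  if (is.null(input_csv) == !isTRUE(simulate)) {
    stop("exactly one input source required: give input_csv OR ",
         "simulate = TRUE", call. = FALSE)
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  structure(list(input_csv = input_csv, simulate = isTRUE(simulate),
                 spec = spec, params = params, out_dir = out_dir,
                 sd_mode = match.arg(sd_mode),
                 repeat_stat = match.arg(repeat_stat),
                 n_repeat_replicates = as.integer(n_repeat_replicates),
                 strict = isTRUE(strict), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Render a comparison table in the wide reporting layout
#'
#' One row per target x comparison level, one column per stratum, cells as
#' `"mean (sd)"` strings rounded to 0.1 mm; missing cells render as an em
#' dash.
#'
#' @param tab A `comparison_table` from [pressure_effect_table()] or
#'   [position_effect_table()].
#' @return A character data frame with columns `target`, `level`, then one
#'   column per stratum.
#' @export
render_wide_table <- function(tab) {
  stopifnot(inherits(tab, "comparison_table"))
  cell <- ifelse(
    is.na(tab$mean_abs_diff_mm), "—",
    sprintf("%.1f (%.1f)", tab$mean_abs_diff_mm, tab$sd_abs_diff_mm)
  )
  strata <- unique(tab$stratum)
  base <- unique(tab[, c("target", "level")])
  out <- base
  for (s in strata) {
    idx <- tab$stratum == s
    m <- stats::setNames(cell[idx],
                         paste(tab$target[idx], tab$level[idx], sep = "."))
    out[[s]] <- unname(m[paste(base$target, base$level, sep = ".")])
  }
  rownames(out) <- NULL
  out
}

#' Tidy distance-matrix export for a study
#'
#' @param sets Named list of [scan_landmark_set()] objects.
#' @return Data frame: `position`, `pressure_mmHg`, `reference`, `target`,
#'   `distance_mm`.
#' @export
distance_table <- function(sets) {
  rows <- lapply(sets, function(s) {
    d <- distance_matrix(s)
    data.frame(position = s$condition$position,
               pressure_mmHg = s$condition$pressure,
               reference = rep(rownames(d), ncol(d)),
               target = rep(colnames(d), each = nrow(d)),
               distance_mm = as.numeric(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> measure distances -> build both comparison tables
#' -> repeatability -> surrogate-vs-truth (simulation runs), writing a
#' report bundle under `cfg$out_dir`: tidy and wide CSVs for each table
#' plus a run log recording exclusions and convention choices.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the report bundle: list with `sets`, `distances`,
#'   `pressure_table`, `position_table`, `repeatability`,
#'   `surrogate_truth` (simulation only), `log`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (cfg$verbose) message(msg)
  }
  study <- NULL
  if (cfg$simulate) {
    say("input: simulation (seed ", cfg$params$seed,
        ", noise sigma ", cfg$params$noise_sigma, " mm)")
    study <- simulate_study(cfg$spec, cfg$params)
    sets <- study$sets
  } else {
    say("input: ", cfg$input_csv)
    sets <- read_long_csv(cfg$input_csv)
  }
  say("loaded ", length(sets), " scan condition(s)")
  for (s in sets) {
    excl <- names(s$excluded)[s$excluded]
    if (length(excl)) {
      say("excluded in ", format(s$condition), ": ",
          paste(excl, collapse = ", "))
    }
  }
  say("SD convention: ", cfg$sd_mode, "; missing-landmark policy: ",
      if (cfg$strict) "strict" else "permissive")

  distances <- distance_table(sets)
  pres <- pressure_effect_table(sets, sd_mode = cfg$sd_mode,
                                strict = cfg$strict)
  post <- position_effect_table(sets, sd_mode = cfg$sd_mode,
                                strict = cfg$strict)
  for (tab in list(pres, post)) {
    ms <- attr(tab, "missing_strata"); ml <- attr(tab, "missing_levels")
    if (length(ms)) say(attr(tab, "layout"), ": missing strata ",
                        paste(ms, collapse = ", "))
    if (length(ml)) say(attr(tab, "layout"), ": missing levels ",
                        paste(ml, collapse = ", "))
    n_miss <- sum(is.na(tab$mean_abs_diff_mm))
    if (n_miss) say(attr(tab, "layout"), ": ", n_miss, " missing cell(s)")
  }

  repeat_tab <- NULL
  if (cfg$simulate && cfg$n_repeat_replicates >= 2L) {
    baseline <- generate_phantom(cfg$spec)
    set.seed(cfg$params$seed + 1L)
    reps <- replicate(cfg$n_repeat_replicates,
                      add_placement_noise(baseline,
                                          cfg$params$noise_sigma),
                      simplify = FALSE)
    repeat_tab <- repeatability(reps, statistic = cfg$repeat_stat,
                                pool = TRUE)
    say("repeatability over ", cfg$n_repeat_replicates,
        " simulated re-placements (", cfg$repeat_stat, " statistic)")
  }

  sv_truth <- NULL
  if (!is.null(study)) {
    sv_truth <- surrogate_vs_truth(study, sd_mode = cfg$sd_mode)
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    distances = file.path(cfg$out_dir, "distances.csv"),
    pressure_tidy = file.path(cfg$out_dir, "pressure_effect_tidy.csv"),
    pressure_wide = file.path(cfg$out_dir, "pressure_effect_wide.csv"),
    position_tidy = file.path(cfg$out_dir, "position_effect_tidy.csv"),
    position_wide = file.path(cfg$out_dir, "position_effect_wide.csv"),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  utils::write.csv(distances, files[["distances"]], row.names = FALSE)
  utils::write.csv(as.data.frame(pres), files[["pressure_tidy"]],
                   row.names = FALSE)
  utils::write.csv(render_wide_table(pres), files[["pressure_wide"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(post), files[["position_tidy"]],
                   row.names = FALSE)
  utils::write.csv(render_wide_table(post), files[["position_wide"]],
                   row.names = FALSE)
  if (!is.null(repeat_tab)) {
    files[["repeatability"]] <- file.path(cfg$out_dir, "repeatability.csv")
    utils::write.csv(repeat_tab, files[["repeatability"]], row.names = FALSE)
  }
  if (!is.null(sv_truth)) {
    files[["surrogate_truth"]] <- file.path(cfg$out_dir,
                                            "surrogate_vs_truth.csv")
    utils::write.csv(sv_truth, files[["surrogate_truth"]],
                     row.names = FALSE)
  }
  writeLines(log_lines, files[["log"]])

  invisible(list(sets = sets, distances = distances, pressure_table = pres,
                 position_table = post, repeatability = repeat_tab,
                 surrogate_truth = sv_truth, log = log_lines,
                 files = files))
}
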