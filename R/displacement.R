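#' Reference-to-target distance matrix
#'
#' Euclidean distances (mm) from every active bony reference to every
#' active target in one scan. Excluded landmarks (R7, skin fiducials, or
#' anything flagged in the set) are omitted. Because only intra-scan
#' distances are used, the matrix is invariant under any rigid motion of
#' the whole scan -- the property that makes the downstream displacement
#' statistic registration-free.
#'
#' @param set A [scan_landmark_set()].
#' @return A `distance_matrix` object: numeric matrix with reference codes
#'   as rownames and target codes as colnames, plus a `condition`
#'   attribute.
#' @export
distance_matrix <- function(set) {
  stopifnot(inherits(set, "scan_landmark_set"))
  refs <- active_references(set)
  tgts <- active_targets(set)
  if (!nrow(refs)) {
    stop("no active reference landmarks in scan ", format(set$condition),
         call. = FALSE)
  }
  if (!nrow(tgts)) {
    stop("no active target landmarks in scan ", format(set$condition),
         call. = FALSE)
  }
  # per-target coordinate differences (precision-safe at torso scales)
  d <- vapply(seq_len(nrow(tgts)), function(k) {
    sqrt(rowSums(sweep(refs, 2, tgts[k, ])^2))
  }, numeric(nrow(refs)))
  d <- matrix(d, nrow(refs), nrow(tgts),
              dimnames = list(rownames(refs), rownames(tgts)))
  structure(d, condition = set$condition, class = c("distance_matrix",
                                                    class(d)))
}

#' Displacement surrogate between two scans for one target
#'
#' The registration-free displacement statistic: for each bony reference
#' present (and active) in both scans, take the absolute difference of the
#' reference-to-target distance between the two scans, then average over
#' references. By the reverse triangle inequality each per-reference term
#' is a lower bound on the target's true displacement in the bony frame,
#' so (with noise-free references) the mean under-reports true motion.
#'
#' @param baseline,comparison [scan_landmark_set()] objects.
#' @param target Target landmark code (e.g. `"P1"`).
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`.
#' @param strict If `TRUE` (default), require all six bony references
#'   R1--R6 in both scans; if `FALSE`, compute over the common active
#'   reference subset (>= 2 references).
#' @return A one-row data frame: `target`, baseline/comparison condition
#'   columns, `mean_abs_diff_mm`, `sd_abs_diff_mm`, `n_references`.
#' @export
displacement <- function(baseline, comparison, target,
                         sd_mode = c("sample", "population"),
                         strict = TRUE) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(baseline, "scan_landmark_set"),
            inherits(comparison, "scan_landmark_set"))
  for (s in list(baseline, comparison)) {
    if (!target %in% rownames(active_targets(s))) {
      stop("target ", target, " missing (or excluded) in scan ",
           format(s$condition), call. = FALSE)
    }
  }
  refs_b <- active_references(baseline)
  refs_c <- active_references(comparison)
  common <- intersect(rownames(refs_b), rownames(refs_c))
  if (strict && !all(paste0("R", 1:6) %in% common)) {
    stop("strict mode requires references R1-R6 in both scans; missing: ",
         paste(setdiff(paste0("R", 1:6), common), collapse = ", "),
         call. = FALSE)
  }
  if (length(common) < 2L) {
    stop("need >= 2 common references between scans (SD undefined); ",
         "found ", length(common), call. = FALSE)
  }
  tb <- baseline$landmarks[target, ]
  tc <- comparison$landmarks[target, ]
  db <- sqrt(rowSums(sweep(refs_b[common, , drop = FALSE], 2, tb)^2))
  dc <- sqrt(rowSums(sweep(refs_c[common, , drop = FALSE], 2, tc)^2))
  delta <- abs(db - dc)
  n <- length(delta)
  sd_val <- if (sd_mode == "sample") stats::sd(delta) else {
    sqrt(mean((delta - mean(delta))^2))
  }
  data.frame(
    target = target,
    baseline_position = baseline$condition$position,
    baseline_pressure = baseline$condition$pressure,
    comparison_position = comparison$condition$position,
    comparison_pressure = comparison$condition$pressure,
    mean_abs_diff_mm = mean(delta),
    sd_abs_diff_mm = sd_val,
    n_references = n,
    stringsAsFactors = FALSE
  )
}

study_lookup <- function(study) {
  stopifnot(is.list(study), length(study) > 0)
  keys <- vapply(study, function(s) condition_key(s$condition), "")
  if (anyDuplicated(keys)) {
    stop("study contains duplicate scan conditions: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(study, keys)
}

build_comparison_table <- function(study, layout, sd_mode, strict) {
  sets <- study_lookup(study)
  positions <- unique(vapply(sets, function(s) s$condition$position, ""))
  pressures <- unique(vapply(sets, function(s) s$condition$pressure, 0))
  targets <- paste0("P", 1:7)
  if (layout == "pressure_effect") {
    strata <- intersect(scan_positions(), positions)
    levels <- setdiff(scan_pressures(), 0)
    baseline_of <- function(stratum) sprintf("%s|0", stratum)
    cell_of <- function(stratum, level) sprintf("%s|%g", stratum, level)
    for (pos in strata) {
      others <- any(sprintf("%s|%g", pos, levels) %in% names(sets))
      if (others && !baseline_of(pos) %in% names(sets)) {
        stop("no 0 mmHg baseline scan for position '", pos, "'",
             call. = FALSE)
      }
    }
    strata <- strata[vapply(strata, function(p)
      baseline_of(p) %in% names(sets), TRUE)]
  } else {
    strata <- intersect(scan_pressures(), pressures)
    levels <- setdiff(scan_positions(), "supine")
    baseline_of <- function(stratum) sprintf("supine|%g", stratum)
    cell_of <- function(stratum, level) sprintf("%s|%g", level, stratum)
    for (pr in strata) {
      others <- any(sprintf("%s|%g", levels, pr) %in% names(sets))
      if (others && !baseline_of(pr) %in% names(sets)) {
        stop("no supine baseline scan at ", pr, " mmHg", call. = FALSE)
      }
    }
    strata <- strata[vapply(strata, function(p)
      baseline_of(p) %in% names(sets), TRUE)]
  }
  missing_strata <- if (layout == "pressure_effect") {
    setdiff(scan_positions(), strata)
  } else setdiff(scan_pressures(), strata)
  # levels absent from the whole study are dropped (and flagged), not padded
  present_level <- function(level) {
    any(vapply(strata, function(s) cell_of(s, level) %in% names(sets), TRUE))
  }
  missing_levels <- levels[!vapply(levels, present_level, TRUE)]
  levels <- setdiff(levels, missing_levels)

  rows <- list()
  for (stratum in strata) {
    base <- sets[[baseline_of(stratum)]]
    for (level in levels) {
      comp <- sets[[cell_of(stratum, level)]]
      for (tg in targets) {
        absent_target <- !strict && !is.null(comp) &&
          !(tg %in% rownames(active_targets(base)) &&
              tg %in% rownames(active_targets(comp)))
        if (is.null(comp) || absent_target) {
          row <- data.frame(
            target = tg, stratum = as.character(stratum),
            level = as.character(level),
            mean_abs_diff_mm = NA_real_, sd_abs_diff_mm = NA_real_,
            n_references = NA_integer_, stringsAsFactors = FALSE
          )
        } else {
          d <- displacement(base, comp, tg, sd_mode = sd_mode,
                            strict = strict)
          row <- data.frame(
            target = tg, stratum = as.character(stratum),
            level = as.character(level),
            mean_abs_diff_mm = d$mean_abs_diff_mm,
            sd_abs_diff_mm = d$sd_abs_diff_mm,
            n_references = d$n_references, stringsAsFactors = FALSE
          )
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, layout = layout, missing_strata = missing_strata,
            missing_levels = as.character(missing_levels), sd_mode = sd_mode,
            class = c("comparison_table", "data.frame"))
}

#' Pressure-effect comparison table
#'
#' For each patient position (stratum) and each non-zero intra-abdominal
#' pressure, the displacement surrogate of every target versus that
#' position's 0 mmHg baseline scan. On a full 20-condition study this
#' yields 7 targets x 3 pressures x 5 positions = 105 cells. Cells whose
#' comparison scan is absent are reported missing (`NA`), never zero.
#'
#' @param study List of [scan_landmark_set()] objects.
#' @inheritParams displacement
#' @return A `comparison_table` data frame (columns `target`, `stratum`,
#'   `level`, `mean_abs_diff_mm`, `sd_abs_diff_mm`, `n_references`) with
#'   attributes `layout` and `missing_strata`.
#' @export
pressure_effect_table <- function(study, sd_mode = c("sample", "population"),
                                  strict = TRUE) {
  build_comparison_table(study, "pressure_effect", match.arg(sd_mode), strict)
}

#' Position-effect comparison table
#'
#' For each pressure level (stratum) and each non-supine position, the
#' displacement surrogate of every target versus the supine scan at that
#' pressure: 7 targets x 4 positions x 4 pressures = 112 cells on a full
#' study.
#'
#' @inheritParams pressure_effect_table
#' @return A `comparison_table` data frame; see [pressure_effect_table()].
#' @export
position_effect_table <- function(study, sd_mode = c("sample", "population"),
                                  strict = TRUE) {
  build_comparison_table(study, "position_effect", match.arg(sd_mode), strict)
}

#' Fiducial placement repeatability
#'
#' Quantifies how reproducibly an operator re-places the same virtual
#' fiducial: across replicate placements of one scan, either the mean
#' pairwise Euclidean distance between placements (default) or the mean
#' distance of each placement to the replicate centroid.
#'
#' @param replicates List of [scan_landmark_set()] objects sharing one scan
#'   condition (>= 2 replicates).
#' @param statistic `"pairwise"` (all unordered replicate pairs, default)
#'   or `"centroid"` (distance to the replicate centroid).
#' @param pool If `TRUE`, additionally pool the per-placement statistics
#'   across landmarks by role, matching the reporting split into bone
#'   reference markers and anatomical target markers.
#' @return A data frame with columns `landmark`, `role`, `n_replicates`,
#'   `mean_mm`, `sd_mm`, `statistic`. With `pool = TRUE`, pooled rows have
#'   `landmark` `"pooled_reference"` / `"pooled_target"`.
#' @export
repeatability <- function(replicates, statistic = c("pairwise", "centroid"),
                          pool = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  conds <- unique(vapply(replicates, function(s) condition_key(s$condition),
                         ""))
  if (length(conds) != 1L) {
    stop("replicates must share a single scan condition; found: ",
         paste(conds, collapse = ", "), call. = FALSE)
  }
  all_codes <- unique(unlist(lapply(replicates,
                                    function(s) rownames(s$landmarks))))
  per_landmark <- list()
  pooled_values <- list(reference = numeric(0), target = numeric(0))
  for (code in all_codes) {
    placements <- do.call(rbind, lapply(replicates, function(s) {
      if (code %in% rownames(s$landmarks)) s$landmarks[code, , drop = FALSE]
    }))
    if (is.null(placements) || nrow(placements) < 2L) {
      warning("landmark ", code, " present in < 2 replicates; excluded ",
              "from repeatability", call. = FALSE)
      next
    }
    vals <- if (statistic == "pairwise") {
      as.numeric(stats::dist(placements))
    } else {
      ctr <- colMeans(placements)
      sqrt(rowSums(sweep(placements, 2, ctr)^2))
    }
    role <- landmark_role(code)
    if (!is.na(role)) {
      pooled_values[[role]] <- c(pooled_values[[role]], vals)
    }
    per_landmark[[length(per_landmark) + 1L]] <- data.frame(
      landmark = code, role = role, n_replicates = nrow(placements),
      mean_mm = mean(vals),
      sd_mm = if (length(vals) > 1L) stats::sd(vals) else 0,
      statistic = statistic, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, per_landmark)
  if (pool) {
    for (role in c("reference", "target")) {
      vals <- pooled_values[[role]]
      if (!length(vals)) next
      out <- rbind(out, data.frame(
        landmark = paste0("pooled_", role), role = role,
        n_replicates = length(replicates), mean_mm = mean(vals),
        sd_mm = stats::sd(vals), statistic = statistic,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}
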