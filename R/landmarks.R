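#' Landmark vocabulary
#'
#' The closed set of anatomical landmarks used throughout the package:
#' six bony reference points (`R1`--`R6`) that define the rigid skeletal
#' frame, one reference recognised but excluded by default (`R7`, the distal
#' sternum tip, which moves with abdominal expansion), and seven
#' retroperitoneal vascular/organ targets (`P1`--`P7`).
#'
#' Skin fiducials (any code prefixed `SKIN_`) are likewise recognised on
#' input but flagged excluded by default: they move unpredictably with
#' patient repositioning and are unusable as a fixed matrix.
#'
#' @return A data frame with columns `code`, `role`
#'   (`"reference"`/`"target"`), `description` and `excluded_default`.
#' @export
landmark_vocabulary <- function() {
  data.frame(
    code = c(paste0("R", 1:7), paste0("P", 1:7)),
    role = c(rep("reference", 7L), rep("target", 7L)),
    description = c(
      "Right anterior superior iliac spine",
      "Left anterior superior iliac spine",
      "Symphysis (upper edge)",
      "First sacral vertebra",
      "Tip of the left XII rib",
      "Tip of the right XII rib",
      "Distal tip of the sternum",
      "Aortic bifurcation",
      "Left renal artery",
      "Right renal artery",
      "Hilum of the left kidney",
      "Hilum of the right kidney",
      "Superior mesenteric artery",
      "Celiac artery"
    ),
    excluded_default = c(rep(FALSE, 6L), TRUE, rep(FALSE, 7L)),
    stringsAsFactors = FALSE
  )
}

#' Role of a landmark code
#'
#' @param code Character vector of landmark codes.
#' @return `"reference"`, `"target"`, or `NA` for codes outside the
#'   vocabulary (skin fiducials `SKIN_*` count as references).
#' @export
landmark_role <- function(code) {
  role <- rep(NA_character_, length(code))
  role[code %in% paste0("R", 1:7) | startsWith(code, "SKIN_")] <- "reference"
  role[code %in% paste0("P", 1:7)] <- "target"
  role
}

#' Default exclusion flag for a landmark code
#'
#' `R7` and skin fiducials are excluded from analysis by default; every
#' other vocabulary code is included. Codes outside the vocabulary are
#' excluded (they carry no anatomical meaning for the analysis).
#'
#' @param code Character vector of landmark codes.
#' @return Logical vector.
#' @export
landmark_excluded_default <- function(code) {
  known <- code %in% c(paste0("R", 1:6), paste0("P", 1:7))
  !known | startsWith(code, "SKIN_")
}

#' Scan positions and pressures
#'
#' The study's factorial design: five patient positions crossed with four
#' intra-abdominal pressure (IAP) levels, giving 20 scan conditions.
#'
#' @name study-design
NULL

#' @rdname study-design
#' @export
scan_positions <- function() {
  c("supine", "left_lateral_decubitus_45", "right_lateral_decubitus_45",
    "trendelenburg_15", "reverse_trendelenburg_15")
}

#' @rdname study-design
#' @export
scan_pressures <- function() c(0, 5, 15, 25)

#' @rdname study-design
#' @return `study_conditions()`: a data frame of all position x pressure
#'   combinations (20 rows).
#' @export
study_conditions <- function() {
  expand.grid(
    position = scan_positions(),
    pressure = scan_pressures(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("position", "pressure")]
}

#' Construct a scan condition
#'
#' @param position One of [scan_positions()].
#' @param pressure Intra-abdominal pressure in mmHg, one of
#'   [scan_pressures()].
#' @return A `scan_condition` object.
#' @export
scan_condition <- function(position, pressure) {
  if (length(position) != 1L || !position %in% scan_positions()) {
    stop("unknown position '", position, "'; allowed: ",
         paste(scan_positions(), collapse = ", "), call. = FALSE)
  }
  pressure <- as.numeric(pressure)
  if (length(pressure) != 1L || !pressure %in% scan_pressures()) {
    stop("unknown pressure '", pressure, "' mmHg; allowed: ",
         paste(scan_pressures(), collapse = ", "), call. = FALSE)
  }
  structure(list(position = position, pressure = pressure),
            class = "scan_condition")
}

#' @export
format.scan_condition <- function(x, ...) {
  sprintf("%s @ %g mmHg", x$position, x$pressure)
}

#' @export
print.scan_condition <- function(x, ...) {
  cat("<scan_condition>", format(x), "\n")
  invisible(x)
}

condition_key <- function(cond) sprintf("%s|%g", cond$position, cond$pressure)

#' Construct a scan landmark set
#'
#' One scan's fiducial observations: named 3-D positions in millimetres,
#' right-anterior-superior (RAS) patient frame, plus per-landmark exclusion
#' flags.
#'
#' @param condition A [scan_condition()].
#' @param landmarks Numeric matrix, one row per landmark, 3 columns (x, y, z
#'   in mm, RAS); rownames are landmark codes.
#' @param excluded Optional named logical vector overriding the default
#'   exclusion flags ([landmark_excluded_default()]).
#' @param provenance Free-text source tag.
#' @return A `scan_landmark_set` object.
#' @export
scan_landmark_set <- function(condition, landmarks,
                              excluded = NULL, provenance = "") {
  stopifnot(inherits(condition, "scan_condition"))
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 3L) {
    stop("landmark matrix must have 3 columns (x, y, z in mm)", call. = FALSE)
  }
  codes <- rownames(landmarks)
  if (is.null(codes) || anyNA(codes) || any(codes == "")) {
    stop("landmark matrix must have landmark codes as rownames", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop("duplicate landmark code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(landmarks))) {
    stop("landmark positions must be finite", call. = FALSE)
  }
  colnames(landmarks) <- c("x", "y", "z")
  storage.mode(landmarks) <- "double"
  excl <- landmark_excluded_default(codes)
  names(excl) <- codes
  if (!is.null(excluded)) {
    stopifnot(is.logical(excluded), !is.null(names(excluded)))
    excl[intersect(names(excluded), codes)] <-
      excluded[intersect(names(excluded), codes)]
  }
  structure(
    list(condition = condition, landmarks = landmarks,
         excluded = excl, provenance = provenance),
    class = "scan_landmark_set"
  )
}

#' @export
print.scan_landmark_set <- function(x, ...) {
  cat("<scan_landmark_set>", format(x$condition), "\n")
  cat("  ", nrow(x$landmarks), "landmarks (",
      sum(!x$excluded & landmark_role(rownames(x$landmarks)) == "reference",
          na.rm = TRUE), "active references,",
      sum(!x$excluded & landmark_role(rownames(x$landmarks)) == "target",
          na.rm = TRUE), "active targets )\n")
  if (nzchar(x$provenance)) cat("   source:", x$provenance, "\n")
  invisible(x)
}

#' Active references / targets of a scan landmark set
#'
#' Positions of the non-excluded landmarks of a given role, as a coordinate
#' matrix with landmark codes as rownames.
#'
#' @param set A [scan_landmark_set()].
#' @return Numeric matrix (n x 3, mm).
#' @export
active_references <- function(set) {
  stopifnot(inherits(set, "scan_landmark_set"))
  codes <- rownames(set$landmarks)
  keep <- !set$excluded & !is.na(landmark_role(codes)) &
    landmark_role(codes) == "reference"
  set$landmarks[keep, , drop = FALSE]
}

#' @rdname active_references
#' @export
active_targets <- function(set) {
  stopifnot(inherits(set, "scan_landmark_set"))
  codes <- rownames(set$landmarks)
  keep <- !set$excluded & !is.na(landmark_role(codes)) &
    landmark_role(codes) == "target"
  set$landmarks[keep, , drop = FALSE]
}

#' Is a landmark set analysis-complete?
#'
#' A set is analysis-complete when all six bony references R1--R6 are
#' present (and active) together with at least one active target.
#'
#' @param set A [scan_landmark_set()].
#' @return Logical scalar.
#' @export
analysis_complete <- function(set) {
  refs <- rownames(active_references(set))
  all(paste0("R", 1:6) %in% refs) && nrow(active_targets(set)) >= 1L
}
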