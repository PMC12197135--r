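#' Default landmark label aliases
#'
#' Maps free-text fiducial labels, as commonly used when marking CT
#' angiography images, onto the package's landmark codes (e.g. `BIF` for
#' the aortic bifurcation `P1`, `L_REN` for the left renal artery `P2`).
#' Codes that are already in the vocabulary map to themselves.
#'
#' @return Named character vector: names are input labels, values codes.
#' @export
default_landmark_aliases <- function() {
  cfg <- system.file("extdata", "landmark_aliases.yaml",
                     package = "pneumoshift", mustWork = TRUE)
  read_landmark_config(cfg)$aliases
}

#' Read a landmark alias/exclusion configuration
#'
#' The YAML file has an `aliases` map (label to landmark code), an
#' `excluded` list of codes excluded from analysis, and a
#' `prefix_excluded` list of label prefixes (by default `SKIN_`) treated
#' the same way.
#'
#' @param path Path to a YAML file.
#' @return List with components `aliases` (named character vector),
#'   `excluded` (character) and `prefix_excluded` (character).
#' @export
read_landmark_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  aliases <- unlist(cfg$aliases %||% list())
  vocab <- landmark_vocabulary()$code
  aliases <- c(aliases, stats::setNames(vocab, vocab))
  aliases <- aliases[!duplicated(names(aliases))]
  bad <- setdiff(unname(aliases), vocab)
  if (length(bad)) {
    stop("alias config maps to unknown landmark code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(
    aliases = aliases,
    excluded = as.character(unlist(cfg$excluded %||% "R7")),
    prefix_excluded = as.character(unlist(cfg$prefix_excluded %||% "SKIN_"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 3D Slicer markups fiducial file (FCSV)
#'
#' Parses the versioned `# Markups fiducial file` comment-header dialect.
#' The header must declare a coordinate system (`RAS`, `LPS`, or the
#' numeric legacy codes `0`/`1`); LPS coordinates are converted to the
#' package's canonical RAS frame by negating x and y. Labels are mapped to
#' landmark codes through an alias table; labels that remain unmapped are
#' retained with a warning and flagged excluded.
#'
#' @param path Path to an `.fcsv` file.
#' @param condition The [scan_condition()] the file was acquired under.
#' @param aliases Named character vector mapping labels to landmark codes;
#'   defaults to [default_landmark_aliases()].
#' @return A [scan_landmark_set()] in RAS millimetres.
#' @export
read_fcsv <- function(path, condition, aliases = default_landmark_aliases()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  if (!length(header) || !grepl("Markups fiducial file", header[1])) {
    stop("malformed FCSV header at line 1: expected '# Markups fiducial ",
         "file version = ...', got '",
         if (length(lines)) lines[1] else "<empty file>", "'", call. = FALSE)
  }
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  if (!length(cs_line)) {
    stop("FCSV header declares no CoordinateSystem (refusing to guess ",
         "between RAS and LPS): ", path, call. = FALSE)
  }
  cs <- toupper(trimws(sub(".*CoordinateSystem\\s*=\\s*", "", cs_line[1])))
  cs <- switch(cs, "RAS" = "RAS", "0" = "RAS", "LPS" = "LPS", "1" = "LPS",
               stop("unrecognised CoordinateSystem '", cs, "' in ", path,
                    call. = FALSE))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) {
    return(scan_landmark_set(condition,
                             matrix(numeric(0), 0, 3,
                                    dimnames = list(NULL, c("x", "y", "z"))),
                             provenance = path))
  }
  df <- utils::read.csv(text = body, header = FALSE,
                        stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 12L) {
    stop("malformed FCSV data rows in ", path,
         ": expected >= 12 comma-separated fields, found ", ncol(df),
         call. = FALSE)
  }
  xyz <- as.matrix(df[, 2:4])
  if (!is.numeric(xyz) || anyNA(xyz)) {
    stop("non-numeric coordinates in FCSV data of ", path, call. = FALSE)
  }
  if (cs == "LPS") xyz[, 1:2] <- -xyz[, 1:2]
  labels <- trimws(as.character(df[, 12]))
  if (anyDuplicated(labels)) {
    stop("duplicate fiducial label(s) in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  codes <- unname(aliases[labels])
  unmapped <- is.na(codes)
  if (any(unmapped)) {
    warning("unmapped fiducial label(s) retained but excluded from ",
            "analysis: ", paste(labels[unmapped], collapse = ", "),
            call. = FALSE)
    codes[unmapped] <- labels[unmapped]
  }
  rownames(xyz) <- codes
  scan_landmark_set(condition, xyz, provenance = path)
}

#' Write a scan landmark set as a Slicer FCSV file
#'
#' @param set A [scan_landmark_set()].
#' @param path Output path.
#' @param coordinate_system `"RAS"` (default) or `"LPS"`.
#' @return `path`, invisibly.
#' @export
write_fcsv <- function(set, path, coordinate_system = c("RAS", "LPS")) {
  stopifnot(inherits(set, "scan_landmark_set"))
  coordinate_system <- match.arg(coordinate_system)
  xyz <- set$landmarks
  if (coordinate_system == "LPS" && nrow(xyz)) xyz[, 1:2] <- -xyz[, 1:2]
  codes <- rownames(set$landmarks)
  rows <- sprintf(
    "vtkMRMLMarkupsFiducialNode_%d,%s,%s,%s,0,0,0,1,1,1,0,%s,,",
    seq_len(nrow(xyz)) - 1L,
    sprintf("%.17g", xyz[, 1]), sprintf("%.17g", xyz[, 2]),
    sprintf("%.17g", xyz[, 3]), codes
  )
  writeLines(c(
    "# Markups fiducial file version = 4.11",
    paste0("# CoordinateSystem = ", coordinate_system),
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    rows
  ), path)
  invisible(path)
}

long_csv_columns <- c("position", "pressure_mmHg", "landmark",
                      "x_mm", "y_mm", "z_mm")

#' Read a long-format landmark CSV
#'
#' One row per landmark observation, with columns `position`,
#' `pressure_mmHg`, `landmark`, `x_mm`, `y_mm`, `z_mm` and optionally
#' `excluded`. Rows are grouped into one [scan_landmark_set()] per distinct
#' (position, pressure) condition; row order is irrelevant.
#'
#' @param path Path to a CSV file.
#' @return Named list of `scan_landmark_set` objects, keyed
#'   `"<position>|<pressure>"`.
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(position = "character",
                                       landmark = "character"))
  missing_cols <- setdiff(long_csv_columns, names(df))
  if (length(missing_cols)) {
    stop("long-format CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) return(structure(list(), names = character(0)))
  for (col in c("x_mm", "y_mm", "z_mm", "pressure_mmHg")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric value in column '", col, "' at data row ",
           which(is.na(v))[1], call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_pos <- setdiff(unique(df$position), scan_positions())
  if (length(bad_pos)) {
    stop("unknown position value(s): ", paste(bad_pos, collapse = ", "),
         "; allowed: ", paste(scan_positions(), collapse = ", "),
         call. = FALSE)
  }
  bad_p <- setdiff(unique(df$pressure_mmHg), scan_pressures())
  if (length(bad_p)) {
    stop("unknown pressure value(s): ", paste(bad_p, collapse = ", "),
         " mmHg; allowed: ", paste(scan_pressures(), collapse = ", "),
         call. = FALSE)
  }
  key <- sprintf("%s|%g", df$position, df$pressure_mmHg)
  sets <- lapply(split(df, key), function(g) {
    xyz <- as.matrix(g[, c("x_mm", "y_mm", "z_mm")])
    rownames(xyz) <- g$landmark
    excl <- NULL
    if ("excluded" %in% names(g)) {
      excl <- stats::setNames(as.logical(g$excluded), g$landmark)
    }
    scan_landmark_set(scan_condition(g$position[1], g$pressure_mmHg[1]),
                      xyz, excluded = excl, provenance = path)
  })
  sets[order(names(sets))]
}

#' Write scan landmark sets as a long-format CSV
#'
#' Coordinates are serialised at full double precision, so
#' `read_long_csv(write_long_csv(sets))` reproduces the input bit-exactly.
#'
#' @param sets A list of [scan_landmark_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(sets, path) {
  if (inherits(sets, "scan_landmark_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    stopifnot(inherits(s, "scan_landmark_set"))
    if (!nrow(s$landmarks)) return(NULL)
    data.frame(
      position = s$condition$position,
      pressure_mmHg = s$condition$pressure,
      landmark = rownames(s$landmarks),
      x_mm = sprintf("%.17g", s$landmarks[, 1]),
      y_mm = sprintf("%.17g", s$landmarks[, 2]),
      z_mm = sprintf("%.17g", s$landmarks[, 3]),
      excluded = unname(s$excluded),
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (is.null(out)) {
    out <- data.frame(position = character(0), pressure_mmHg = numeric(0),
                      landmark = character(0), x_mm = character(0),
                      y_mm = character(0), z_mm = character(0),
                      excluded = logical(0))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
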