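#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric vector, mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 numeric matrix (or length-3 vector), mm.
#' @return Transformed points, same shape and rownames.
#' @export
apply_rigid <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, 1L, 3L) else as.matrix(points)
  out <- pts %*% t(transform$rotation) +
    matrix(transform$translation, nrow(pts), 3L, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Homogeneous 4x4 form of a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return 4x4 numeric matrix.
#' @export
homogeneous_matrix <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
}

#' @rdname homogeneous_matrix
#' @param m A 4x4 homogeneous matrix.
#' @export
rigid_from_homogeneous <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4L, 4L)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Least-squares rigid registration of reference constellations (Kabsch)
#'
#' Fits the rigid transform (rotation + translation, no scaling, no
#' reflection) that maps reference set A onto reference set B in the
#' least-squares sense, via SVD of the cross-covariance of the centred
#' point sets. Used to express scans in a common bony frame so that true
#' target displacement can be measured.
#'
#' @param refs_A,refs_B n x 3 coordinate matrices (mm) with landmark codes
#'   as rownames; only codes common to both are used.
#' @return A `registration_report`: list with the fitted `transform`
#'   (A onto B), `fre` (root-mean-square residual over references after
#'   alignment, mm), and `per_reference_residuals` (named vector, mm).
#' @export
fit_rigid <- function(refs_A, refs_B) {
  refs_A <- as.matrix(refs_A); refs_B <- as.matrix(refs_B)
  common <- intersect(rownames(refs_A), rownames(refs_B))
  if (length(common) < 3L) {
    stop("rigid registration needs >= 3 common references; found ",
         length(common), call. = FALSE)
  }
  A <- refs_A[common, , drop = FALSE]
  B <- refs_B[common, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(Ac)$d
  if (sv[2] < 1e-6 * sv[1]) {
    stop("degenerate (collinear) reference geometry: singular value ratio ",
         format(sv[2] / sv[1], digits = 3), call. = FALSE)
  }
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - drop(R %*% ca)
  transform <- rigid_transform(R, tr)
  resid_vec <- apply_rigid(transform, A) - B
  residuals <- sqrt(rowSums(resid_vec^2))
  names(residuals) <- common
  structure(list(transform = transform,
                 fre = sqrt(mean(residuals^2)),
                 per_reference_residuals = residuals),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat("<registration_report> FRE =", format(x$fre, digits = 4), "mm over",
      length(x$per_reference_residuals), "references\n")
  invisible(x)
}

#' True target displacement in the bony frame
#'
#' Ground-truth counterpart of the registration-free surrogate: the
#' comparison scan is rigidly registered onto the baseline scan using the
#' active bony references only, and the target's residual motion after
#' alignment is reported. Invariant to any common rigid motion of both
#' scans.
#'
#' @inheritParams displacement
#' @return Displacement in mm (scalar).
#' @export
true_displacement <- function(baseline, comparison, target) {
  stopifnot(inherits(baseline, "scan_landmark_set"),
            inherits(comparison, "scan_landmark_set"))
  for (s in list(baseline, comparison)) {
    if (!target %in% rownames(active_targets(s))) {
      stop("target ", target, " missing (or excluded) in scan ",
           format(s$condition), call. = FALSE)
    }
  }
  fit <- fit_rigid(active_references(comparison),
                   active_references(baseline))
  aligned <- apply_rigid(fit$transform, comparison$landmarks[target, ])
  sqrt(sum((aligned - baseline$landmarks[target, ])^2))
}

#' Surrogate versus ground truth over a synthetic study
#'
#' For every comparison performed by [pressure_effect_table()] and
#' [position_effect_table()], tabulates the registration-free surrogate
#' next to the simulator's exact ground-truth displacement (noiseless
#' soft-tissue motion in the bony frame). The ratio surrogate/truth
#' quantifies how much the surrogate under-reports true motion; it is
#' defined as 1 when both are below 1e-9 mm, and flagged undefined
#' (`NA`) when truth is ~0 but the surrogate is not (placement noise).
#'
#' @param study A [simulate_study()] result (carries ground truth).
#' @inheritParams displacement
#' @return Data frame: `layout`, `target`, `stratum`, `level`,
#'   `surrogate_mm`, `truth_mm`, `ratio`.
#' @export
surrogate_vs_truth <- function(study, sd_mode = c("sample", "population")) {
  stopifnot(inherits(study, "synthetic_study"))
  sd_mode <- match.arg(sd_mode)
  gt <- study$ground_truth
  truth_between <- function(key_b, key_c, target) {
    sqrt(sum((gt[[key_c]][target, ] - gt[[key_b]][target, ])^2))
  }
  rows <- list()
  for (layout in c("pressure_effect", "position_effect")) {
    tab <- build_comparison_table(study$sets, layout, sd_mode, strict = TRUE)
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      if (is.na(r$mean_abs_diff_mm)) next
      if (layout == "pressure_effect") {
        key_b <- sprintf("%s|0", r$stratum)
        key_c <- sprintf("%s|%s", r$stratum, r$level)
      } else {
        key_b <- sprintf("supine|%s", r$stratum)
        key_c <- sprintf("%s|%s", r$level, r$stratum)
      }
      truth <- truth_between(key_b, key_c, r$target)
      surr <- r$mean_abs_diff_mm
      ratio <- if (surr < 1e-9 && truth < 1e-9) 1 else
        if (truth < 1e-9) NA_real_ else surr / truth
      rows[[length(rows) + 1L]] <- data.frame(
        layout = layout, target = r$target, stratum = r$stratum,
        level = r$level, surrogate_mm = surr, truth_mm = truth,
        ratio = ratio, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
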