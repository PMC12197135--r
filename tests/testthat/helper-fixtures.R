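# Shared fixtures: random geometry generators and the hand-checked
# octahedral worked example.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# 13-landmark set with positions drawn iid N(0, scale^2) per coordinate
random_landmark_set <- function(condition = scan_condition("supine", 0),
                                scale = 100) {
  codes <- c(paste0("R", 1:6), paste0("P", 1:7))
  xyz <- matrix(stats::rnorm(39, 0, scale), 13, 3,
                dimnames = list(codes, c("x", "y", "z")))
  scan_landmark_set(condition, xyz)
}

# apply a rigid motion to every landmark of a set
transform_set <- function(set, rotation, translation = c(0, 0, 0)) {
  set$landmarks <- set$landmarks %*% t(rotation) +
    matrix(translation, nrow(set$landmarks), 3, byrow = TRUE)
  set
}

# Octahedral reference constellation (radius 10 mm) around a single
# target that moves from the origin to `shift`. Hand-derived surrogate for
# shift (1,0,0): per-reference |delta| = {1, 1, sqrt(101)-10 x4},
# mean = (2 + 4*(sqrt(101)-10))/6 = 0.36658366; true displacement 1.
octahedron_pair <- function(shift = c(1, 0, 0)) {
  refs <- rbind(R1 = c(10, 0, 0), R2 = c(-10, 0, 0),
                R3 = c(0, 10, 0), R4 = c(0, -10, 0),
                R5 = c(0, 0, 10), R6 = c(0, 0, -10))
  list(
    baseline = scan_landmark_set(scan_condition("supine", 0),
                                 rbind(refs, P1 = c(0, 0, 0))),
    comparison = scan_landmark_set(scan_condition("supine", 15),
                                   rbind(refs, P1 = shift))
  )
}

octahedron_expected_mean <- (2 + 4 * (sqrt(101) - 10)) / 6

# deformation parameters with randomized gains (for property tests)
random_deformation_params <- function(noise_sigma = 0) {
  deformation_params(
    alpha = stats::runif(1, 0.5, 1.5),
    lambda_depth = stats::runif(1, 40, 90),
    sag_compliance = stats::setNames(stats::runif(7, 2, 12),
                                     paste0("P", 1:7)),
    noise_sigma = noise_sigma,
    seed = sample.int(.Machine$integer.max, 1)
  )
}

# minimal valid FCSV text for given labelled RAS positions
fcsv_text <- function(xyz, labels, coordinate_system = "RAS") {
  c(
    "# Markups fiducial file version = 4.11",
    paste0("# CoordinateSystem = ", coordinate_system),
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    sprintf("vtkMRMLMarkupsFiducialNode_%d,%g,%g,%g,0,0,0,1,1,1,0,%s,,",
            seq_along(labels) - 1L, xyz[, 1], xyz[, 2], xyz[, 3], labels)
  )
}
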