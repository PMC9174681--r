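#' @keywords internal
.deg2rad <- function(deg) deg * pi / 180

.is_vec3 <- function(v) is.numeric(v) && length(v) == 3L && all(is.finite(v))

.stop_geom <- function(...) stop(sprintf(...), call. = FALSE)

#' Rotation matrix for a hip pose
#'
#' Builds the rigid rotation applied to femur-fixed points for a given hip
#' pose, in the pelvis-fixed right-handed frame with x cranial, y dorsal and
#' z lateral (right body side). Extension `phi` rotates about the
#' mediolateral axis (z) through the centre of rotation, sweeping the femur
#' long axis from cranial (0 deg) through ventral (90 deg) to caudal
#' (180 deg); abduction `beta` is applied afterwards about the dorsoventral
#' axis (y), tilting the whole extension sweep laterally. The femur long-axis
#' direction is therefore `R_y(beta) %*% R_z(phi) %*% c(1, 0, 0)`.
#'
#' @param extension_deg hip extension angle in degrees, in \[0, 180\].
#' @param abduction_deg hip abduction angle in degrees, non-negative.
#' @return a 3 x 3 rotation matrix.
#' @export
pose_rotation <- function(extension_deg, abduction_deg) {
  p <- validate_pose(extension_deg, abduction_deg)
  a <- .deg2rad(p$extension_deg)
  b <- .deg2rad(p$abduction_deg)
  ## x-hat -> (cos phi, -sin phi, 0): cranial through ventral to caudal
  E <- matrix(c(cos(a),  sin(a), 0,
                -sin(a), cos(a), 0,
                0,       0,      1), 3, 3, byrow = TRUE)
  ## x-hat -> (cos beta, 0, sin beta): cranial tilted laterally
  A <- matrix(c(cos(b), 0, -sin(b),
                0,      1, 0,
                sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  A %*% E
}

validate_pose <- function(extension_deg, abduction_deg) {
  if (!is.numeric(extension_deg) || length(extension_deg) != 1L ||
      !is.finite(extension_deg) || extension_deg < 0 || extension_deg > 180)
    .stop_geom("extension_deg must be a finite scalar in [0, 180], got %s",
               format(extension_deg))
  if (!is.numeric(abduction_deg) || length(abduction_deg) != 1L ||
      !is.finite(abduction_deg) || abduction_deg < 0)
    .stop_geom("abduction_deg must be a finite non-negative scalar, got %s",
               format(abduction_deg))
  list(extension_deg = as.numeric(extension_deg),
       abduction_deg = as.numeric(abduction_deg))
}

#' Construct a hip model
#'
#' A hip model holds the named landmarks needed for moment-arm computation
#' of one specimen: the muscle origin on the ilium, the insertion at the
#' most proximal point of the greater trochanter, the hip centre of rotation
#' (CoR, typically a femoral-head sphere-fit centre), a distal point
#' defining the femur long axis, and the anteroposterior femoral midshaft
#' diameter used as the body-size proxy. All coordinates are centimetres in
#' the pelvis-fixed frame (x cranial, y dorsal, z lateral).
#'
#' @param species species or specimen label.
#' @param origin 3-vector, muscle origin landmark (pelvis-fixed).
#' @param insertion 3-vector, muscle insertion landmark (femur-fixed).
#' @param cor 3-vector, hip joint centre of rotation.
#' @param femur_axis_point 3-vector, distal femur point; with `cor` it
#'   defines the femur long axis.
#' @param femoral_diameter positive scalar, cm.
#' @param femur_mesh,pelvis_mesh optional numeric matrices (n x 3) of mesh
#'   vertices in the same frame and units, used only for collision checks.
#' @return an object of class `hip_model`.
#' @export
hip_model <- function(species, origin, insertion, cor, femur_axis_point,
                      femoral_diameter, femur_mesh = NULL, pelvis_mesh = NULL) {
  for (nm in c("origin", "insertion", "cor", "femur_axis_point")) {
    v <- get(nm)
    if (!.is_vec3(v)) .stop_geom("%s must be a finite numeric 3-vector", nm)
  }
  if (!is.numeric(femoral_diameter) || length(femoral_diameter) != 1L ||
      !is.finite(femoral_diameter) || femoral_diameter <= 0)
    .stop_geom("femoral_diameter must be a positive scalar (cm)")
  if (isTRUE(all.equal(as.numeric(origin), as.numeric(insertion))))
    .stop_geom("origin and insertion landmarks coincide")
  if (isTRUE(all.equal(as.numeric(insertion), as.numeric(cor))))
    .stop_geom("insertion coincides with the centre of rotation")
  if (isTRUE(all.equal(as.numeric(femur_axis_point), as.numeric(cor))))
    .stop_geom("femur_axis_point coincides with the centre of rotation")
  for (m in list(femur_mesh, pelvis_mesh))
    if (!is.null(m) && (!is.matrix(m) || ncol(m) != 3L || !is.numeric(m)))
      .stop_geom("meshes must be numeric n x 3 vertex matrices")
  structure(list(species = as.character(species),
                 origin = as.numeric(origin),
                 insertion = as.numeric(insertion),
                 cor = as.numeric(cor),
                 femur_axis_point = as.numeric(femur_axis_point),
                 femoral_diameter = as.numeric(femoral_diameter),
                 femur_mesh = femur_mesh,
                 pelvis_mesh = pelvis_mesh),
            class = "hip_model")
}

#' @export
print.hip_model <- function(x, ...) {
  cat("Hip model:", x$species, "\n")
  cat(sprintf("  in-lever %.4f cm, femoral diameter %.4f cm\n",
              compute_in_lever(x), x$femoral_diameter))
  cat(sprintf("  meshes: femur %s, pelvis %s\n",
              if (is.null(x$femur_mesh)) "absent" else nrow(x$femur_mesh),
              if (is.null(x$pelvis_mesh)) "absent" else nrow(x$pelvis_mesh)))
  invisible(x)
}

#' Rigidly pose the femur of a hip model
#'
#' Applies the pose rotation about the centre of rotation to all femur-fixed
#' entities (insertion, femur axis point, femur mesh if present); pelvis-side
#' entities are untouched. The reference pose (0 deg extension, 0 deg
#' abduction) is the identity.
#'
#' @param model a [hip_model()].
#' @param extension_deg,abduction_deg the pose, degrees.
#' @return the model with femur-fixed entities replaced by their posed copies.
#' @export
pose_femur <- function(model, extension_deg, abduction_deg) {
  stopifnot(inherits(model, "hip_model"))
  R <- pose_rotation(extension_deg, abduction_deg)
  rot <- function(p) as.numeric(model$cor + R %*% (p - model$cor))
  out <- model
  out$insertion <- rot(model$insertion)
  out$femur_axis_point <- rot(model$femur_axis_point)
  if (!is.null(model$femur_mesh)) {
    ctr <- matrix(model$cor, nrow(model$femur_mesh), 3, byrow = TRUE)
    out$femur_mesh <- (model$femur_mesh - ctr) %*% t(R) + ctr
  }
  out
}

#' Instantaneous muscle moment arm of one pose
#'
#' The IMMA is the perpendicular distance from the joint centre of rotation
#' to the muscle's line of action, taken as the infinite straight line
#' through the origin and insertion landmarks. The orthogonal projection
#' (foot point) may fall between the attachments or beyond them; the
#' distance is measured either way and the position is reported as a flag.
#'
#' @param cor,origin,insertion numeric 3-vectors, same frame and units.
#' @return a list with `imma_cm` (the distance), `foot_point` (projection of
#'   `cor` on the line), and `on_segment` (whether the foot point lies
#'   between the attachments).
#' @export
compute_imma <- function(cor, origin, insertion) {
  if (!.is_vec3(cor) || !.is_vec3(origin) || !.is_vec3(insertion))
    .stop_geom("cor, origin and insertion must be finite numeric 3-vectors")
  d <- insertion - origin
  len <- sqrt(sum(d^2))
  if (len == 0) .stop_geom("origin and insertion coincide: line of action undefined")
  u <- d / len
  t <- sum((cor - origin) * u)
  foot <- origin + t * u
  list(imma_cm = sqrt(sum((cor - foot)^2)),
       foot_point = foot,
       on_segment = (t >= 0 && t <= len))
}

#' Osteological in-lever
#'
#' Euclidean distance from the muscle insertion to the joint centre of
#' rotation. Being femur-fixed, it is pose-invariant, and it bounds the
#' IMMA from above: the two are equal exactly when the in-lever is
#' perpendicular to the line of action.
#'
#' @param model a [hip_model()].
#' @return distance in cm.
#' @export
compute_in_lever <- function(model) {
  stopifnot(inherits(model, "hip_model"))
  sqrt(sum((model$insertion - model$cor)^2))
}

#' Standardized hip pose grid
#'
#' Cartesian product of extension angles (inclusive of both endpoints) and
#' abduction settings, ordered by abduction then extension. The default
#' protocol (extension 0-180 deg in 10 deg steps at 0/30/60 deg abduction)
#' yields 57 poses.
#'
#' @param ext_start,ext_stop,ext_step extension sweep in degrees.
#' @param abductions numeric vector of abduction settings, degrees.
#' @return a data frame with columns `abduction_deg`, `extension_deg`.
#' @export
generate_pose_grid <- function(ext_start = 0, ext_stop = 180, ext_step = 10,
                               abductions = c(0, 30, 60)) {
  if (!is.numeric(ext_step) || length(ext_step) != 1L || ext_step <= 0)
    .stop_geom("ext_step must be a positive scalar")
  if (ext_stop < ext_start) .stop_geom("ext_stop must be >= ext_start")
  if (length(abductions) == 0L) .stop_geom("abductions must be nonempty")
  ext <- seq(ext_start, ext_stop, by = ext_step)
  data.frame(abduction_deg = rep(as.numeric(abductions), each = length(ext)),
             extension_deg = rep(ext, times = length(abductions)))
}

#' Profile the IMMA of a hip model over a pose grid
#'
#' Measures the moment arm at every pose by rigidly posing the femur and
#' projecting the centre of rotation onto the line of action. If both meshes
#' are present and `collision_min_sep` is given, a pose is flagged
#' infeasible when the minimum separation between the posed femur vertex
#' cloud and the pelvis vertex cloud falls below the threshold (0 cm is an
#' intersection proxy); with meshes absent every pose is feasible.
#'
#' @param model a [hip_model()].
#' @param grid pose grid from [generate_pose_grid()].
#' @param collision_min_sep minimum femur-pelvis separation in cm, or `NULL`
#'   to skip collision checking.
#' @return an object of class `imma_profile`: list with `species`, `poses`
#'   (data frame: abduction_deg, extension_deg, imma_cm, feasible,
#'   on_segment) and `in_lever_cm`.
#' @export
profile_imma <- function(model, grid = generate_pose_grid(),
                         collision_min_sep = NULL) {
  stopifnot(inherits(model, "hip_model"), is.data.frame(grid))
  if (!is.null(collision_min_sep) &&
      (is.null(model$femur_mesh) || is.null(model$pelvis_mesh)))
    .stop_geom("collision checking requested but model lacks femur or pelvis mesh")
  il <- compute_in_lever(model)
  n <- nrow(grid)
  imma <- feas <- onseg <- numeric(n)
  feas <- rep(TRUE, n); onseg <- rep(NA, n)
  for (i in seq_len(n)) {
    posed <- pose_femur(model, grid$extension_deg[i], grid$abduction_deg[i])
    r <- compute_imma(posed$cor, posed$origin, posed$insertion)
    if (r$imma_cm > il * (1 + 1e-9))
      .stop_geom("IMMA exceeds in-lever at pose %g/%g: numerical defect",
                 grid$extension_deg[i], grid$abduction_deg[i])
    imma[i] <- min(r$imma_cm, il)
    onseg[i] <- r$on_segment
    if (!is.null(collision_min_sep))
      feas[i] <- .min_cloud_sep(posed$femur_mesh, posed$pelvis_mesh) >=
        collision_min_sep
  }
  structure(list(species = model$species,
                 poses = data.frame(grid,
                                    imma_cm = imma,
                                    feasible = as.logical(feas),
                                    on_segment = as.logical(onseg)),
                 in_lever_cm = il),
            class = "imma_profile")
}

## minimum separation between two vertex clouds; chunked to bound memory
.min_cloud_sep <- function(a, b) {
  best <- Inf
  step <- 512L
  for (i0 in seq(1L, nrow(a), by = step)) {
    ai <- a[i0:min(i0 + step - 1L, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(ai^2), rowSums(b^2), "+") - 2 * ai %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' @export
print.imma_profile <- function(x, ...) {
  cat(sprintf("IMMA profile: %s  (%d poses, in-lever %.4f cm)\n",
              x$species, nrow(x$poses), x$in_lever_cm))
  invisible(x)
}

#' @export
as.data.frame.imma_profile <- function(x, ...) {
  cbind(species = x$species, x$poses, in_lever_cm = x$in_lever_cm)
}

#' Digital-to-metric scale factor
#'
#' Mean of per-measurement ratios physical/digital; all digital measurements
#' are multiplied by this factor once at ingest.
#'
#' @param physical_cm,digital_units positive numeric vectors of paired
#'   measurements.
#' @return scalar scale factor.
#' @export
scale_to_metric <- function(physical_cm, digital_units) {
  if (length(physical_cm) == 0L || length(physical_cm) != length(digital_units))
    .stop_geom("need equally many, at least one, physical and digital measurements")
  if (any(!is.finite(physical_cm)) || any(!is.finite(digital_units)) ||
      any(physical_cm <= 0) || any(digital_units <= 0))
    .stop_geom("all measurements must be positive and finite")
  mean(physical_cm / digital_units)
}

#' Size-normalize an IMMA profile
#'
#' Divides every moment-arm value (and the in-lever) by the femoral
#' diameter, giving the dimensionless normalized IMMA used for lifestyle
#' comparisons. Feasibility flags are preserved.
#'
#' @param profile an [profile_imma()] result.
#' @param femoral_diameter positive scalar, cm; defaults to the model
#'   diameter recorded nowhere in the profile, so it must be supplied.
#' @return an `imma_profile` with dimensionless values.
#' @export
normalize_profile <- function(profile, femoral_diameter) {
  stopifnot(inherits(profile, "imma_profile"))
  if (!is.numeric(femoral_diameter) || length(femoral_diameter) != 1L ||
      !is.finite(femoral_diameter) || femoral_diameter <= 0)
    .stop_geom("femoral_diameter must be a positive scalar")
  out <- profile
  out$poses$imma_cm <- profile$poses$imma_cm / femoral_diameter
  out$in_lever_cm <- profile$in_lever_cm / femoral_diameter
  out
}
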