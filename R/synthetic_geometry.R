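#' Parameters of the synthetic hip geometry
#'
#' Dimensions of an idealized pelvis-femur pair in the pelvis-fixed frame
#' (CoR at the frame origin). Defaults approximate a mid-sized caviomorph
#' (femur ~5 cm) and are chosen so the moment-arm-vs-extension curve is the
#' single-peaked sigmoidal rise observed in real hip extensors, peaking
#' around 100-120 deg extension at 30 deg abduction.
#'
#' @param trochanter_offset cm, distance of the insertion from the CoR
#'   (this is the in-lever).
#' @param insertion_dorsal_deg,insertion_lateral_deg dorsal and lateral
#'   tilts of the insertion off the (reversed) femur long axis, degrees.
#'   The lateral tilt keeps the line of action from crossing the centre of
#'   rotation anywhere in the extension range, which is what makes the
#'   moment-arm curve single-peaked over the full sweep; a planar
#'   (in-sagittal) trochanter necessarily produces a zero crossing.
#' @param origin_cranial,origin_dorsal,origin_lateral cm, placement of the
#'   ilium origin landmark relative to the CoR (negative lateral = medial).
#' @param femur_length cm, CoR to distal axis point.
#' @param diameter_coef femoral midshaft diameter as a fraction of femur
#'   length.
#' @param lifestyle_shift named cm vector: regime-dependent cranial
#'   displacement of the muscle origin (scansorial origins sit farther from
#'   the joint).
#' @param lifestyle_trochanter named multiplier per regime on the
#'   trochanter offset, so the in-lever itself carries a lifestyle signal
#'   (climbers grow longer trochanters).
#' @param head_radius cm, femoral-head radius for the primitive sphere mesh.
#' @param landmark_sd cm, isotropic landmark jitter between specimens.
#' @return a `geometry_params` list.
#' @export
geometry_params <- function(trochanter_offset = 0.8,
                            insertion_dorsal_deg = 24,
                            insertion_lateral_deg = 52,
                            origin_cranial = 1.5,
                            origin_dorsal = 0.5,
                            origin_lateral = -0.65,
                            femur_length = 5,
                            diameter_coef = 0.08,
                            lifestyle_shift = c(cursorial = 0,
                                                fossorial = -0.1,
                                                scansorial = 0.25),
                            lifestyle_trochanter = c(cursorial = 1,
                                                     fossorial = 0.96,
                                                     scansorial = 1.12),
                            head_radius = 0.4,
                            landmark_sd = 0.04) {
  p <- list(trochanter_offset = trochanter_offset,
            insertion_dorsal_deg = insertion_dorsal_deg,
            insertion_lateral_deg = insertion_lateral_deg,
            origin_cranial = origin_cranial, origin_dorsal = origin_dorsal,
            origin_lateral = origin_lateral,
            femur_length = femur_length, diameter_coef = diameter_coef,
            lifestyle_shift = lifestyle_shift,
            lifestyle_trochanter = lifestyle_trochanter,
            head_radius = head_radius,
            landmark_sd = landmark_sd)
  for (nm in c("trochanter_offset", "origin_cranial", "origin_dorsal",
               "femur_length", "diameter_coef", "head_radius"))
    if (p[[nm]] <= 0) .stop_geom("geometry parameter %s must be positive", nm)
  if (landmark_sd < 0) .stop_geom("landmark_sd must be non-negative")
  structure(p, class = "geometry_params")
}

## Fibonacci sphere point sampling (deterministic)
.sphere_points <- function(center, radius, n = 200L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * cos(theta) * sin(phi),
        center[2] + radius * sin(theta) * sin(phi),
        center[3] + radius * cos(phi))
}

#' Generate a synthetic hip model
#'
#' Builds an idealized [hip_model()] in the reference pose: the CoR sits at
#' the frame origin, the femur long axis points cranially (+x), the
#' insertion lies `trochanter_offset` proximal of the CoR on that axis, and
#' the muscle origin sits cranio-dorsally on the "ilium", displaced
#' cranially by the regime's `lifestyle_shift`. An overall size factor
#' (log-normal across specimens, `size_log_sd`) scales all lengths
#' isometrically; the femoral diameter is `diameter_coef * femur_length`.
#' Optional primitive meshes (femoral-head sphere, femur-shaft cylinder,
#' ilium plate) support sphere-fit and collision tests.
#'
#' @param params a [geometry_params()].
#' @param regime lifestyle regime label (selects the origin shift).
#' @param species specimen label.
#' @param size_factor isometric scale multiplier (1 = defaults).
#' @param include_meshes attach primitive vertex meshes.
#' @param seed optional integer seed for landmark jitter.
#' @return a [hip_model()].
#' @export
generate_hip_model <- function(params = geometry_params(),
                               regime = "cursorial",
                               species = "synthetic",
                               size_factor = 1,
                               include_meshes = FALSE,
                               seed = NULL) {
  stopifnot(inherits(params, "geometry_params"))
  if (size_factor <= 0) .stop_geom("size_factor must be positive")
  if (!is.null(seed)) set.seed(seed)
  s <- size_factor
  shift <- if (regime %in% names(params$lifestyle_shift))
    params$lifestyle_shift[[regime]] else 0
  troch <- if (regime %in% names(params$lifestyle_trochanter))
    params$lifestyle_trochanter[[regime]] else 1
  jit <- function() stats::rnorm(3, 0, params$landmark_sd * s)
  cor <- c(0, 0, 0)
  dd <- .deg2rad(params$insertion_dorsal_deg)
  dl <- .deg2rad(params$insertion_lateral_deg)
  insertion <- params$trochanter_offset * troch * s *
    c(-cos(dd) * cos(dl), sin(dd) * cos(dl), sin(dl)) + jit()
  origin <- c((params$origin_cranial + shift) * s,
              params$origin_dorsal * s,
              params$origin_lateral * s) + jit()
  axis_pt <- c(params$femur_length * s, 0, 0)
  femur_mesh <- pelvis_mesh <- NULL
  if (include_meshes) {
    head <- .sphere_points(cor, params$head_radius * s, 240L)
    shaft_t <- seq(0.15, 1, length.out = 40L)
    ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
    r_shaft <- params$diameter_coef * params$femur_length * s / 2
    shaft <- do.call(rbind, lapply(shaft_t, function(tt)
      cbind(params$femur_length * s * tt,
            r_shaft * cos(ang), r_shaft * sin(ang))))
    femur_mesh <- rbind(head, shaft)
    gx <- seq(0.4, 1.6, length.out = 16L) * params$origin_cranial * s
    gy <- seq(0.4, 1.4, length.out = 12L) * params$origin_dorsal * s
    pelvis_mesh <- cbind(rep(gx, times = length(gy)),
                         rep(gy, each = length(gx)), 0)
  }
  hip_model(species = species, origin = origin, insertion = insertion,
            cor = cor, femur_axis_point = axis_pt,
            femoral_diameter = params$diameter_coef * params$femur_length * s,
            femur_mesh = femur_mesh, pelvis_mesh = pelvis_mesh)
}
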