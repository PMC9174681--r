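#' Write hip-model landmarks to tidy CSV
#'
#' One row per landmark with columns `species,name,x,y,z,units`. The
#' femoral diameter travels in the tip table, not here.
#'
#' @param models list of [hip_model()] objects.
#' @param file output path.
#' @export
write_landmarks <- function(models, file) {
  rows <- do.call(rbind, lapply(models, function(m) {
    pts <- rbind(origin = m$origin, insertion = m$insertion, cor = m$cor,
                 femur_axis_point = m$femur_axis_point)
    data.frame(species = m$species, name = rownames(pts),
               x = pts[, 1], y = pts[, 2], z = pts[, 3], units = "cm",
               row.names = NULL)
  }))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read hip models from a landmark CSV
#'
#' Expects the [write_landmarks()] layout; every species needs the four
#' landmarks `origin`, `insertion`, `cor`, `femur_axis_point`.
#'
#' @param file landmark CSV path.
#' @param diameters named vector of femoral diameters (cm) per species.
#' @param scale multiplicative digital-to-metric factor applied at ingest
#'   (see [scale_to_metric()]).
#' @return named list of [hip_model()] objects.
#' @export
read_landmarks <- function(file, diameters, scale = 1) {
  if (!file.exists(file)) .stop_geom("landmark file not found: %s", file)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "name", "x", "y", "z")
  if (!all(need %in% names(d)))
    .stop_geom("landmark CSV must have columns %s", paste(need, collapse = ","))
  out <- lapply(split(d, d$species), function(s) {
    get1 <- function(nm) {
      r <- s[s$name == nm, ]
      if (nrow(r) != 1L)
        .stop_geom("species %s: landmark '%s' missing or duplicated",
                   s$species[1], nm)
      scale * c(r$x, r$y, r$z)
    }
    sp <- s$species[1]
    if (!sp %in% names(diameters))
      .stop_geom("no femoral diameter for species %s", sp)
    hip_model(sp, origin = get1("origin"), insertion = get1("insertion"),
              cor = get1("cor"), femur_axis_point = get1("femur_axis_point"),
              femoral_diameter = scale * diameters[[sp]])
  })
  out[order(names(out))]
}

#' Read vertices from a minimal OBJ or PLY mesh file
#'
#' Vertex-only ingestion for collision checks: `v` lines of an OBJ, or the
#' vertex block of an ASCII PLY. Faces are ignored.
#'
#' @param file mesh path (.obj or .ply).
#' @return numeric n x 3 matrix of vertices.
#' @export
read_mesh_vertices <- function(file) {
  if (!file.exists(file)) .stop_geom("mesh file not found: %s", file)
  lines <- readLines(file, warn = FALSE)
  if (grepl("\\.obj$", file, ignore.case = TRUE)) {
    vl <- lines[startsWith(lines, "v ")]
    m <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(p) as.numeric(p[1:3])))
  } else if (grepl("\\.ply$", file, ignore.case = TRUE)) {
    if (!any(lines == "format ascii 1.0"))
      .stop_geom("only ASCII PLY is supported")
    nv <- as.integer(sub("element vertex ", "",
                         lines[startsWith(lines, "element vertex")]))
    start <- which(lines == "end_header") + 1L
    m <- do.call(rbind, lapply(strsplit(trimws(lines[start:(start + nv - 1L)]),
                                        "\\s+"),
                               function(p) as.numeric(p[1:3])))
  } else .stop_geom("unsupported mesh format: %s", file)
  if (is.null(m) || any(!is.finite(m))) .stop_geom("bad vertices in %s", file)
  m
}

## polynomial rolling hash of a character scalar: provenance fingerprints
## without external digest dependencies
.fnv1a <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
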