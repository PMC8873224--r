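# Domain types and disc/fovea-anchored retinal geometry.
#
# All coordinates are 0-based pixel coordinates with x increasing to the
# right and y increasing downwards. Distances are expressed in disc
# diameters (DD) so that pixel scale cancels between cameras.

#' Recognised lesion type labels
#'
#' The closed enumeration of lesion labels understood by the graders.
#' `ARTEFACT` marks a detection that is not a diabetic retinopathy lesion;
#' it is rejected nowhere but contributes to no grade.
#'
#' @return character vector of the 15 recognised labels.
#' @export
#' @examples
#' lesion_types()
lesion_types <- function() {
  c("MA", "HAEMORRHAGE", "BLOT_HAEMORRHAGE", "EXUDATE", "CWS",
    "VENOUS_BEADING", "VENOUS_REDUPLICATION", "VENOUS_LOOP", "IRMA",
    "NVD", "NVE", "PRERETINAL_HAEMORRHAGE", "FIBROSIS", "SCAR",
    "ARTEFACT")
}

#' Lesion labels that can contribute to a DR grade
#'
#' @return character vector: [lesion_types()] without `ARTEFACT`.
#' @export
dr_lesion_types <- function() {
  setdiff(lesion_types(), "ARTEFACT")
}

#' Construct a lesion table
#'
#' A lesion table is a plain `data.frame` with one row per detected or
#' annotated lesion and columns `id`, `type`, `x`, `y`, `area`,
#' `confidence`. The constructor validates the closed type enumeration,
#' non-negative areas, confidences in \[0, 1\] and finite centroids.
#'
#' @param type character vector of labels from [lesion_types()].
#' @param x,y lesion centroid coordinates in pixels.
#' @param area lesion area in pixels (non-negative).
#' @param confidence detector confidence in \[0, 1\].
#' @param id integer lesion identifiers; defaults to `seq_along(type)`.
#' @return a validated `data.frame` of lesions.
#' @export
#' @examples
#' lesion_frame(type = c("MA", "EXUDATE"), x = c(10, 40), y = c(20, 25),
#'              area = c(4, 30))
lesion_frame <- function(type = character(), x = numeric(), y = numeric(),
                         area = numeric(), confidence = NULL, id = NULL) {
  n <- length(type)
  if (is.null(confidence)) confidence <- rep(1, n)
  if (is.null(id)) id <- seq_len(n)
  df <- data.frame(id = as.integer(id), type = as.character(type),
                   x = as.double(x), y = as.double(y),
                   area = as.double(area),
                   confidence = as.double(confidence),
                   stringsAsFactors = FALSE)
  validate_lesion_frame(df)
}

#' @rdname lesion_frame
#' @param df a data.frame to validate as a lesion table.
#' @export
validate_lesion_frame <- function(df) {
  required <- c("id", "type", "x", "y", "area", "confidence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("lesion table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$type), lesion_types())
  if (length(bad)) {
    stop("unknown lesion type(s): ", paste(bad, collapse = ", "),
         "; recognised labels are ", paste(lesion_types(), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("lesion centroids must be finite", call. = FALSE)
  }
  if (any(df$area < 0 | !is.finite(df$area))) {
    stop("lesion areas must be finite and >= 0", call. = FALSE)
  }
  if (any(df$confidence < 0 | df$confidence > 1 | is.na(df$confidence))) {
    stop("lesion confidences must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("lesion ids must be unique", call. = FALSE)
  df[required]
}

#' Fundus landmark geometry
#'
#' Bundles the two anatomical landmarks (optic-disc centre and fovea
#' centre), the optic-disc diameter and the image extent. The disc
#' diameter defines the retinal distance unit (DD) and the fovea anchors
#' the five-region partition and the quadrants.
#'
#' @param disc_centre optic-disc centre, length-2 numeric (pixels).
#' @param disc_diameter optic-disc diameter in pixels (> 0).
#' @param fovea_centre fovea centre, length-2 numeric (pixels); must
#'   differ from `disc_centre`.
#' @param image_width,image_height image extent in pixels (> 0).
#' @return an object of class `fundus_geometry`.
#' @export
#' @examples
#' g <- fundus_geometry(c(1450, 1000), 180, c(1000, 1000), 2000, 2000)
#' distance_dd(c(1000, 1180), g)
fundus_geometry <- function(disc_centre, disc_diameter, fovea_centre,
                            image_width, image_height) {
  disc_centre <- drop(as_points(disc_centre))
  fovea_centre <- drop(as_points(fovea_centre))
  assert_scalar_number(disc_diameter, "disc_diameter", lower = 1e-12)
  assert_scalar_number(image_width, "image_width", lower = 1)
  assert_scalar_number(image_height, "image_height", lower = 1)
  if (all(disc_centre == fovea_centre)) {
    stop("disc_centre and fovea_centre must differ", call. = FALSE)
  }
  structure(list(disc_centre = unname(disc_centre),
                 disc_diameter = as.double(disc_diameter),
                 fovea_centre = unname(fovea_centre),
                 image_width = as.double(image_width),
                 image_height = as.double(image_height)),
            class = "fundus_geometry")
}

#' @export
print.fundus_geometry <- function(x, ...) {
  cat(sprintf("<fundus_geometry> disc (%.1f, %.1f) d=%.1fpx, fovea (%.1f, %.1f), %gx%g\n",
              x$disc_centre[1], x$disc_centre[2], x$disc_diameter,
              x$fovea_centre[1], x$fovea_centre[2],
              x$image_width, x$image_height))
  invisible(x)
}

is_fundus_geometry <- function(x) inherits(x, "fundus_geometry")

stopifnot_geometry <- function(geometry) {
  if (!is_fundus_geometry(geometry)) {
    stop("`geometry` must be a fundus_geometry object", call. = FALSE)
  }
  invisible(geometry)
}

#' One annotated image of one eye at one visit
#'
#' @param image_id non-empty identifier string.
#' @param geometry a [fundus_geometry()].
#' @param lesions a lesion table ([lesion_frame()]); defaults to empty.
#' @param eye one of `"LEFT"`, `"RIGHT"`, `"UNKNOWN"`.
#' @param capture_time opaque ordinal timestamp (ISO-8601 strings compare
#'   lexically).
#' @param gradable logical; was the image of gradable quality.
#' @param allow_outside logical; permit lesion centroids outside the
#'   image extent (used e.g. after registration maps points off-frame).
#' @return an object of class `image_record`.
#' @export
image_record <- function(image_id, geometry, lesions = lesion_frame(),
                         eye = "UNKNOWN", capture_time = "",
                         gradable = TRUE, allow_outside = FALSE) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id)) {
    stop("`image_id` must be a non-empty string", call. = FALSE)
  }
  stopifnot_geometry(geometry)
  lesions <- validate_lesion_frame(lesions)
  eye <- match.arg(eye, c("LEFT", "RIGHT", "UNKNOWN"))
  assert_flag(gradable, "gradable")
  if (!allow_outside && nrow(lesions)) {
    out <- lesions$x < 0 | lesions$x >= geometry$image_width |
      lesions$y < 0 | lesions$y >= geometry$image_height
    if (any(out)) {
      stop(sprintf("lesion id(s) %s lie outside the image extent; pass allow_outside = TRUE to keep them",
                   paste(lesions$id[out], collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(image_id = image_id, eye = eye,
                 capture_time = as.character(capture_time),
                 geometry = geometry, lesions = lesions,
                 gradable = gradable),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %s [%s] %d lesion(s)%s\n", x$image_id, x$eye,
              nrow(x$lesions), if (x$gradable) "" else " (ungradable)"))
  invisible(x)
}

#' Distance from the fovea in disc-diameter units
#'
#' @param points a length-2 point or an n x 2 matrix of points (pixels).
#' @param geometry a [fundus_geometry()].
#' @return numeric vector of Euclidean distances to the fovea centre,
#'   divided by the disc diameter.
#' @export
#' @examples
#' g <- fundus_geometry(c(200, 0), 80, c(10, 10), 512, 512)
#' distance_dd(c(10, 110), g)  # 1.25
distance_dd <- function(points, geometry) {
  stopifnot_geometry(geometry)
  p <- as_points(points)
  sqrt((p[, 1] - geometry$fovea_centre[1])^2 +
       (p[, 2] - geometry$fovea_centre[2])^2) / geometry$disc_diameter
}

#' Assign points to the five fovea-centred regions
#'
#' The retina is partitioned into five concentric regions around the
#' fovea: region 1 within 1 DD, region 2 in (1, 1.5\] DD, region 3 in
#' (1.5, 2\] DD, region 4 in (2, 3\] DD and region 5 beyond 3 DD.
#' Boundaries are upper-edge inclusive, so exactly 1.0 DD falls in
#' region 1 and the five regions partition the plane.
#'
#' @inheritParams distance_dd
#' @return integer vector of region indices in `1:5`.
#' @export
#' @examples
#' g <- fundus_geometry(c(300, 0), 100, c(0, 0), 1024, 1024)
#' assign_region(c(125, 0), g)  # region 2
assign_region <- function(points, geometry) {
  d <- distance_dd(points, geometry)
  as.integer(5L - (d <= 3) - (d <= 2) - (d <= 1.5) - (d <= 1))
}

#' Assign points to fovea-centred quadrants
#'
#' Quadrants are the four half-plane intersections delimited by the
#' horizontal and vertical axes through the fovea, numbered 1 =
#' upper-right then counter-clockwise as displayed (2 = upper-left,
#' 3 = lower-left, 4 = lower-right; note y grows downwards in image
#' coordinates). Points exactly on an axis join the lower-numbered
#' adjacent quadrant; the fovea itself is quadrant 1.
#'
#' @inheritParams distance_dd
#' @return integer vector of quadrant indices in `1:4`.
#' @export
assign_quadrant <- function(points, geometry) {
  stopifnot_geometry(geometry)
  p <- as_points(points)
  dx <- p[, 1] - geometry$fovea_centre[1]
  dy <- p[, 2] - geometry$fovea_centre[2]
  q <- integer(length(dx))
  q[dx > 0 & dy < 0] <- 1L
  q[dx < 0 & dy < 0] <- 2L
  q[dx < 0 & dy > 0] <- 3L
  q[dx > 0 & dy > 0] <- 4L
  # axis tie-breaks: lower-numbered adjacent quadrant
  q[dx == 0 & dy < 0] <- 1L   # on vertical axis, above
  q[dx == 0 & dy > 0] <- 3L   # on vertical axis, below
  q[dy == 0 & dx > 0] <- 1L   # on horizontal axis, right
  q[dy == 0 & dx < 0] <- 2L   # on horizontal axis, left
  q[dx == 0 & dy == 0] <- 1L  # fovea centre
  q
}
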