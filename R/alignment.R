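# Landmark-based registration and lesion-level progression analysis.
#
# Baseline and follow-up images of the same eye are registered from the
# two anatomical landmarks alone (optic-disc centre and fovea centre):
# two point pairs determine the 4-degree-of-freedom similarity transform
# in closed form, which stays well defined when vessels are obscured by
# pathology. Lesions are then matched per type by greedy nearest
# neighbour within a disc-diameter radius and each pair is classified as
# NEW / RESOLVED / GROWN / SHRUNK / STABLE.

#' Similarity transforms of the image plane
#'
#' `similarity_transform()` builds a transform p -> scale * R(rotation)
#' p + translation; `apply_transform()` maps points; `invert_transform()`
#' and `compose_transform()` give the group operations.
#'
#' @param scale positive scale factor.
#' @param rotation rotation in radians, in (-pi, pi\].
#' @param translation length-2 translation vector (pixels).
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  assert_scalar_number(scale, "scale", lower = 1e-12)
  assert_scalar_number(rotation, "rotation")
  translation <- drop(as_points(translation))
  structure(list(scale = as.double(scale), rotation = as.double(rotation),
                 translation = unname(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, rotation %.6g rad, translation (%.6g, %.6g)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' @rdname similarity_transform
#' @param t,a,b similarity transforms.
#' @param points a length-2 point or n x 2 matrix.
#' @export
apply_transform <- function(t, points) {
  stopifnot(inherits(t, "similarity_transform"))
  p <- as_points(points)
  cs <- cos(t$rotation) * t$scale
  sn <- sin(t$rotation) * t$scale
  cbind(cs * p[, 1] - sn * p[, 2] + t$translation[1],
        sn * p[, 1] + cs * p[, 2] + t$translation[2])
}

#' @rdname similarity_transform
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  s <- 1 / t$scale
  r <- -t$rotation
  cs <- cos(r) * s
  sn <- sin(r) * s
  similarity_transform(s, r, c(-(cs * t$translation[1] - sn * t$translation[2]),
                               -(sn * t$translation[1] + cs * t$translation[2])))
}

#' @rdname similarity_transform
#' @export
compose_transform <- function(a, b) {
  # returns the transform p -> a(b(p))
  stopifnot(inherits(a, "similarity_transform"),
            inherits(b, "similarity_transform"))
  rot <- a$rotation + b$rotation
  rot <- atan2(sin(rot), cos(rot))  # wrap to (-pi, pi]
  similarity_transform(a$scale * b$scale, rot,
                       drop(apply_transform(a, b$translation)))
}

#' Fit the similarity transform between two landmark geometries
#'
#' Closed form from the two point pairs (disc centre, fovea centre):
#' writing points as complex numbers, the transform z -> a z + b with
#' a = (fovea2 - disc2) / (fovea1 - disc1) maps the baseline landmarks
#' exactly onto the follow-up landmarks.
#'
#' @param baseline_geometry,followup_geometry [fundus_geometry()] objects
#'   of the same eye at the two visits.
#' @return a [similarity_transform()] mapping baseline pixel coordinates
#'   into the follow-up frame.
#' @export
fit_landmark_transform <- function(baseline_geometry, followup_geometry) {
  stopifnot_geometry(baseline_geometry)
  stopifnot_geometry(followup_geometry)
  z1d <- complex(real = baseline_geometry$disc_centre[1],
                 imaginary = baseline_geometry$disc_centre[2])
  z1f <- complex(real = baseline_geometry$fovea_centre[1],
                 imaginary = baseline_geometry$fovea_centre[2])
  z2d <- complex(real = followup_geometry$disc_centre[1],
                 imaginary = followup_geometry$disc_centre[2])
  z2f <- complex(real = followup_geometry$fovea_centre[1],
                 imaginary = followup_geometry$fovea_centre[2])
  if (Mod(z1f - z1d) < 1e-12 || Mod(z2f - z2d) < 1e-12) {
    stop("degenerate geometry: disc and fovea coincide", call. = FALSE)
  }
  a <- (z2f - z2d) / (z1f - z1d)
  b <- z2d - a * z1d
  similarity_transform(Mod(a), Arg(a), c(Re(b), Im(b)))
}

#' Map a lesion table through a similarity transform
#'
#' Centroids are transformed and areas scaled by the squared scale
#' factor (the Jacobian of a similarity); types, ids and confidences are
#' unchanged.
#'
#' @param lesions a lesion table ([lesion_frame()]).
#' @param t a [similarity_transform()].
#' @return the transformed lesion table.
#' @export
map_lesions <- function(lesions, t) {
  lesions <- validate_lesion_frame(lesions)
  if (!nrow(lesions)) return(lesions)
  p <- apply_transform(t, cbind(lesions$x, lesions$y))
  lesions$x <- p[, 1]
  lesions$y <- p[, 2]
  lesions$area <- lesions$area * t$scale^2
  lesions
}

#' Match baseline and follow-up lesions
#'
#' Greedy nearest-neighbour matching per lesion type: candidate pairs
#' within `tau_dd` disc diameters are taken in increasing distance order
#' (ties broken by the lower baseline id, then the lower follow-up id);
#' each lesion joins at most one pair. Baseline lesions must already be
#' mapped into the follow-up frame.
#'
#' @param baseline lesion table mapped into the follow-up frame.
#' @param followup follow-up lesion table.
#' @param tau_dd matching radius in disc-diameter units (default 0.25).
#' @param geometry the follow-up [fundus_geometry()] (supplies the DD
#'   scale).
#' @return data.frame with columns `baseline_id`, `followup_id`
#'   (NA for one-sided entries) and `distance_dd`.
#' @export
match_lesions <- function(baseline, followup, tau_dd = 0.25, geometry) {
  baseline <- validate_lesion_frame(baseline)
  followup <- validate_lesion_frame(followup)
  assert_scalar_number(tau_dd, "tau_dd", lower = 1e-12)
  stopifnot_geometry(geometry)
  radius <- tau_dd * geometry$disc_diameter
  out <- list()
  for (tp in unique(c(baseline$type, followup$type))) {
    b <- baseline[baseline$type == tp, , drop = FALSE]
    f <- followup[followup$type == tp, , drop = FALSE]
    matched_b <- logical(nrow(b))
    matched_f <- logical(nrow(f))
    if (nrow(b) && nrow(f)) {
      d <- outer(seq_len(nrow(b)), seq_len(nrow(f)), function(i, j) {
        sqrt((b$x[i] - f$x[j])^2 + (b$y[i] - f$y[j])^2)
      })
      cand <- which(d <= radius, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], b$id[cand[, 1]], f$id[cand[, 2]])
        for (k in ord) {
          i <- cand[k, 1]
          j <- cand[k, 2]
          if (!matched_b[i] && !matched_f[j]) {
            matched_b[i] <- TRUE
            matched_f[j] <- TRUE
            out[[length(out) + 1L]] <- data.frame(
              baseline_id = b$id[i], followup_id = f$id[j],
              distance_dd = d[i, j] / geometry$disc_diameter)
          }
        }
      }
    }
    for (i in which(!matched_b)) {
      out[[length(out) + 1L]] <- data.frame(baseline_id = b$id[i],
                                            followup_id = NA_integer_,
                                            distance_dd = NA_real_)
    }
    for (j in which(!matched_f)) {
      out[[length(out) + 1L]] <- data.frame(baseline_id = NA_integer_,
                                            followup_id = f$id[j],
                                            distance_dd = NA_real_)
    }
  }
  if (!length(out)) {
    return(data.frame(baseline_id = integer(), followup_id = integer(),
                      distance_dd = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(is.na(res$baseline_id), res$baseline_id, res$followup_id), ,
      drop = FALSE]
}

#' Progression analysis configuration
#'
#' @param match_radius_dd greedy matching radius in disc diameters
#'   (default 0.25).
#' @param area_deadband relative deadband delta for size changes: a
#'   matched lesion is GROWN when follow-up/baseline area ratio exceeds
#'   `1 + delta`, SHRUNK when it falls below `1 - delta`, else STABLE
#'   (default 0.2).
#' @param scheme grading scheme used for the per-visit grades attached
#'   to the report.
#' @param conf_threshold lesion confidence threshold for grading.
#' @return a list of class `progression_config`.
#' @export
progression_config <- function(match_radius_dd = 0.25, area_deadband = 0.2,
                               scheme = c("icdrs", "nsc"),
                               conf_threshold = 0.5) {
  assert_scalar_number(match_radius_dd, "match_radius_dd", lower = 1e-12)
  assert_scalar_number(area_deadband, "area_deadband", 0, 1)
  structure(list(match_radius_dd = match_radius_dd,
                 area_deadband = area_deadband,
                 scheme = match.arg(scheme),
                 conf_threshold = conf_threshold),
            class = "progression_config")
}

classify_pair <- function(area_ratio, deadband) {
  if (area_ratio > 1 + deadband) "GROWN"
  else if (area_ratio < 1 - deadband) "SHRUNK"
  else "STABLE"
}

#' Compare two visits of the same eye
#'
#' Full progression pipeline: fit the landmark transform, map baseline
#' lesions into the follow-up frame, match lesions per type, classify
#' each match as STABLE / GROWN / SHRUNK (area ratio against the
#' deadband) and each one-sided entry as NEW or RESOLVED, then aggregate
#' per region (computed in the follow-up frame, the clinically current
#' image) and attach both visits' grades.
#'
#' @param baseline,followup [image_record()] objects of the same eye.
#' @param config a [progression_config()].
#' @return an object of class `progression_report`: fields `events`
#'   (data.frame: kind, lesion_type, region, baseline_id, followup_id,
#'   area_ratio), `transform`, `baseline_grade`, `followup_grade`,
#'   `grade_delta` and `region_table` (kind x region counts).
#' @export
compare_visits <- function(baseline, followup, config = progression_config()) {
  stopifnot(inherits(baseline, "image_record"),
            inherits(followup, "image_record"),
            inherits(config, "progression_config"))
  if (baseline$eye != "UNKNOWN" && followup$eye != "UNKNOWN" &&
      baseline$eye != followup$eye) {
    stop("baseline and follow-up records are from different eyes",
         call. = FALSE)
  }
  if (!baseline$gradable || !followup$gradable) {
    stop("both visits must be gradable for progression analysis",
         call. = FALSE)
  }
  t <- fit_landmark_transform(baseline$geometry, followup$geometry)
  mapped <- map_lesions(baseline$lesions, t)
  pairs <- match_lesions(mapped, followup$lesions,
                         tau_dd = config$match_radius_dd,
                         geometry = followup$geometry)
  n <- nrow(pairs)
  events <- data.frame(kind = character(n), lesion_type = character(n),
                       region = integer(n),
                       baseline_id = pairs$baseline_id,
                       followup_id = pairs$followup_id,
                       area_ratio = rep(NA_real_, n),
                       stringsAsFactors = FALSE)
  bl <- mapped[match(pairs$baseline_id, mapped$id), , drop = FALSE]
  fl <- followup$lesions[match(pairs$followup_id, followup$lesions$id), ,
                         drop = FALSE]
  for (i in seq_len(n)) {
    if (is.na(pairs$baseline_id[i])) {
      events$kind[i] <- "NEW"
      events$lesion_type[i] <- fl$type[i]
      events$region[i] <- assign_region(c(fl$x[i], fl$y[i]),
                                        followup$geometry)
    } else if (is.na(pairs$followup_id[i])) {
      events$kind[i] <- "RESOLVED"
      events$lesion_type[i] <- bl$type[i]
      events$region[i] <- assign_region(c(bl$x[i], bl$y[i]),
                                        followup$geometry)
    } else {
      ratio <- if (bl$area[i] > 0) fl$area[i] / bl$area[i] else Inf
      events$kind[i] <- classify_pair(ratio, config$area_deadband)
      events$lesion_type[i] <- fl$type[i]
      events$region[i] <- assign_region(c(fl$x[i], fl$y[i]),
                                        followup$geometry)
      events$area_ratio[i] <- ratio
    }
  }
  table <- grading_table(config$scheme)
  g_base <- grade_record(baseline, table, config$conf_threshold)
  g_follow <- grade_record(followup, table, config$conf_threshold)
  kinds <- c("NEW", "RESOLVED", "GROWN", "SHRUNK", "STABLE")
  region_table <- table(factor(events$kind, levels = kinds),
                        factor(events$region, levels = 1:5))
  structure(list(events = events, transform = t,
                 baseline_grade = g_base, followup_grade = g_follow,
                 grade_delta = g_follow$level_index - g_base$level_index,
                 region_table = region_table,
                 config = config),
            class = "progression_report")
}

#' @export
print.progression_report <- function(x, ...) {
  counts <- table(factor(x$events$kind,
                         levels = c("NEW", "RESOLVED", "GROWN", "SHRUNK",
                                    "STABLE")))
  cat(sprintf("<progression_report> %s %s -> %s (delta %+d); %s\n",
              x$baseline_grade$scheme, x$baseline_grade$level,
              x$followup_grade$level, x$grade_delta,
              paste(names(counts), as.integer(counts), sep = "=",
                    collapse = " ")))
  invisible(x)
}
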