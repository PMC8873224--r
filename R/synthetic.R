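# Synthetic graded cohorts: the generator inverts the decision tables so
# that a lesion set synthesised for a target level satisfies that
# level's predicate and fails every higher one. Detector error is
# modelled as per-type misses, spurious detections (including
# artefacts), centroid jitter and area jitter; longitudinal pairs plant
# lesion-level change events under a camera-frame perturbation and
# return the exact ground-truth change log.

#' Default synthetic fundus geometry
#'
#' A macula-centred 2000 x 2000 frame with the fovea at the centre, a
#' 180-pixel disc diameter and the optic disc 2.5 DD temporal to the
#' fovea — typical proportions for a 45-50 degree colour fundus
#' photograph.
#'
#' @return a [fundus_geometry()].
#' @export
default_fundus_geometry <- function() {
  fundus_geometry(disc_centre = c(1450, 1000), disc_diameter = 180,
                  fovea_centre = c(1000, 1000),
                  image_width = 2000, image_height = 2000)
}

# Typical lesion pixel areas (at the default 180 px disc diameter).
lesion_area_range <- function(type) {
  switch(type,
    MA = c(4, 14),
    HAEMORRHAGE = c(30, 150),
    BLOT_HAEMORRHAGE = c(80, 300),
    EXUDATE = c(20, 120),
    CWS = c(120, 400),
    VENOUS_BEADING = c(50, 200),
    VENOUS_REDUPLICATION = c(50, 200),
    VENOUS_LOOP = c(50, 200),
    IRMA = c(40, 160),
    NVD = c(200, 800),
    NVE = c(200, 800),
    PRERETINAL_HAEMORRHAGE = c(300, 1000),
    FIBROSIS = c(300, 1000),
    SCAR = c(200, 600),
    ARTEFACT = c(20, 200),
    c(20, 200))
}

# Sample n points at fovea distances within dd_range (in DD), uniform in
# area over the annulus; optionally constrained to one quadrant. A small
# angular margin keeps samples off the quadrant axes.
sample_positions <- function(n, geometry, dd_range = c(0.15, 3.4),
                             quadrant = NULL) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  r <- geometry$disc_diameter *
    sqrt(stats::runif(n, dd_range[1]^2, dd_range[2]^2))
  eps <- 0.02
  theta <- if (is.null(quadrant)) {
    stats::runif(n, 0, 2 * pi)
  } else {
    # y grows downwards: quadrant 1 (up-right) has dy < 0
    lims <- switch(quadrant,
                   c(-pi / 2, 0), c(-pi, -pi / 2),
                   c(pi / 2, pi), c(0, pi / 2))
    stats::runif(n, lims[1] + eps, lims[2] - eps)
  }
  cbind(geometry$fovea_centre[1] + r * cos(theta),
        geometry$fovea_centre[2] + r * sin(theta))
}

# Rows of lesions of one type at sampled positions.
make_lesions <- function(n, type, geometry, dd_range = c(0.15, 3.4),
                         quadrant = NULL) {
  if (n == 0) {
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      area = numeric(), confidence = numeric()))
  }
  p <- sample_positions(n, geometry, dd_range, quadrant)
  ar <- lesion_area_range(type)
  data.frame(type = type, x = p[, 1], y = p[, 2],
             area = round(stats::runif(n, ar[1], ar[2])),
             confidence = 1, stringsAsFactors = FALSE)
}

# Exudate placement respecting the maculopathy flag: inside the
# maculopathy radius when requested, comfortably outside it otherwise.
make_exudates <- function(n_outside, maculopathy, geometry, table) {
  r <- table$maculopathy$radius_dd
  out <- make_lesions(n_outside, "EXUDATE", geometry,
                      dd_range = c(r + 0.15, 3.4))
  if (maculopathy) {
    out <- rbind(out, make_lesions(1L, "EXUDATE", geometry,
                                   dd_range = c(0.15, r - 0.1)))
  }
  out
}

#' Synthesise a lesion set for a target severity level
#'
#' Inverse of the decision tables: returns an image record whose lesion
#' set satisfies the target level's predicate and fails every higher
#' level's predicate, with counts and positions randomised within those
#' constraints. `maculopathy = TRUE` additionally plants an exudate
#' inside the maculopathy radius; this is infeasible (an error) for
#' levels whose predicates an exudate would already exceed (ICDRS 0/1,
#' NSC R0).
#'
#' @param table a [grading_table()] (one of the two shipped schemes).
#' @param level target level label on `table$levels`.
#' @param maculopathy logical; plant macular exudate.
#' @param geometry a [fundus_geometry()].
#' @param seed integer seed; the call is deterministic given it.
#' @param image_id identifier for the record.
#' @return an [image_record()].
#' @export
synthesise_for_level <- function(table, level, maculopathy = FALSE,
                                 geometry = default_fundus_geometry(),
                                 seed = 1L, image_id = NULL) {
  stopifnot(inherits(table, "grading_scheme"))
  if (!level %in% table$levels) {
    stop(sprintf("level '%s' is not on the %s ladder", level, table$scheme),
         call. = FALSE)
  }
  assert_flag(maculopathy, "maculopathy")
  image_id <- image_id %||%
    sprintf("synth-%s-%s-%d", tolower(table$scheme), level, seed)
  parts <- with_seed(seed, {
    if (table$scheme == "ICDRS") {
      synth_icdrs_level(level, maculopathy, geometry, table)
    } else if (table$scheme == "NSC") {
      synth_nsc_level(level, maculopathy, geometry, table)
    } else {
      stop("synthesis is implemented for the shipped ICDRS and NSC tables",
           call. = FALSE)
    }
  })
  lesions <- do.call(rbind, parts)
  rec <- image_record(image_id, geometry,
                      lesion_frame(type = lesions$type, x = lesions$x,
                                   y = lesions$y, area = lesions$area,
                                   confidence = lesions$confidence),
                      eye = "RIGHT", capture_time = "2020-01-01T00:00:00",
                      allow_outside = TRUE)
  rec
}

empty_part <- function() {
  data.frame(type = character(), x = numeric(), y = numeric(),
             area = numeric(), confidence = numeric())
}

mac_infeasible <- function(level, scheme) {
  stop(sprintf("maculopathy is infeasible at %s level %s: a macular exudate would exceed the target level",
               scheme, level), call. = FALSE)
}

synth_icdrs_level <- function(level, maculopathy, geometry, table) {
  parts <- list(empty_part())
  moderate_pool <- function() {
    # moderate-defining lesions kept clear of the severe 4-2-1 rule
    out <- list()
    out$haem <- make_lesions(sample(0:6, 1), "HAEMORRHAGE", geometry)
    out$blot <- make_lesions(sample(0:3, 1), "BLOT_HAEMORRHAGE", geometry)
    out$cws <- make_lesions(sample(0:2, 1), "CWS", geometry)
    out$loop <- make_lesions(sample(0:1, 1), "VENOUS_LOOP", geometry)
    out$exu <- make_exudates(sample(0:3, 1), maculopathy, geometry, table)
    out
  }
  if (level == "0") {
    if (maculopathy) mac_infeasible(level, "ICDRS")
  } else if (level == "1") {
    if (maculopathy) mac_infeasible(level, "ICDRS")
    parts$ma <- make_lesions(sample(1:10, 1), "MA", geometry)
  } else if (level == "2") {
    parts$ma <- make_lesions(sample(0:8, 1), "MA", geometry)
    pool <- moderate_pool()
    if (!sum(vapply(pool, nrow, 0L)) && !maculopathy) {
      pool$haem <- make_lesions(sample(1:4, 1), "HAEMORRHAGE", geometry)
    }
    parts <- c(parts, pool)
  } else if (level == "3") {
    branch <- sample(3L, 1)
    if (branch == 1L) {
      # >= 20 haemorrhages in each of the four quadrants
      for (q in 1:4) {
        parts[[paste0("q", q)]] <- make_lesions(sample(20:24, 1),
                                                "HAEMORRHAGE", geometry,
                                                quadrant = q)
      }
    } else if (branch == 2L) {
      # venous beading in >= 2 quadrants
      qs <- sample(4L, sample(2:4, 1))
      for (q in qs) {
        parts[[paste0("vb", q)]] <- make_lesions(1L, "VENOUS_BEADING",
                                                 geometry, quadrant = q)
      }
    } else {
      parts$irma <- make_lesions(sample(1:3, 1), "IRMA", geometry)
    }
    parts$ma <- make_lesions(sample(0:5, 1), "MA", geometry)
    parts$exu <- make_exudates(sample(0:2, 1), maculopathy, geometry, table)
  } else if (level == "4") {
    pdr_types <- c("NVD", "NVE", "PRERETINAL_HAEMORRHAGE", "FIBROSIS")
    chosen <- sample(pdr_types, sample(1:2, 1))
    for (tp in chosen) parts[[tp]] <- make_lesions(1L, tp, geometry)
    parts$ma <- make_lesions(sample(0:8, 1), "MA", geometry)
    parts$haem <- make_lesions(sample(0:8, 1), "HAEMORRHAGE", geometry)
    parts$exu <- make_exudates(sample(0:3, 1), maculopathy, geometry, table)
  }
  parts
}

synth_nsc_level <- function(level, maculopathy, geometry, table) {
  parts <- list(empty_part())
  background_pool <- function(require_one = FALSE) {
    out <- list()
    out$ma <- make_lesions(sample(0:8, 1), "MA", geometry)
    out$haem <- make_lesions(sample(0:4, 1), "HAEMORRHAGE", geometry)
    out$cws <- make_lesions(sample(0:2, 1), "CWS", geometry)
    out$exu <- make_exudates(sample(0:3, 1), maculopathy, geometry, table)
    if (require_one && !sum(vapply(out, nrow, 0L))) {
      out$ma <- make_lesions(sample(1:8, 1), "MA", geometry)
    }
    out
  }
  if (level == "R0") {
    if (maculopathy) mac_infeasible(level, "NSC")
  } else if (level == "R1") {
    parts <- c(parts, background_pool(require_one = !maculopathy))
  } else if (level == "R2") {
    if (sample(2L, 1) == 1L) {
      tp <- sample(c("VENOUS_BEADING", "VENOUS_LOOP",
                     "VENOUS_REDUPLICATION", "IRMA"), 1)
      parts[[tp]] <- make_lesions(sample(1:3, 1), tp, geometry)
    } else {
      parts$blot <- make_lesions(sample(5:9, 1), "BLOT_HAEMORRHAGE",
                                 geometry)
    }
    parts <- c(parts, background_pool())
  } else if (level == "R3") {
    pdr_types <- c("NVD", "NVE", "PRERETINAL_HAEMORRHAGE", "FIBROSIS")
    chosen <- sample(pdr_types, sample(1:2, 1))
    for (tp in chosen) parts[[tp]] <- make_lesions(1L, tp, geometry)
    parts <- c(parts, background_pool())
  }
  parts
}

#' Cohort prevalence configuration and the three published presets
#'
#' `prevalence_config()` builds a per-level prevalence map;
#' `prevalence_preset()` returns one of the three shipped national
#' screening presets, whose per-level image counts are the published
#' dataset compositions (China and Saudi Arabia graded in NSC, Kenya in
#' ICDRS) and whose proportions are those counts divided by the row sum.
#'
#' @param scheme `"icdrs"` or `"nsc"`.
#' @param proportions named numeric vector over the scheme's levels,
#'   summing to 1.
#' @param maculopathy_rate named per-level maculopathy probability;
#'   defaults to 0 where maculopathy is infeasible and to modest rates
#'   rising with severity elsewhere.
#' @param counts optional per-level integer counts the proportions were
#'   derived from.
#' @return a list of class `prevalence_config`.
#' @export
#' @examples
#' prevalence_preset("china")$counts
prevalence_config <- function(scheme, proportions, maculopathy_rate = NULL,
                              counts = NULL) {
  table <- grading_table(scheme)
  if (is.null(names(proportions)) ||
      !setequal(names(proportions), table$levels)) {
    stop("proportions must be named by every level of the scheme",
         call. = FALSE)
  }
  proportions <- proportions[table$levels]
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  if (is.null(maculopathy_rate)) {
    feasible <- vapply(table$levels, function(lv) {
      !((table$scheme == "ICDRS" && lv %in% c("0", "1")) ||
        (table$scheme == "NSC" && lv == "R0"))
    }, TRUE)
    ladder <- seq_along(table$levels) - 1L
    maculopathy_rate <- ifelse(feasible, pmin(0.1 * ladder + 0.05, 0.35), 0)
    names(maculopathy_rate) <- table$levels
  }
  maculopathy_rate <- maculopathy_rate[table$levels]
  if (any(maculopathy_rate < 0 | maculopathy_rate > 1)) {
    stop("maculopathy rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(scheme = tolower(scheme), levels = table$levels,
                 proportions = proportions,
                 maculopathy_rate = maculopathy_rate,
                 counts = counts),
            class = "prevalence_config")
}

#' @rdname prevalence_config
#' @param name `"china"`, `"saudi"` or `"kenya"`.
#' @export
prevalence_preset <- function(name = c("china", "saudi", "kenya")) {
  name <- match.arg(name)
  spec <- switch(name,
    china = list(scheme = "nsc",
                 counts = c(R0 = 9986, R1 = 3279, R2 = 1240, R3 = 495)),
    saudi = list(scheme = "nsc",
                 counts = c(R0 = 7451, R1 = 1854, R2 = 582, R3 = 139)),
    kenya = list(scheme = "icdrs",
                 counts = c(`0` = 13304, `1` = 10967, `2` = 3935,
                            `3` = 381, `4` = 93)))
  prevalence_config(spec$scheme, spec$counts / sum(spec$counts),
                    counts = spec$counts)
}

#' Detector noise model
#'
#' Parameters of the simulated lesion detector's error channels. Each of
#' `miss_prob` and `false_alarm_rate` may be a single number (applied to
#' every type) or a named per-type vector (missing types default to 0).
#'
#' @param miss_prob probability that a true lesion is missed.
#' @param false_alarm_rate expected number of spurious detections per
#'   image per type (Poisson); spurious types may include `ARTEFACT`.
#' @param false_alarm_types types eligible for spurious detections when
#'   `false_alarm_rate` is a scalar.
#' @param centroid_jitter_dd standard deviation of isotropic centroid
#'   jitter, in disc diameters.
#' @param area_jitter_sdlog standard deviation of the log-normal area
#'   multiplier.
#' @param confidence_beta optional `c(shape1, shape2)` of the Beta
#'   distribution of reported confidences for true lesions (default:
#'   confidence 1).
#' @param false_alarm_confidence_beta Beta parameters for spurious
#'   detections' confidences (defaults to `confidence_beta`).
#' @return a list of class `noise_model`. The default is the zero-noise
#'   model: detections reproduce the annotation exactly.
#' @export
noise_model <- function(miss_prob = 0, false_alarm_rate = 0,
                        false_alarm_types = c("MA", "HAEMORRHAGE",
                                              "EXUDATE", "ARTEFACT"),
                        centroid_jitter_dd = 0, area_jitter_sdlog = 0,
                        confidence_beta = NULL,
                        false_alarm_confidence_beta = confidence_beta) {
  if (any(miss_prob < 0 | miss_prob > 1)) {
    stop("miss probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(false_alarm_rate < 0)) {
    stop("false-alarm rates must be >= 0", call. = FALSE)
  }
  assert_scalar_number(centroid_jitter_dd, "centroid_jitter_dd", 0)
  assert_scalar_number(area_jitter_sdlog, "area_jitter_sdlog", 0)
  structure(list(miss_prob = miss_prob,
                 false_alarm_rate = false_alarm_rate,
                 false_alarm_types = false_alarm_types,
                 centroid_jitter_dd = centroid_jitter_dd,
                 area_jitter_sdlog = area_jitter_sdlog,
                 confidence_beta = confidence_beta,
                 false_alarm_confidence_beta = false_alarm_confidence_beta),
            class = "noise_model")
}

is_zero_noise <- function(noise) {
  all(noise$miss_prob == 0) && all(noise$false_alarm_rate == 0) &&
    noise$centroid_jitter_dd == 0 && noise$area_jitter_sdlog == 0 &&
    is.null(noise$confidence_beta)
}

param_for_type <- function(param, type, default = 0) {
  if (is.null(names(param))) {
    if (length(param) != 1L) stop("unnamed noise parameter must be scalar",
                                  call. = FALSE)
    rep(param, length(type))
  } else {
    out <- param[type]
    out[is.na(out)] <- default
    unname(out)
  }
}

#' Corrupt an image record with detector noise
#'
#' Applies, in order: per-lesion Bernoulli misses, centroid jitter, area
#' jitter, confidence resampling, then Poisson spurious detections
#' (uniformly positioned, including artefacts). Deterministic given
#' `seed`; the zero-noise model returns the record unchanged.
#'
#' @param record an [image_record()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return the corrupted [image_record()].
#' @export
apply_detector_noise <- function(record, noise, seed = 1L) {
  stopifnot(inherits(record, "image_record"), inherits(noise, "noise_model"))
  if (is_zero_noise(noise)) return(record)
  geometry <- record$geometry
  les <- with_seed(seed, {
    les <- record$lesions
    if (nrow(les)) {
      miss <- param_for_type(noise$miss_prob, les$type)
      les <- les[stats::runif(nrow(les)) >= miss, , drop = FALSE]
    }
    n <- nrow(les)
    if (n && noise$centroid_jitter_dd > 0) {
      sd_px <- noise$centroid_jitter_dd * geometry$disc_diameter
      les$x <- les$x + stats::rnorm(n, 0, sd_px)
      les$y <- les$y + stats::rnorm(n, 0, sd_px)
    }
    if (n && noise$area_jitter_sdlog > 0) {
      les$area <- les$area * exp(stats::rnorm(n, 0, noise$area_jitter_sdlog))
    }
    if (n && !is.null(noise$confidence_beta)) {
      les$confidence <- stats::rbeta(n, noise$confidence_beta[1],
                                     noise$confidence_beta[2])
    }
    fa_types <- if (is.null(names(noise$false_alarm_rate))) {
      noise$false_alarm_types
    } else {
      names(noise$false_alarm_rate)
    }
    for (tp in fa_types) {
      rate <- param_for_type(noise$false_alarm_rate, tp)
      k <- stats::rpois(1, rate)
      if (k > 0) {
        extra <- make_lesions(k, tp, geometry)
        cb <- noise$false_alarm_confidence_beta
        if (!is.null(cb)) extra$confidence <- stats::rbeta(k, cb[1], cb[2])
        extra$id <- NA_integer_
        les <- rbind(les[names(extra)][, , drop = FALSE], extra)
      }
    }
    les$id <- seq_len(nrow(les))
    les
  })
  record$lesions <- validate_lesion_frame(les)
  record
}

#' Sample a graded synthetic cohort
#'
#' Draws ground-truth levels from the prevalence configuration, plants
#' maculopathy at the configured per-level rates, synthesises each clean
#' lesion set by decision-table inversion and corrupts it with the noise
#' model. Fully deterministic given `seed`.
#'
#' @param prevalence a [prevalence_config()] or preset name.
#' @param n cohort size.
#' @param noise a [noise_model()] (default zero noise).
#' @param seed integer seed.
#' @param geometry the common [fundus_geometry()].
#' @return an object of class `dr_cohort`: `records` (list of
#'   [image_record()]), `truth` (data.frame image_id, level,
#'   maculopathy, referable), and the generating configuration.
#' @export
sample_cohort <- function(prevalence, n, noise = noise_model(), seed = 1L,
                          geometry = default_fundus_geometry()) {
  if (is.character(prevalence)) prevalence <- prevalence_preset(prevalence)
  stopifnot(inherits(prevalence, "prevalence_config"),
            inherits(noise, "noise_model"))
  assert_scalar_number(n, "n", lower = 1)
  table <- grading_table(prevalence$scheme)
  draws <- with_seed(seed, {
    levels <- sample(prevalence$levels, n, replace = TRUE,
                     prob = prevalence$proportions)
    mac <- stats::runif(n) < prevalence$maculopathy_rate[levels]
    list(levels = levels, mac = mac)
  })
  records <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- synthesise_for_level(table, draws$levels[i], draws$mac[i],
                                geometry = geometry,
                                seed = derive_seed(seed, i),
                                image_id = sprintf("cohort-%d-%05d", seed, i))
    records[[i]] <- apply_detector_noise(rec, noise,
                                         seed = derive_seed(seed, n + i))
  }
  truth <- data.frame(image_id = vapply(records, `[[`, "", "image_id"),
                      level = draws$levels,
                      maculopathy = draws$mac,
                      stringsAsFactors = FALSE)
  truth$referable <- vapply(seq_len(n), function(i) {
    is_referable(truth$level[i], table, dmo = truth$maculopathy[i])
  }, TRUE)
  structure(list(records = records, truth = truth,
                 prevalence = prevalence, noise = noise,
                 seed = as.integer(seed), scheme = prevalence$scheme),
            class = "dr_cohort")
}

#' @export
print.dr_cohort <- function(x, ...) {
  cat(sprintf("<dr_cohort> n=%d, scheme %s, seed %d\n",
              nrow(x$truth), toupper(x$scheme), x$seed))
  print(table(x$truth$level))
  invisible(x)
}

#' Progression script: planted longitudinal changes
#'
#' Describes the ground truth of a synthetic follow-up visit: a camera
#' perturbation (similarity transform applied to the whole frame) plus
#' an ordered list of planted lesion events.
#'
#' @param events data.frame with columns `kind` (`NEW`, `RESOLVED`,
#'   `GROWN`, `SHRUNK`), `lesion_type`, `region` (target region for NEW,
#'   `NA` otherwise), `area_factor` (for GROWN/SHRUNK; defaults 2 and
#'   0.5), and optional `baseline_id` (`NA` = pick an eligible lesion at
#'   random).
#' @param camera a [similarity_transform()] perturbing the follow-up
#'   frame (default identity).
#' @return a list of class `progression_script`.
#' @export
progression_script <- function(events, camera = similarity_transform()) {
  stopifnot(is.data.frame(events),
            inherits(camera, "similarity_transform"))
  if (!nrow(events)) {
    events <- data.frame(kind = character(), lesion_type = character(),
                         region = integer(), area_factor = numeric(),
                         baseline_id = integer())
  }
  if (is.null(events$area_factor)) events$area_factor <- NA_real_
  if (is.null(events$baseline_id)) events$baseline_id <- NA_integer_
  if (is.null(events$region)) events$region <- NA_integer_
  bad <- setdiff(events$kind, c("NEW", "RESOLVED", "GROWN", "SHRUNK"))
  if (length(bad)) stop("unknown event kind(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  events$area_factor <- ifelse(is.na(events$area_factor),
                               ifelse(events$kind == "GROWN", 2,
                                      ifelse(events$kind == "SHRUNK", 0.5,
                                             NA_real_)),
                               events$area_factor)
  structure(list(events = events, camera = camera),
            class = "progression_script")
}

#' Synthesise a follow-up visit from a baseline and a script
#'
#' Applies the camera perturbation to the geometry and lesions, plants
#' the scripted events, corrupts the result with the noise model, and
#' returns the follow-up record together with the exact ground-truth
#' change log (including STABLE entries for untouched lesions) for
#' scoring the progression pipeline.
#'
#' @param baseline an [image_record()].
#' @param script a [progression_script()].
#' @param noise a [noise_model()] (default zero noise).
#' @param seed integer seed.
#' @param min_separation_dd minimum fovea-plane distance (in DD) between
#'   a planted NEW lesion and every same-type lesion already present;
#'   keeping this at twice the matching radius guarantees the matcher
#'   cannot pair a planted lesion with an unrelated one (default 0.5 =
#'   2 x the default 0.25 DD radius).
#' @return list with `followup` ([image_record()]) and `truth`
#'   (data.frame: kind, lesion_type, region, baseline_id, followup_id).
#' @export
synthesise_pair <- function(baseline, script, noise = noise_model(),
                            seed = 1L, min_separation_dd = 0.5) {
  stopifnot(inherits(baseline, "image_record"),
            inherits(script, "progression_script"))
  cam <- script$camera
  g <- baseline$geometry
  dc <- drop(apply_transform(cam, g$disc_centre))
  fc <- drop(apply_transform(cam, g$fovea_centre))
  g2 <- fundus_geometry(dc, g$disc_diameter * cam$scale, fc,
                        g$image_width, g$image_height)
  out <- with_seed(seed, {
    les <- map_lesions(baseline$lesions, cam)
    state <- data.frame(baseline_id = les$id,
                        kind = rep("STABLE", length(les$id)),
                        stringsAsFactors = FALSE)
    new_rows <- list()
    n_new <- 0L
    for (i in seq_len(nrow(script$events))) {
      ev <- script$events[i, ]
      if (ev$kind == "NEW") {
        region <- if (is.na(ev$region)) sample(1:4, 1) else ev$region
        bounds <- list(c(0.15, 0.95), c(1.05, 1.45), c(1.55, 1.95),
                       c(2.05, 2.95), c(3.05, 3.4))[[region]]
        same <- les[les$type == ev$lesion_type, c("x", "y"), drop = FALSE]
        for (prev in new_rows) {
          same <- rbind(same, prev[prev$type == ev$lesion_type,
                                   c("x", "y"), drop = FALSE])
        }
        min_px <- min_separation_dd * g2$disc_diameter
        for (try in 1:100) {
          row <- make_lesions(1L, ev$lesion_type, g2, dd_range = bounds)
          if (!nrow(same) || min(sqrt((same$x - row$x)^2 +
                                      (same$y - row$y)^2)) >= min_px) break
        }
        n_new <- n_new + 1L
        new_rows[[n_new]] <- row
      } else {
        eligible <- state$baseline_id[state$kind == "STABLE" &
          les$type[match(state$baseline_id, les$id)] == ev$lesion_type]
        target <- ev$baseline_id
        if (is.na(target)) {
          if (!length(eligible)) {
            stop(sprintf("script event %d (%s %s) has no eligible baseline lesion",
                         i, ev$kind, ev$lesion_type), call. = FALSE)
          }
          target <- if (length(eligible) == 1L) eligible
                    else sample(eligible, 1)
        } else if (!target %in% eligible) {
          stop(sprintf("script event %d targets baseline id %d which is not an eligible %s lesion",
                       i, target, ev$lesion_type), call. = FALSE)
        }
        state$kind[state$baseline_id == target] <- ev$kind
        if (ev$kind %in% c("GROWN", "SHRUNK")) {
          les$area[les$id == target] <- les$area[les$id == target] *
            ev$area_factor
        }
      }
    }
    list(les = les, state = state, new_rows = new_rows)
  })
  les <- out$les
  state <- out$state
  keep <- state$kind != "RESOLVED"
  followup_les <- les[match(state$baseline_id[keep], les$id), , drop = FALSE]
  truth <- data.frame(kind = state$kind,
                      lesion_type = les$type[match(state$baseline_id,
                                                   les$id)],
                      region = assign_region(cbind(
                        les$x[match(state$baseline_id, les$id)],
                        les$y[match(state$baseline_id, les$id)]), g2),
                      baseline_id = state$baseline_id,
                      followup_id = NA_integer_,
                      stringsAsFactors = FALSE)
  if (length(out$new_rows)) {
    new_df <- do.call(rbind, out$new_rows)
    truth <- rbind(truth, data.frame(
      kind = "NEW", lesion_type = new_df$type,
      region = assign_region(cbind(new_df$x, new_df$y), g2),
      baseline_id = NA_integer_, followup_id = NA_integer_,
      stringsAsFactors = FALSE))
    followup_les <- rbind(
      followup_les[c("type", "x", "y", "area", "confidence")],
      new_df[c("type", "x", "y", "area", "confidence")])
  } else {
    followup_les <- followup_les[c("type", "x", "y", "area", "confidence")]
  }
  followup_ids <- seq_len(nrow(followup_les))
  # follow-up ids: surviving baseline lesions first (baseline order), then
  # the planted NEW lesions in script order
  surv <- which(truth$kind %in% c("STABLE", "GROWN", "SHRUNK"))
  truth$followup_id[surv] <- seq_along(surv)
  truth$followup_id[truth$kind == "NEW"] <-
    seq(length(surv) + 1L, length.out = sum(truth$kind == "NEW"))
  followup <- image_record(paste0(baseline$image_id, "-followup"), g2,
                           lesion_frame(type = followup_les$type,
                                        x = followup_les$x,
                                        y = followup_les$y,
                                        area = followup_les$area,
                                        confidence = followup_les$confidence,
                                        id = followup_ids),
                           eye = baseline$eye,
                           capture_time = paste0(baseline$capture_time, "+1"),
                           allow_outside = TRUE)
  followup <- apply_detector_noise(followup, noise,
                                   seed = derive_seed(seed, 999983L))
  list(followup = followup, truth = truth)
}

#' Random camera perturbation
#'
#' @param seed integer seed.
#' @param scale_range,rotation_range,translation_range sampling ranges
#'   for the similarity parameters.
#' @return a [similarity_transform()].
#' @export
random_camera <- function(seed = 1L, scale_range = c(0.9, 1.1),
                          rotation_range = c(-0.1, 0.1),
                          translation_range = c(-30, 30)) {
  with_seed(seed, {
    similarity_transform(stats::runif(1, scale_range[1], scale_range[2]),
                         stats::runif(1, rotation_range[1],
                                      rotation_range[2]),
                         stats::runif(2, translation_range[1],
                                      translation_range[2]))
  })
}
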