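# Lesion summaries and decision-table grading.

#' Summarise the lesions of an image record
#'
#' Collapses an image's lesion table into the counts the graders consume:
#' per-type totals, per-type per-region and per-quadrant counts, total
#' areas, and the minimum fovea distance (DD) per type. Lesions with
#' confidence below `conf_threshold` and all `ARTEFACT` detections are
#' excluded before counting.
#'
#' @param record an [image_record()].
#' @param conf_threshold minimum detector confidence for a lesion to
#'   count; default 0.5.
#' @return an object of class `lesion_summary`.
#' @export
#' @examples
#' g <- fundus_geometry(c(1450, 1000), 180, c(1000, 1000), 2000, 2000)
#' rec <- image_record("img1", g,
#'                     lesion_frame(type = "MA", x = 1050, y = 1000, area = 4))
#' summarise_lesions(rec)$counts[["MA"]]
summarise_lesions <- function(record, conf_threshold = 0.5) {
  stopifnot(inherits(record, "image_record"))
  assert_scalar_number(conf_threshold, "conf_threshold", 0, 1)
  types <- dr_lesion_types()
  les <- record$lesions
  keep <- les$confidence >= conf_threshold & les$type != "ARTEFACT"
  les <- les[keep, , drop = FALSE]

  counts <- stats::setNames(numeric(length(types)), types)
  areas <- counts
  min_dd <- stats::setNames(rep(Inf, length(types)), types)
  region_counts <- matrix(0, length(types), 5,
                          dimnames = list(types, paste0("region", 1:5)))
  quadrant_counts <- matrix(0, length(types), 4,
                            dimnames = list(types, paste0("quadrant", 1:4)))
  if (nrow(les)) {
    pts <- cbind(les$x, les$y)
    les$region <- assign_region(pts, record$geometry)
    les$quadrant <- assign_quadrant(pts, record$geometry)
    les$dd <- distance_dd(pts, record$geometry)
    tf <- factor(les$type, levels = types)
    counts[] <- as.double(table(tf))
    areas[] <- as.double(tapply(les$area, tf, sum, default = 0))
    mins <- tapply(les$dd, tf, min)
    min_dd[names(mins)[!is.na(mins)]] <- mins[!is.na(mins)]
    region_counts[] <- as.double(table(tf, factor(les$region, levels = 1:5)))
    quadrant_counts[] <- as.double(table(tf, factor(les$quadrant, levels = 1:4)))
  } else {
    les$region <- integer(0)
    les$quadrant <- integer(0)
    les$dd <- numeric(0)
  }
  structure(list(counts = counts, areas = areas, min_dd = min_dd,
                 region_counts = region_counts,
                 quadrant_counts = quadrant_counts,
                 lesions = les, geometry = record$geometry,
                 conf_threshold = conf_threshold,
                 n_total = sum(counts)),
            class = "lesion_summary")
}

#' @export
print.lesion_summary <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat(sprintf("<lesion_summary> %g lesion(s)%s\n", x$n_total,
              if (length(nz)) paste0(": ", paste(names(nz), nz, sep = "=",
                                                 collapse = ", ")) else ""))
  invisible(x)
}

#' Grade a lesion summary with a decision table
#'
#' Evaluates the table's rules highest severity first and returns the
#' first level whose predicate holds; the empty summary reaches the
#' default (lowest) level. The result records which rule fired and the
#' ids of the supporting lesions.
#'
#' `grade_icdrs()` and `grade_nsc()` are thin wrappers binding the two
#' shipped default tables.
#'
#' @param summary a [summarise_lesions()] result.
#' @param table a [grading_table()].
#' @return an object of class `grade_result` with fields `scheme`,
#'   `level`, `level_index` (1-based position on the ladder), `dmo`,
#'   `referable`, `evidence` and (ensemble path only) `probabilities`.
#' @export
grade_summary <- function(summary, table) {
  stopifnot(inherits(summary, "lesion_summary"),
            inherits(table, "grading_scheme"))
  level <- table$default_level
  evidence <- list(rule = "default", lesion_ids = integer(0))
  for (rule in table$rules) {
    for (cond in rule$any) {
      if (condition_holds(cond, summary)) {
        level <- rule$level
        evidence <- list(rule = rule$name,
                         lesion_ids = condition_evidence(cond, summary))
        break
      }
    }
    if (!identical(level, table$default_level)) break
  }
  dmo <- assess_maculopathy(summary, table)
  new_grade_result(table, level, dmo = dmo, evidence = evidence)
}

new_grade_result <- function(table, level, dmo, evidence = NULL,
                             probabilities = NULL) {
  idx <- match(level, table$levels)
  if (is.na(idx)) stop(sprintf("level '%s' is not on the %s ladder",
                               level, table$scheme), call. = FALSE)
  res <- structure(list(scheme = table$scheme, level = level,
                        level_index = idx, dmo = dmo,
                        referable = NA, evidence = evidence,
                        probabilities = probabilities),
                   class = "grade_result")
  res$referable <- is_referable(res, table)
  res
}

#' @rdname grade_summary
#' @export
grade_icdrs <- function(summary, table = grading_table("icdrs")) {
  grade_summary(summary, table)
}

#' @rdname grade_summary
#' @export
grade_nsc <- function(summary, table = grading_table("nsc")) {
  grade_summary(summary, table)
}

#' Grade an image record end to end
#'
#' Convenience wrapper: [summarise_lesions()] then [grade_summary()].
#'
#' @inheritParams summarise_lesions
#' @param table a [grading_table()] (default ICDRS).
#' @return a `grade_result`.
#' @export
grade_record <- function(record, table = grading_table("icdrs"),
                         conf_threshold = 0.5) {
  grade_summary(summarise_lesions(record, conf_threshold), table)
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf("<grade_result> %s %s%s%s (rule: %s)\n", x$scheme, x$level,
              if (isTRUE(x$dmo)) " + maculopathy" else "",
              if (isTRUE(x$referable)) " [referable]" else "",
              x$evidence$rule %||% "ensemble"))
  invisible(x)
}

#' Maculopathy / DMO surrogate assessment
#'
#' Flags maculopathy when any lesion of the configured types (default:
#' exudates) lies within the configured disc-diameter radius of the
#' fovea (default 1 DD). This is a 2-D colour-fundus surrogate for
#' diabetic macular oedema.
#'
#' @param summary a [summarise_lesions()] result.
#' @param table a [grading_table()] carrying the maculopathy config.
#' @return logical.
#' @export
assess_maculopathy <- function(summary, table = grading_table("icdrs")) {
  stopifnot(inherits(summary, "lesion_summary"))
  any(summary$min_dd[table$maculopathy$types] <= table$maculopathy$radius_dd)
}

#' Referability of a grade
#'
#' Deterministic policy lookup: a grade is referable when its level is at
#' or above the scheme's configured referable cut-off, or (if the policy
#' says so) when maculopathy is present. Shipped defaults: ICDRS level
#' >= 2 or DMO; NSC >= R2 or M1.
#'
#' @param result a `grade_result` (or a level label).
#' @param table the [grading_table()] carrying the policy.
#' @param dmo maculopathy flag, used when `result` is a bare level label.
#' @return logical.
#' @export
is_referable <- function(result, table, dmo = FALSE) {
  if (inherits(result, "grade_result")) {
    level <- result$level
    dmo <- isTRUE(result$dmo)
  } else {
    level <- as.character(result)
  }
  idx <- match(level, table$levels)
  if (is.na(idx)) {
    stop(sprintf("unknown level '%s' for scheme %s", level, table$scheme),
         call. = FALSE)
  }
  cut <- match(table$referable$min_level, table$levels)
  idx >= cut || (table$referable$or_maculopathy && dmo)
}

#' Fixed-length feature vector of a lesion summary
#'
#' Deterministic flattening used by the ensemble grader: for each of the
#' 14 DR lesion types (in [dr_lesion_types()] order) the slots are total
#' count, `log(1 + total area)`, then the five per-region counts —
#' 14 x 7 = 98 features, stable across runs.
#'
#' @param summary a [summarise_lesions()] result.
#' @return named numeric vector of length 98.
#' @export
featurise <- function(summary) {
  stopifnot(inherits(summary, "lesion_summary"))
  types <- dr_lesion_types()
  blocks <- lapply(types, function(tp) {
    v <- c(summary$counts[[tp]], log1p(summary$areas[[tp]]),
           summary$region_counts[tp, ])
    names(v) <- paste0(tp, c("_count", "_log_area", paste0("_region", 1:5)))
    v
  })
  unlist(blocks)
}
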