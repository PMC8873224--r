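# Readers and writers for the artifact formats: annotation JSON, ground
# truth and grade tables (CSV), evaluation and progression reports
# (JSON/CSV). All writers use fixed column orders and stable float
# formatting so identical inputs produce byte-identical files.

ANNOTATION_SCHEMA_VERSION <- "1.0"

geometry_to_payload <- function(g) {
  list(disc_centre = g$disc_centre, disc_diameter = g$disc_diameter,
       fovea_centre = g$fovea_centre, image_width = g$image_width,
       image_height = g$image_height)
}

record_to_payload <- function(rec) {
  les <- rec$lesions
  list(image_id = rec$image_id, eye = rec$eye,
       capture_time = rec$capture_time, gradable = rec$gradable,
       geometry = geometry_to_payload(rec$geometry),
       lesions = lapply(seq_len(nrow(les)), function(i) {
         list(id = les$id[i], type = les$type[i], x = les$x[i],
              y = les$y[i], area = les$area[i],
              confidence = les$confidence[i])
       }))
}

#' Write and read annotation documents
#'
#' The annotation document is a JSON file: `schema_version` plus a list
#' of image payloads (image_id, eye, capture_time, gradable, geometry,
#' lesions). Writing then reading yields records equal to the input;
#' schema violations are reported with the offending image and field
#' named.
#'
#' @param records a list of [image_record()] objects (or a single one).
#' @param path file path.
#' @param allow_outside tolerate lesion centroids outside the image
#'   extent on read.
#' @return `read_annotations()` returns a list of [image_record()].
#' @export
write_annotations <- function(records, path) {
  if (inherits(records, "image_record")) records <- list(records)
  doc <- list(schema_version = ANNOTATION_SCHEMA_VERSION,
              images = lapply(records, record_to_payload))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, allow_outside = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$images)) {
    stop("annotation document lacks the 'images' field", call. = FALSE)
  }
  lapply(seq_along(doc$images), function(i) {
    payload_to_record(doc$images[[i]], i, allow_outside)
  })
}

payload_to_record <- function(p, i, allow_outside) {
  where <- sprintf("image %d (id '%s')", i, p$image_id %||% "?")
  need <- function(x, field) {
    if (is.null(x)) stop(sprintf("%s: missing field '%s'", where, field),
                         call. = FALSE)
    x
  }
  g <- need(p$geometry, "geometry")
  geometry <- tryCatch(
    fundus_geometry(unlist(need(g$disc_centre, "geometry.disc_centre")),
                    need(g$disc_diameter, "geometry.disc_diameter"),
                    unlist(need(g$fovea_centre, "geometry.fovea_centre")),
                    need(g$image_width, "geometry.image_width"),
                    need(g$image_height, "geometry.image_height")),
    error = function(e) stop(sprintf("%s: invalid geometry: %s", where,
                                     conditionMessage(e)), call. = FALSE))
  les <- p$lesions %||% list()
  pull <- function(field, default = NULL) {
    vapply(seq_along(les), function(j) {
      v <- les[[j]][[field]] %||% default
      if (is.null(v)) {
        stop(sprintf("%s: lesion %d: missing field '%s'", where, j, field),
             call. = FALSE)
      }
      as.double(v)
    }, 0)
  }
  types <- vapply(seq_along(les), function(j) {
    as.character(les[[j]][["type"]] %||%
      stop(sprintf("%s: lesion %d: missing field 'type'", where, j),
           call. = FALSE))
  }, "")
  bad <- setdiff(unique(types), lesion_types())
  if (length(bad)) {
    stop(sprintf("%s: field 'type': unknown lesion type(s) %s", where,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  lesions <- tryCatch(
    lesion_frame(type = types, x = pull("x"), y = pull("y"),
                 area = pull("area"), confidence = pull("confidence", 1),
                 id = if (length(les)) as.integer(pull("id")) else NULL),
    error = function(e) stop(sprintf("%s: invalid lesions: %s", where,
                                     conditionMessage(e)), call. = FALSE))
  image_record(need(p$image_id, "image_id"), geometry, lesions,
               eye = as.character(p$eye %||% "UNKNOWN"),
               capture_time = as.character(p$capture_time %||% ""),
               gradable = isTRUE(p$gradable %||% TRUE),
               allow_outside = allow_outside)
}

#' Grade every record of a cohort into a grade table
#'
#' One row per image: level, ladder position, maculopathy flag,
#' referability, the rule that fired, and an ordinal severity score
#' (`level_index - 1 + 0.5 * dmo`) usable as a ROC score when ensemble
#' probabilities are not available.
#'
#' @param records a list of [image_record()] or a `dr_cohort`.
#' @param table a [grading_table()].
#' @param conf_threshold lesion confidence threshold (default 0.5).
#' @return data.frame with columns image_id, scheme, level, level_index,
#'   dmo, referable, rule, score.
#' @export
grade_cohort <- function(records, table = grading_table("icdrs"),
                         conf_threshold = 0.5) {
  if (inherits(records, "dr_cohort")) records <- records$records
  rows <- lapply(records, function(rec) {
    g <- grade_record(rec, table, conf_threshold)
    data.frame(image_id = rec$image_id, scheme = g$scheme,
               level = g$level, level_index = g$level_index,
               dmo = g$dmo, referable = g$referable,
               rule = g$evidence$rule,
               score = g$level_index - 1 + 0.5 * g$dmo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write and read ground-truth and grade tables as CSV
#'
#' @param truth,grades data.frames as produced by [sample_cohort()]
#'   (`$truth`) and [grade_cohort()].
#' @param path file path.
#' @return the read functions return data.frames.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(level = "character"))
  need <- setdiff(c("image_id", "level"), names(df))
  if (length(need)) stop("truth table missing column(s): ",
                         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(df$maculopathy)) df$maculopathy <- FALSE
  df
}

#' @rdname write_truth_csv
#' @export
write_grades_csv <- function(grades, path) {
  grades$score <- format_num(grades$score)
  utils::write.csv(grades, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_grades_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(level = "character"))
  need <- setdiff(c("image_id", "level"), names(df))
  if (length(need)) stop("grade table missing column(s): ",
                         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(df$dmo)) df$dmo <- FALSE
  df
}

#' Evaluate a graded cohort against ground truth on the four tasks
#'
#' Joins grade and truth tables on image_id, classifies every image's
#' feature-conditioned confusion outcome for each binary task and
#' summarises each task.
#'
#' @param grades a [grade_cohort()] data.frame (or path).
#' @param truth a truth data.frame (or path) with image_id, level and
#'   optionally maculopathy.
#' @param table the [grading_table()] the levels live on.
#' @param tasks character vector of task names (default all four).
#' @param ci_method `"wilson"` or `"clopper"`.
#' @param conventional logical; use plain confusion counting instead of
#'   the feature-conditioned outcome definitions.
#' @return named list of `eval_summary`, one per task, with an
#'   `outcomes` attribute holding the per-image labels.
#' @export
evaluate_cohort <- function(grades, truth, table = grading_table("icdrs"),
                            tasks = c("DR_VS_NONDR", "REFERABLE",
                                      "PDR_VS_NONPDR", "DMO"),
                            ci_method = "wilson", conventional = FALSE) {
  if (is.character(grades)) grades <- read_grades_csv(grades)
  if (is.character(truth)) truth <- read_truth_csv(truth)
  m <- merge(grades, truth, by = "image_id",
             suffixes = c("_pred", "_gt"))
  if (!nrow(m)) stop("no image_ids shared between grades and truth",
                     call. = FALSE)
  out <- list()
  for (task_name in tasks) {
    task <- binary_task(task_name, table)
    labels <- vapply(seq_len(nrow(m)), function(i) {
      classify_outcome(m$level_pred[i], m$level_gt[i], task,
                       gt_dmo = isTRUE(m$maculopathy[i]),
                       predicted_dmo = isTRUE(m$dmo[i]),
                       conventional = conventional)
    }, "")
    s <- summarise_eval(labels, ci_method = ci_method)
    attr(s, "outcomes") <- labels
    out[[task_name]] <- s
  }
  out
}

#' Flatten an evaluation into one row per task
#'
#' @param evals a named list of `eval_summary` from [evaluate_cohort()].
#' @return data.frame: task, counts, metrics and CI bounds.
#' @export
eval_table <- function(evals) {
  rows <- lapply(names(evals), function(nm) {
    s <- evals[[nm]]
    m <- s$metrics
    row <- data.frame(task = nm, n = s$n, TP = s$counts[["TP"]],
                      TN = s$counts[["TN"]], FP = s$counts[["FP"]],
                      FN = s$counts[["FN"]], stringsAsFactors = FALSE)
    for (metric in rownames(m)) {
      row[[metric]] <- m[metric, "estimate"]
      row[[paste0(metric, "_ci_low")]] <- m[metric, "ci_low"]
      row[[paste0(metric, "_ci_high")]] <- m[metric, "ci_high"]
    }
    row
  })
  do.call(rbind, rows)
}

#' Serialise a progression report
#'
#' `write_progression_json()` writes the full report (transform, grades,
#' events, per-region table); `write_change_events_csv()` writes the
#' flat change-event log.
#'
#' @param report a [compare_visits()] result.
#' @param path file path.
#' @export
write_progression_json <- function(report, path) {
  stopifnot(inherits(report, "progression_report"))
  doc <- list(
    transform = list(scale = report$transform$scale,
                     rotation = report$transform$rotation,
                     translation = report$transform$translation),
    baseline_grade = list(scheme = report$baseline_grade$scheme,
                          level = report$baseline_grade$level,
                          dmo = report$baseline_grade$dmo,
                          referable = report$baseline_grade$referable),
    followup_grade = list(scheme = report$followup_grade$scheme,
                          level = report$followup_grade$level,
                          dmo = report$followup_grade$dmo,
                          referable = report$followup_grade$referable),
    grade_delta = report$grade_delta,
    event_counts = as.list(table(report$events$kind)),
    region_table = as.data.frame.matrix(unclass(report$region_table)),
    events = report$events)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_progression_json
#' @export
write_change_events_csv <- function(report, path) {
  stopifnot(inherits(report, "progression_report"))
  ev <- report$events
  ev$area_ratio <- format_num(ev$area_ratio)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
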