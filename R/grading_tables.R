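# Grading schemes as configurable decision tables.
#
# A scheme is a JSON document: an ordered level ladder plus a list of
# rules, each rule a target level with a disjunction of predicates over a
# lesion summary. Rules are evaluated highest severity first and the
# first satisfied rule wins; the empty lesion set reaches the default
# (lowest) level. The two shipped tables encode the published ICDRS
# scale (including the 4-2-1 severe-NPDR rule) and the UK NSC R-levels;
# every threshold lives in the JSON so graders are swappable without
# code change.

.table_cache <- new.env(parent = emptyenv())

#' Load a grading scheme decision table
#'
#' @param scheme `"icdrs"`, `"nsc"`, or a path to a JSON decision-table
#'   file following the same schema as the two shipped defaults (see
#'   `system.file("extdata", "icdrs.json", package = "drscreen")`).
#' @return an object of class `grading_scheme`.
#' @export
#' @examples
#' tab <- grading_table("icdrs")
#' tab$levels
grading_table <- function(scheme = c("icdrs", "nsc")) {
  if (length(scheme) == 1L && file.exists(scheme) &&
      !(scheme %in% c("icdrs", "nsc"))) {
    return(parse_grading_table(scheme))
  }
  scheme <- match.arg(scheme)
  key <- paste0("table_", scheme)
  if (is.null(.table_cache[[key]])) {
    path <- system.file("extdata", paste0(scheme, ".json"),
                        package = "drscreen", mustWork = TRUE)
    .table_cache[[key]] <- parse_grading_table(path)
  }
  .table_cache[[key]]
}

parse_grading_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("scheme", "levels", "rules", "default_level")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("decision table '%s' is missing field '%s'", path, field),
           call. = FALSE)
    }
  }
  levels <- vapply(doc$levels, as.character, "")
  if (anyDuplicated(levels) || length(levels) < 2L) {
    stop("decision table levels must be >= 2 distinct ordered labels",
         call. = FALSE)
  }
  if (!identical(as.character(doc$default_level), levels[1L])) {
    stop("decision table default_level must be the lowest level",
         call. = FALSE)
  }
  rules <- lapply(doc$rules, function(r) {
    lv <- as.character(r$level)
    if (!lv %in% levels) {
      stop(sprintf("rule targets unknown level '%s'", lv), call. = FALSE)
    }
    conds <- lapply(r$any, parse_condition)
    list(level = lv, level_index = match(lv, levels),
         name = as.character(r$name %||% lv), any = conds)
  })
  idx <- vapply(rules, function(r) r$level_index, 0)
  if (is.unsorted(rev(idx), strictly = TRUE)) {
    stop("decision table rules must be ordered strictly highest severity first",
         call. = FALSE)
  }
  if (any(idx == 1L)) {
    stop("the lowest level is the default and must not carry a rule",
         call. = FALSE)
  }
  mac <- doc$maculopathy %||% list(types = "EXUDATE", radius_dd = 1.0)
  ref <- doc$referable %||% list(min_level = levels[min(3L, length(levels))],
                                 or_maculopathy = TRUE)
  if (!as.character(ref$min_level) %in% levels) {
    stop("referable min_level must be one of the scheme levels", call. = FALSE)
  }
  structure(list(
    scheme = as.character(doc$scheme),
    levels = levels,
    level_names = lapply(doc$level_names %||% list(), as.character),
    rules = rules,
    default_level = levels[1L],
    maculopathy = list(types = vapply(mac$types, as.character, ""),
                       radius_dd = as.double(mac$radius_dd %||% 1.0)),
    referable = list(min_level = as.character(ref$min_level),
                     or_maculopathy = isTRUE(ref$or_maculopathy))
  ), class = "grading_scheme")
}

parse_condition <- function(cond) {
  kind <- as.character(cond$kind %||% "")
  known <- c("present", "count_ge", "per_quadrant_count_ge",
             "quadrants_present_ge", "area_ge", "min_dd_le")
  if (!kind %in% known) {
    stop(sprintf("unknown predicate kind '%s' (known: %s)", kind,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  types <- vapply(cond$types, as.character, "")
  bad <- setdiff(types, lesion_types())
  if (length(bad)) {
    stop("predicate references unknown lesion type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(kind = kind, types = types,
       count = if (!is.null(cond$count)) as.double(cond$count),
       quadrants = if (!is.null(cond$quadrants)) as.integer(cond$quadrants),
       area = if (!is.null(cond$area)) as.double(cond$area),
       dd = if (!is.null(cond$dd)) as.double(cond$dd))
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat(sprintf("<grading_scheme> %s: levels %s; %d rule(s); referable >= %s%s\n",
              x$scheme, paste(x$levels, collapse = " < "), length(x$rules),
              x$referable$min_level,
              if (x$referable$or_maculopathy) " or maculopathy" else ""))
  invisible(x)
}

# Evaluate one predicate against a lesion summary.
condition_holds <- function(cond, summary) {
  counts <- summary$counts[cond$types]
  switch(cond$kind,
    present = sum(counts) > 0,
    count_ge = sum(counts) >= cond$count,
    per_quadrant_count_ge = {
      per_q <- colSums(summary$quadrant_counts[cond$types, , drop = FALSE])
      sum(per_q >= cond$count) >= cond$quadrants
    },
    quadrants_present_ge = {
      per_q <- colSums(summary$quadrant_counts[cond$types, , drop = FALSE])
      sum(per_q > 0) >= cond$quadrants
    },
    area_ge = sum(summary$areas[cond$types]) >= cond$area,
    min_dd_le = any(summary$min_dd[cond$types] <= cond$dd),
    stop("unreachable predicate kind")
  )
}

# Lesion ids supporting a satisfied predicate (evidence trail).
condition_evidence <- function(cond, summary) {
  les <- summary$lesions
  ids <- les$id[les$type %in% cond$types]
  if (cond$kind == "min_dd_le") {
    d <- distance_dd(cbind(les$x, les$y), summary$geometry)
    ids <- les$id[les$type %in% cond$types & d <= cond$dd]
  }
  sort(ids)
}

# TRUE iff any predicate of `rule` holds for `summary`.
rule_holds <- function(rule, summary) {
  for (cond in rule$any) if (condition_holds(cond, summary)) return(TRUE)
  FALSE
}

#' Which decision-table levels does a summary satisfy?
#'
#' Diagnostic helper used by the synthetic generator's soundness checks:
#' evaluates every rule of `table` against `summary` independently of the
#' highest-first short-circuit.
#'
#' @param summary a [summarise_lesions()] result.
#' @param table a [grading_table()].
#' @return named logical vector, one entry per rule (named by level).
#' @export
satisfied_levels <- function(summary, table) {
  stopifnot(inherits(summary, "lesion_summary"),
            inherits(table, "grading_scheme"))
  out <- vapply(table$rules, function(r) rule_holds(r, summary), TRUE)
  names(out) <- vapply(table$rules, function(r) r$level, "")
  out
}
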