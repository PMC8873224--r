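# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit double loops, pairwise enumeration) and
# never call the implementation paths they check.

tiny_geometry <- function() {
  fundus_geometry(disc_centre = c(300, 0), disc_diameter = 100,
                  fovea_centre = c(0, 0),
                  image_width = 1024, image_height = 1024)
}

record_with <- function(types, dd = NULL, x = NULL, y = NULL,
                        area = NULL, confidence = NULL,
                        geometry = default_fundus_geometry()) {
  n <- length(types)
  if (is.null(x)) {
    dd <- dd %||% rep(2, n)
    # place lesions along distinct angles at the requested DD distances
    theta <- seq(0.3, 5.9, length.out = max(n, 1))[seq_len(n)]
    x <- geometry$fovea_centre[1] + dd * geometry$disc_diameter * cos(theta)
    y <- geometry$fovea_centre[2] + dd * geometry$disc_diameter * sin(theta)
  }
  image_record("fixture", geometry,
               lesion_frame(type = types, x = x, y = y,
                            area = area %||% rep(25, n),
                            confidence = confidence),
               allow_outside = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force quadratic weighted kappa: explicit O and E tabulation with
# scalar double loops.
brute_qwk <- function(a, b, k) {
  n <- length(a)
  O <- matrix(0, k, k)
  for (i in seq_len(n)) O[a[i] + 1, b[i] + 1] <- O[a[i] + 1, b[i] + 1] + 1
  E <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) E[i, j] <- sum(O[i, ]) * sum(O[, j]) / n
  num <- 0
  den <- 0
  for (i in 1:k) for (j in 1:k) {
    w <- (i - j)^2 / (k - 1)^2
    num <- num + w * O[i, j]
    den <- den + w * E[i, j]
  }
  1 - num / den
}

# Rank-statistic AUC: Mann-Whitney U over all positive/negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Closed-form Wilson interval written out independently.
brute_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  lo <- (p + z^2 / (2 * n) - z * sqrt((p * (1 - p) + z^2 / (4 * n)) / n)) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt((p * (1 - p) + z^2 / (4 * n)) / n)) /
    (1 + z^2 / n)
  c(max(0, lo), min(1, hi))
}

# Exhaustive operating-point search over every curve row.
brute_operating_point <- function(curve, mode, floor) {
  sens <- curve$tpr
  spec <- 1 - curve$fpr
  target <- if (mode == "HIGH_SENSITIVITY") sens else spec
  other <- if (mode == "HIGH_SPECIFICITY") sens else spec
  feasible <- which(target >= floor)
  if (!length(feasible)) return(NULL)
  best <- feasible[1]
  for (i in feasible) {
    if (other[i] > other[best] ||
        (other[i] == other[best] && target[i] > target[best])) best <- i
  }
  list(sensitivity = sens[best], specificity = spec[best])
}

# A random progression script whose events are guaranteed applicable to
# the baseline; returns a progression_script. Targets are picked here so
# no two events touch the same lesion.
random_script <- function(baseline, seed) {
  withr::with_seed(seed, {
    les <- baseline$lesions
    events <- data.frame(kind = character(), lesion_type = character(),
                         region = integer(), area_factor = numeric(),
                         baseline_id = integer())
    for (i in seq_len(sample(1:3, 1))) {
      events <- rbind(events, data.frame(
        kind = "NEW",
        lesion_type = sample(c("MA", "HAEMORRHAGE", "EXUDATE"), 1),
        region = sample(1:4, 1), area_factor = NA_real_,
        baseline_id = NA_integer_))
    }
    pool <- les$id
    for (kind in c("RESOLVED", "GROWN", "SHRUNK")) {
      if (!length(pool) || sample(0:1, 1) == 0) next
      id <- if (length(pool) == 1) pool else sample(pool, 1)
      pool <- setdiff(pool, id)
      events <- rbind(events, data.frame(
        kind = kind, lesion_type = les$type[les$id == id],
        region = NA_integer_, area_factor = NA_real_, baseline_id = id))
    }
    progression_script(events, random_camera(seed + 13))
  })
}

# Canonical sortable representation of a change log for exact comparison.
event_key <- function(df) {
  keys <- sprintf("%s|%s|%d|%s|%s", df$kind, df$lesion_type, df$region,
                  ifelse(is.na(df$baseline_id), "-", df$baseline_id),
                  ifelse(is.na(df$followup_id), "-", df$followup_id))
  sort(keys)
}
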