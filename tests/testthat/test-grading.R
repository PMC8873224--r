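icdrs <- grading_table("icdrs")
nsc <- grading_table("nsc")

test_that("summarise_lesions books counts, regions and the confidence filter", {
  g <- default_fundus_geometry()
  empty <- summarise_lesions(image_record("e", g))
  expect_true(all(empty$counts == 0))
  expect_identical(empty$n_total, 0)

  rec <- record_with(rep("MA", 3), dd = c(0.3, 0.5, 0.8), geometry = g)
  s <- summarise_lesions(rec, conf_threshold = 0)
  expect_identical(s$counts[["MA"]], 3)
  expect_identical(s$region_counts["MA", "region1"], 3)
  expect_identical(sum(s$region_counts["MA", ]), s$counts[["MA"]])

  rec2 <- record_with(c("MA", "MA"), dd = c(1, 2),
                      confidence = c(0.3, 0.9), geometry = g)
  expect_identical(summarise_lesions(rec2, 0.5)$counts[["MA"]], 1)
  # artefacts never count
  rec3 <- record_with(c("ARTEFACT", "MA"), dd = c(1, 2), geometry = g)
  s3 <- summarise_lesions(rec3, 0)
  expect_identical(s3$counts[["MA"]], 1)
  expect_identical(s3$n_total, 1)
})

test_that("the ICDRS decision table grades canonical lesion sets", {
  cases <- list(
    list(types = character(), level = "0"),
    list(types = c("MA", "MA", "MA"), level = "1"),
    list(types = c("MA", "HAEMORRHAGE", "EXUDATE"), level = "2"),
    list(types = "NVE", level = "4"),
    list(types = "IRMA", level = "3"),
    list(types = c("VENOUS_BEADING"), level = "2"),  # single quadrant
    list(types = "SCAR", level = "0"))
  for (case in cases) {
    rec <- record_with(case$types, dd = rep(2, length(case$types)))
    g <- grade_record(rec, icdrs, conf_threshold = 0)
    expect_identical(g$level, case$level)
  }
  # 4-2-1: >= 20 haemorrhages in each quadrant
  geom <- default_fundus_geometry()
  qpos <- do.call(rbind, lapply(list(c(1, -1), c(-1, -1), c(-1, 1),
                                     c(1, 1)), function(s) {
    cbind(geom$fovea_centre[1] + s[1] * seq(40, 420, length.out = 20),
          geom$fovea_centre[2] + s[2] * seq(420, 40, length.out = 20))
  }))
  rec <- image_record("q", geom,
                      lesion_frame(type = rep("HAEMORRHAGE", 80),
                                   x = qpos[, 1], y = qpos[, 2],
                                   area = rep(50, 80)))
  expect_identical(grade_record(rec, icdrs)$level, "3")
  # beading in two quadrants is severe; evidence names the rule
  rec2 <- image_record("b", geom,
                       lesion_frame(type = rep("VENOUS_BEADING", 2),
                                    x = geom$fovea_centre[1] + c(100, -100),
                                    y = geom$fovea_centre[2] - c(100, 100),
                                    area = c(60, 60)))
  g2 <- grade_record(rec2, icdrs)
  expect_identical(g2$level, "3")
  expect_identical(g2$evidence$rule, "severe-4-2-1")
  expect_identical(g2$evidence$lesion_ids, 1:2)
})

test_that("the NSC decision table grades canonical lesion sets", {
  cases <- list(
    list(types = character(), level = "R0"),
    list(types = c("MA", "HAEMORRHAGE", "EXUDATE"), level = "R1"),
    list(types = "IRMA", level = "R2"),
    list(types = rep("BLOT_HAEMORRHAGE", 5), level = "R2"),
    list(types = rep("BLOT_HAEMORRHAGE", 4), level = "R1"),
    list(types = "PRERETINAL_HAEMORRHAGE", level = "R3"))
  for (case in cases) {
    rec <- record_with(case$types, dd = rep(2, length(case$types)))
    expect_identical(grade_record(rec, nsc, conf_threshold = 0)$level,
                     case$level)
  }
})

test_that("maculopathy depends on exudate distance to the fovea", {
  expect_false(assess_maculopathy(summarise_lesions(record_with("MA",
                                                                dd = 0.2))))
  s_in <- summarise_lesions(record_with("EXUDATE", dd = 0.5))
  s_out <- summarise_lesions(record_with("EXUDATE", dd = 2.5))
  expect_true(assess_maculopathy(s_in))
  expect_false(assess_maculopathy(s_out))
  g_in <- grade_summary(s_in, nsc)
  expect_true(g_in$dmo)
  expect_identical(g_in$level, "R1")
  expect_true(g_in$referable)  # M1 makes R1 referable
})

test_that("referability follows the configured policy", {
  mk <- function(level, dmo, tab) {
    is_referable(level, tab, dmo = dmo)
  }
  expect_false(mk("0", FALSE, icdrs))
  expect_false(mk("1", FALSE, icdrs))
  expect_true(mk("2", FALSE, icdrs))
  expect_true(mk("1", TRUE, icdrs))
  expect_false(mk("R1", FALSE, nsc))
  expect_true(mk("R1", TRUE, nsc))
  expect_true(mk("R2", FALSE, nsc))
  expect_error(mk("R9", FALSE, nsc), "unknown level")
})

test_that("featurise is a stable 98-long flattening", {
  empty <- featurise(summarise_lesions(image_record("e",
                                                    default_fundus_geometry())))
  expect_length(empty, 98L)
  expect_true(all(empty == 0))
  rec <- record_with(rep("MA", 3), dd = c(0.3, 0.5, 0.8),
                     area = c(4, 4, 4))
  v <- featurise(summarise_lesions(rec, 0))
  expect_identical(v[["MA_count"]], 3)
  expect_equal(v[["MA_log_area"]], log(13))
  expect_identical(v[["MA_region1"]], 3)
  expect_true(all(v[setdiff(names(v), c("MA_count", "MA_log_area",
                                        "MA_region1"))] == 0))
})

test_that("grading is deterministic and monotone under lesion addition", {
  geom <- default_fundus_geometry()
  for (i in 1:200) {
    seed <- 5000 + i
    lv <- sample(icdrs$levels, 1)
    rec <- synthesise_for_level(icdrs, lv, seed = seed)
    g1 <- grade_record(rec, icdrs)
    g2 <- grade_record(rec, icdrs)
    expect_identical(g1, g2)
    # add one random lesion: level never decreases under either table
    extra_type <- withr::with_seed(seed, sample(dr_lesion_types(), 1))
    les <- rec$lesions
    les <- rbind(les, data.frame(id = max(les$id, 0L) + 1L,
                                 type = extra_type,
                                 x = geom$fovea_centre[1] + 200,
                                 y = geom$fovea_centre[2] - 150,
                                 area = 40, confidence = 1))
    rec2 <- image_record("aug", geom, les, allow_outside = TRUE)
    for (tab in list(icdrs, nsc)) {
      expect_gte(grade_record(rec2, tab)$level_index,
                 grade_record(rec, tab)$level_index)
    }
  }
})

test_that("default tables are concordant at the ladder extremes", {
  for (seed in 1:100) {
    lv <- sample(icdrs$levels, 1)
    rec <- synthesise_for_level(icdrs, lv, seed = 60000 + seed)
    gi <- grade_record(rec, icdrs)
    gn <- grade_record(rec, nsc)
    if (gi$level == "4") expect_identical(gn$level, "R3")
    if (gi$level == "0") expect_identical(gn$level, "R0")
  }
})

test_that("malformed decision tables are rejected", {
  bad <- tempfile(fileext = ".json")
  doc <- jsonlite::read_json(system.file("extdata", "icdrs.json",
                                         package = "drscreen"))
  doc$rules <- rev(doc$rules)  # unordered
  jsonlite::write_json(doc, bad, auto_unbox = TRUE)
  expect_error(grading_table(bad), "highest severity first")
  doc2 <- jsonlite::read_json(system.file("extdata", "icdrs.json",
                                          package = "drscreen"))
  doc2$default_level <- "2"
  jsonlite::write_json(doc2, bad, auto_unbox = TRUE)
  expect_error(grading_table(bad), "default_level")
})
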