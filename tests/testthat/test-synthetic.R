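test_that("prevalence presets reproduce the published dataset compositions", {
  china <- prevalence_preset("china")
  saudi <- prevalence_preset("saudi")
  kenya <- prevalence_preset("kenya")
  expect_identical(sum(china$counts), 15000)
  expect_identical(sum(saudi$counts), 10026)
  expect_identical(sum(kenya$counts), 28680)
  expect_equal(unname(china$proportions),
               unname(china$counts / sum(china$counts)))
  expect_equal(sum(china$proportions), 1, tolerance = 1e-9)
  expect_identical(china$scheme, "nsc")
  expect_identical(kenya$scheme, "icdrs")
  expect_error(prevalence_config("nsc", c(R0 = 0.5, R1 = 0.6, R2 = 0,
                                          R3 = 0)), "sum to 1")
})

test_that("synthesised lesion sets satisfy exactly the target level", {
  # inverse-table soundness: target rule holds, no higher rule holds
  for (scheme in c("icdrs", "nsc")) {
    tab <- grading_table(scheme)
    for (lv in tab$levels) {
      for (seed in seq(1, 60, by = 3)) {
        rec <- synthesise_for_level(tab, lv, seed = seed)
        s <- summarise_lesions(rec)
        sat <- satisfied_levels(s, tab)
        target_idx <- match(lv, tab$levels)
        higher <- sat[match(names(sat), tab$levels) > target_idx]
        expect_true(all(!higher))
        if (target_idx > 1L) {
          expect_true(sat[[lv]])
        } else {
          expect_identical(nrow(rec$lesions), 0L)
        }
      }
    }
  }
})

test_that("maculopathy planting respects feasibility", {
  icdrs <- grading_table("icdrs")
  nsc <- grading_table("nsc")
  expect_error(synthesise_for_level(icdrs, "0", maculopathy = TRUE),
               "infeasible")
  expect_error(synthesise_for_level(icdrs, "1", maculopathy = TRUE),
               "infeasible")
  expect_error(synthesise_for_level(nsc, "R0", maculopathy = TRUE),
               "infeasible")
  for (seed in 1:10) {
    rec <- synthesise_for_level(nsc, "R1", maculopathy = TRUE, seed = seed)
    g <- grade_record(rec, nsc)
    expect_identical(g$level, "R1")
    expect_true(g$dmo)
    rec2 <- synthesise_for_level(nsc, "R1", maculopathy = FALSE, seed = seed)
    expect_false(grade_record(rec2, nsc)$dmo)
  }
})

test_that("cohorts are deterministic and track the prevalence preset", {
  c1 <- sample_cohort("china", 40, seed = 8)
  c2 <- sample_cohort("china", 40, seed = 8)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$records[[17]]$lesions, c2$records[[17]]$lesions)
  c3 <- sample_cohort("china", 40, seed = 9)
  expect_false(identical(c1$truth$level, c3$truth$level))

  big <- sample_cohort("china", 3000, seed = 12,
                       noise = noise_model())  # zero noise
  frac <- table(factor(big$truth$level, levels = c("R0", "R1", "R2", "R3"))) /
    3000
  expect_true(all(abs(frac - prevalence_preset("china")$proportions) < 0.03))
})

test_that("detector noise behaves as specified", {
  tab <- grading_table("icdrs")
  rec <- synthesise_for_level(tab, "3", seed = 5)  # many lesions
  # zero noise is the identity
  expect_identical(apply_detector_noise(rec, noise_model(), seed = 1), rec)

  # misses are Binomial(k, 1 - m): chi-square goodness of fit
  k <- nrow(rec$lesions)
  m <- 0.3
  counts <- vapply(1:600, function(s) {
    nrow(apply_detector_noise(rec, noise_model(miss_prob = m),
                              seed = s)$lesions)
  }, 0)
  expect_equal(mean(counts) / k, 1 - m, tolerance = 0.05)
  breaks <- unique(qbinom(c(0.2, 0.4, 0.6, 0.8), k, 1 - m))
  bins <- cut(counts, c(-1, breaks, k))
  probs <- diff(c(0, pbinom(breaks, k, 1 - m), 1))
  gof <- suppressWarnings(chisq.test(table(bins), p = probs))
  expect_gt(gof$p.value, 0.01)

  # false alarms add lesions, including artefacts that never grade
  healthy <- image_record("h", default_fundus_geometry())
  noisy <- apply_detector_noise(healthy,
                                noise_model(false_alarm_rate = c(ARTEFACT = 4)),
                                seed = 3)
  expect_gt(nrow(noisy$lesions), 0)
  expect_identical(grade_record(noisy, tab)$level, "0")
})

test_that("synthesise_pair returns the exact ground-truth change log", {
  tab <- grading_table("icdrs")
  base <- synthesise_for_level(tab, "2", seed = 21)
  # empty script, zero noise: all STABLE
  empty <- progression_script(data.frame(kind = character(),
                                         lesion_type = character()))
  pair0 <- synthesise_pair(base, empty, seed = 1)
  rep0 <- compare_visits(base, pair0$followup)
  expect_true(all(rep0$events$kind == "STABLE"))

  # planted events recovered exactly, including ids and regions
  for (seed in 1:40) {
    b <- synthesise_for_level(tab, "2", seed = 700 + seed)
    pair <- synthesise_pair(b, random_script(b, seed), seed = seed)
    rep <- compare_visits(b, pair$followup)
    expect_identical(event_key(rep$events), event_key(pair$truth))
  }

  # inapplicable events error
  bad <- progression_script(data.frame(kind = "RESOLVED",
                                       lesion_type = "NVD"))
  expect_error(synthesise_pair(image_record("h", default_fundus_geometry()),
                               bad, seed = 1), "no eligible")
})

test_that("phantom rendering and the demo detector round-trip", {
  pg <- phantom_geometry()
  # empty record: nothing detected outside disc/vessels
  empty_rec <- image_record("empty", pg)
  img0 <- render_phantom(empty_rec, seed = 2)
  expect_identical(nrow(demo_detect(img0, pg)$lesions), 0L)

  les <- lesion_frame(type = c("EXUDATE", "EXUDATE", "EXUDATE", "EXUDATE",
                               "EXUDATE", "MA", "HAEMORRHAGE"),
                      x = c(120, 260, 150, 250, 80, 180, 150),
                      y = c(120, 120, 300, 280, 200, 60, 200),
                      area = c(60, 80, 60, 70, 60, 9, 100))
  rec <- image_record("ph", pg, les)
  det <- demo_detect(render_phantom(rec, seed = 2), pg)
  expect_identical(sum(det$lesions$type == "EXUDATE"), 5L)
  # every planted blob recovered within 0.1 DD
  for (i in seq_len(nrow(les))) {
    d <- sqrt((det$lesions$x - les$x[i])^2 + (det$lesions$y - les$y[i])^2)
    expect_lt(min(d) / pg$disc_diameter, 0.1)
  }
  # end-to-end: rendered mild phantom grades mild
  mild <- image_record("mild", pg,
                       lesion_frame(type = rep("MA", 3),
                                    x = c(150, 250, 200),
                                    y = c(150, 150, 270), area = rep(8, 3)))
  det_mild <- demo_detect(render_phantom(mild, seed = 4), pg)
  expect_identical(grade_record(det_mild, grading_table("icdrs"))$level, "1")
})
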