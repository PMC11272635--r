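fake_records <- function(impinged_regions) {
  # impinged_regions: named vector condition_id -> region, others clear
  data.frame(patient_id = 1L, tilt_deg = 0, condition_id = 1:12,
             mode = "x", limiting_angle = 10,
             impinged = as.character(1:12) %in% names(impinged_regions),
             region = ifelse(as.character(1:12) %in% names(impinged_regions),
                             impinged_regions[as.character(1:12)],
                             NA_character_),
             stringsAsFactors = FALSE)
}

test_that("incidence follows count / 12 * 100 exactly on the whole lattice", {
  for (n in 0:12) {
    regs <- if (n > 0) setNames(rep("A", n), as.character(seq_len(n)))
    else setNames(character(0), character(0))
    inc <- compute_incidence(fake_records(regs))
    expect_identical(inc$incidence_pct[inc$region == "A"], n / 12 * 100)
    expect_identical(inc$incidence_pct[inc$region == "total"], n / 12 * 100)
    expect_equal(inc$incidence_pct[inc$region == "A"] * 12 / 100, n)
  }
})

test_that("incidence handles saturation, mixtures and empty runs", {
  allA <- compute_incidence(fake_records(setNames(rep("A", 12),
                                                  as.character(1:12))))
  expect_equal(allA$incidence_pct[allA$region == "A"], 100)
  expect_equal(allA$incidence_pct[allA$region == "total"], 100)

  four <- compute_incidence(fake_records(setNames(rep("A", 4),
                                                  as.character(1:4))))
  expect_equal(four$incidence_pct, c(100 / 3, 0, 0, 100 / 3),
               tolerance = 1e-12)

  none <- compute_incidence(fake_records(setNames(character(0), character(0))))
  expect_true(all(none$incidence_pct == 0))

  mix <- compute_incidence(fake_records(c(`1` = "A", `2` = "B", `5` = "C",
                                          `9` = "A")))
  counts <- setNames(mix$count, mix$region)
  expect_equal(counts[["total"]], counts[["A"]] + counts[["B"]] + counts[["C"]])
})

test_that("malformed record sets are rejected", {
  r <- fake_records(c(`1` = "A"))
  expect_error(compute_incidence(r[-1, ]), "12")
  r2 <- r; r2$condition_id[2] <- 1L
  expect_error(compute_incidence(r2), "condition ids")
})

test_that("cohort summaries report means, SDs and subgroups correctly", {
  # two patients, identical A incidence 50 at all tilts
  recs <- do.call(rbind, lapply(1:2, function(pid) {
    do.call(rbind, lapply(c(-10, 0, 10), function(tau) {
      r <- fake_records(setNames(rep("A", 6), as.character(1:6)))
      r$patient_id <- pid; r$tilt_deg <- tau
      r
    }))
  }))
  cov <- data.frame(patient_id = 1:2, aiis_type = c("I", "II"),
                    alpha_angle = 60, lcea = c(20, 45),
                    acetabular_version = 18, femoral_version = c(2, 30),
                    head_radius = 24)
  inc <- cohort_incidence(recs, cov)
  expect_true(all(inc$incidence_pct[inc$region == "A"] == 50))
  s <- summarize_cohort(inc)
  tot <- s$overall[s$overall$region == "total", ]
  expect_true(all(tot$mean == 50))
  expect_true(all(tot$sd == 0))
  expect_setequal(s$by_fv$group, c("low", "high"))       # 2 and 30 degrees
  expect_setequal(s$by_lcea$group, c("low", "high"))     # 20 and 45 degrees

  # single-patient subgroup: SD reported as NA, not propagated
  expect_true(all(is.na(s$by_aiis$sd)))

  # incidence values lie on the 100/12 lattice
  expect_true(all(abs(inc$incidence_pct * 12 / 100 -
                        round(inc$incidence_pct * 12 / 100)) < 1e-9))
})

test_that("the incidence CSV contract round-trips", {
  recs <- fake_records(c(`3` = "A", `7` = "B"))
  recs <- do.call(rbind, lapply(c(-10, 0, 10), function(tau) {
    r <- recs; r$tilt_deg <- tau; r
  }))
  cov <- data.frame(patient_id = 1L, aiis_type = "II", alpha_angle = 67,
                    lcea = 31, acetabular_version = 19, femoral_version = 14,
                    head_radius = 24)
  inc <- cohort_incidence(recs, cov)
  path <- tempfile(fileext = ".csv")
  write_incidence_csv(inc, path)
  back <- read_incidence_csv(path)
  expect_equal(back$incidence_pct, inc$incidence_pct)
  expect_identical(names(back), names(inc))
})
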