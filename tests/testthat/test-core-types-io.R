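test_that("glycemia conversion uses the fixed 18 mg/dL per mM factor", {
  expect_equal(convert_glycemia(180, "mg/dL", "mM"), 10)
  expect_equal(convert_glycemia(0, "mg/dL", "mM"), 0)
  expect_equal(convert_glycemia(90, "mg/dL", "mM"), 5)
  expect_equal(convert_glycemia(10, "mM", "mg/dL"), 180)
  # round trip is identity to 1e-12 relative
  x <- c(3.7, 86.4, 250)
  expect_equal(convert_glycemia(convert_glycemia(x, "mg/dL", "mM"),
                                "mM", "mg/dL"), x, tolerance = 1e-12)
  expect_error(convert_glycemia(1, "mol/L", "mM"), "unknown glycemia unit")
})

test_that("insulinemia conversion uses 6.945 pM per uU/mL", {
  expect_equal(convert_insulinemia(1, "uU/mL", "pM"), 6.945)
  expect_equal(convert_insulinemia(0, "uU/mL", "pM"), 0)
  expect_equal(convert_insulinemia(10, "uU/mL", "pM"), 69.45)
  x <- c(4.32, 8.30, 100)
  expect_equal(convert_insulinemia(convert_insulinemia(x, "uU/mL", "pM"),
                                   "pM", "uU/mL"), x, tolerance = 1e-12)
  expect_error(convert_insulinemia(1, "mU/L", "pM"),
               "unknown insulinemia unit")
})

test_that("ogtt_record enforces protocol invariants", {
  rec <- make_clinical_record()
  expect_s3_class(rec, "ogtt_record")
  expect_equal(rec$glycemia[1], 86.4 / 18)
  expect_equal(rec$insulinemia[1], 4.32 * 6.945)
  expect_equal(rec$dose_mmol, 75 / 0.18)
  expect_error(ogtt_record("s", c(30, 60, 90, 120, 150), 1:5, 1:5),
               "basal")
  expect_error(ogtt_record("s", c(0, 60, 30, 90, 120), 1:5, 1:5),
               "strictly increasing")
  expect_error(ogtt_record("s", c(0, 30), c(5, -1), c(30, 40)),
               "finite and > 0")
  expect_error(ogtt_record("s", c(0, 30, 60), 1:2, 1:3), "equal length")
})

test_that("long and wide OGTT CSVs read to identical records", {
  long <- data.frame(
    subject_id = rep(c("a", "b"), each = 5),
    time_min = rep(c(0, 30, 60, 90, 120), 2),
    glycemia = c(86.4, 120, 135, 110, 95, 90, 140, 150, 120, 100),
    insulinemia = c(4.32, 25, 40, 30, 15, 6, 30, 50, 40, 20))
  fl <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, fl, row.names = FALSE)
  recs_l <- read_ogtt_table(fl)
  expect_length(recs_l, 2)
  expect_equal(length(recs_l$a$times), 5)
  expect_equal(recs_l$a$glycemia[1], 4.8)

  wide <- data.frame(subject_id = c("a", "b"))
  for (k in seq_along(c(0, 30, 60, 90, 120))) {
    t <- c(0, 30, 60, 90, 120)[k]
    wide[[paste0("glycemia_", t)]] <- long$glycemia[long$time_min == t]
    wide[[paste0("insulinemia_", t)]] <- long$insulinemia[long$time_min == t]
  }
  fw <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, fw, row.names = FALSE)
  recs_w <- read_ogtt_table(fw)
  expect_equal(recs_w$a$glycemia, recs_l$a$glycemia)
  expect_equal(recs_w$b$insulinemia, recs_l$b$insulinemia)

  # missing basal row names the subject
  bad <- long[!(long$subject_id == "b" & long$time_min == 0), ]
  fb <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, fb, row.names = FALSE)
  expect_error(read_ogtt_table(fb), "'b'")
})

test_that("write/read round trip preserves numeric content exactly", {
  recs <- list(a = make_clinical_record("a"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ogtt_table(recs, f)
  back <- read_ogtt_table(f, glycemia_unit = "mM", insulinemia_unit = "pM")
  expect_identical(back$a$glycemia, recs$a$glycemia)
  expect_identical(back$a$insulinemia, recs$a$insulinemia)
})

test_that("packaged reference table has the 14 printed rows and bounds", {
  rt <- load_reference_ranges()
  expect_equal(nrow(rt), 14)
  gb <- rt[rt$index == "G_b", ]
  expect_equal(c(gb$healthy_lo, gb$healthy_hi), c(4.10, 5.03))
  expect_equal(c(gb$undesirable_lo, gb$undesirable_hi), c(5.03, 5.29))
  expect_equal(gb$abnormal_direction, "above")
  expect_equal(gb$abnormal_bound, 5.29)
  kjs <- rt[rt$index == "k_js", ]
  expect_equal(c(kjs$healthy_lo, kjs$healthy_hi), c(0.0198, 0.244))
  expect_equal(kjs$abnormal_direction, "below")
  expect_equal(kjs$abnormal_bound, 0.01)
  expect_equal(rt[rt$index == "eta", "units"], "L^-3")
})

test_that("every reference row is interval-adjacent and direction-consistent", {
  rt <- load_reference_ranges()
  for (i in seq_len(nrow(rt))) {
    r <- rt[i, ]
    if (r$abnormal_direction == "below") {
      expect_equal(r$undesirable_hi, r$healthy_lo, info = r$index)
      expect_equal(r$abnormal_bound, r$undesirable_lo, info = r$index)
    } else {
      expect_equal(r$undesirable_lo, r$healthy_hi, info = r$index)
      expect_equal(r$abnormal_bound, r$undesirable_hi, info = r$index)
    }
  }
})

test_that("range classification respects boundaries toward health", {
  expect_equal(classify_in_ranges(4.5, "G_b"), "normal")
  expect_equal(classify_in_ranges(5.10, "G_b"), "undesirable")
  expect_equal(classify_in_ranges(5.40, "G_b"), "abnormal")
  # shared boundary takes the healthier label
  expect_equal(classify_in_ranges(5.03, "G_b"), "normal")
  expect_equal(classify_in_ranges(5.29, "G_b"), "undesirable")
  # below-direction index
  expect_equal(classify_in_ranges(0.05, "k_js"), "normal")
  expect_equal(classify_in_ranges(0.015, "k_js"), "undesirable")
  expect_equal(classify_in_ranges(0.005, "k_js"), "abnormal")
  expect_equal(classify_in_ranges(0.0198, "k_js"), "normal")
  expect_error(classify_in_ranges(1, "nope"), "unknown index")
})
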