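test_that("method/assay/unit screen keeps comparable chemistry only", {
  recs <- make_records(
    make_record(sample_id = "a", assay = "stannous_chloride"),
    make_record(sample_id = "b", assay = "molybdenum_blue"),
    make_record(sample_id = "c", assay = "ion_chromatography"),
    make_record(sample_id = "d", assay = "unknown"),
    make_record(sample_id = "e", assay = "molybdenum_blue",
                unit = "volumetric"),
    make_record(sample_id = "f", value = NA_real_))
  dec <- screen_method(recs)
  expect_equal(dec$keep, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(dec$reason, c("method", NA, NA, NA, "unit", "malformed"))
})

test_that("detection limits are inferred from repeated low values", {
  set.seed(11)
  vals <- c(rep(1.0, 40), runif(400, 5, 80))
  inf <- infer_detection_limit(vals)
  expect_equal(inf$half_limit, 1.0)
  expect_equal(inf$implied_limit, 2.0)

  # nothing repeats: no limit
  expect_null(infer_detection_limit(seq(1, 50, by = 0.5)))
  # a repeated value that is not low (constant source): no limit
  expect_null(infer_detection_limit(rep(50, 100)))
  # repeated value in the middle of the distribution: not a limit
  expect_null(infer_detection_limit(c(rep(40, 30), runif(100, 1, 80))))
  expect_null(infer_detection_limit(numeric(0)))
})

test_that("half-limit substitution follows the censoring convention", {
  expect_equal(substitute_detection_limit(1.5, FALSE, limit = 2), 1.0)
  expect_equal(substitute_detection_limit(30, FALSE, limit = 2), 30)
  expect_equal(substitute_detection_limit(0, TRUE, limit = 4), 2.0)
  # at-limit values untouched by default, substituted when configured
  expect_equal(substitute_detection_limit(2, FALSE, limit = 2), 2)
  expect_equal(substitute_detection_limit(2, FALSE, limit = 2,
                                          at_limit = TRUE), 1)
  expect_error(substitute_detection_limit(-1, FALSE, 2), "invalid")
})

test_that("substitution never increases a value and is idempotent", {
  set.seed(21)
  v <- c(runif(200, 0, 10), rep(0.5, 5))
  flag <- runif(205) < 0.2
  out1 <- substitute_detection_limit(v, flag, limit = 2)
  expect_true(all(out1 <= pmax(v, 1)))
  expect_true(all(out1[flag | v < 2] == 1))
  # idempotent: a substituted table passes through unchanged
  out2 <- substitute_detection_limit(out1, FALSE, limit = 2)
  expect_identical(out1, out2)
})

test_that("geo-temporal screen applies window, exemptions and province rules", {
  cfg <- filter_config(exempt_sources = "sahel_misc",
                       china_source_id = "CTSDB")
  recs <- make_records(
    make_record(sample_id = "a", year = 1998L),
    make_record(sample_id = "b", year = 1990L, source_id = "sahel_misc"),
    make_record(sample_id = "c", year = 1996L, source_id = "CTSDB",
                province = "Anhui"),
    make_record(sample_id = "d", year = 1994L, source_id = "CTSDB",
                province = "Qinghai"),
    make_record(sample_id = "e", year = 1996L, source_id = "CTSDB",
                province = "Qinghai"),
    make_record(sample_id = "f", year = 2010L),
    make_record(sample_id = "g", longitude = 0, latitude = 0),
    make_record(sample_id = "h", latitude = 95))
  dec <- filter_geotemporal(recs, cfg)
  expect_equal(dec$reason,
               c("year", NA, "province", "year", NA, NA,
                 "georeference", "georeference"))
})

test_that("land mask discards off-land records via nearest-cell lookup", {
  mask <- p_grid(matrix(c(1, 0, 1, 1), 2, 2), xmin = 0, ymin = 0, res = 1)
  cfg <- filter_config(land_mask = mask)
  recs <- make_records(
    make_record(sample_id = "on", longitude = 0.5, latitude = 0.5),
    make_record(sample_id = "off", longitude = 0.5, latitude = 1.5),
    make_record(sample_id = "out", longitude = 5, latitude = 5))
  dec <- filter_geotemporal(recs, cfg)
  expect_equal(dec$reason, c(NA, "land_mask", "land_mask"))
})

test_that("filtering one record at a time equals filtering the batch", {
  cfg <- filter_config(exempt_sources = "x", china_source_id = "CTSDB")
  set.seed(5)
  recs <- do.call(rbind, lapply(1:40, function(i)
    make_record(sample_id = paste0("r", i),
                year = sample(c(1990L, 1997L, 2005L, 2018L), 1),
                source_id = sample(c("src_a", "x", "CTSDB"), 1),
                province = sample(c("Anhui", "Qinghai", NA), 1),
                longitude = sample(c(10, 0), 1),
                latitude = sample(c(45, 0), 1))))
  batch <- filter_geotemporal(recs, cfg)
  single <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i)
    filter_geotemporal(recs[i, , drop = FALSE], cfg)))
  rownames(single) <- NULL
  expect_equal(batch, single)
})

test_that("filter report conserves every record through the full screen", {
  recs <- make_records(
    make_record(sample_id = "a"),
    make_record(sample_id = "b", assay = "stannous_chloride"),
    make_record(sample_id = "c", year = 1950L),
    make_record(sample_id = "d", unit = "volumetric"),
    make_record(sample_id = "e", value = 1.2))
  out <- filter_samples(recs)
  rp <- out$report
  expect_equal(rp$input_n, 5L)
  expect_equal(rp$kept_n + rp$discarded_n, rp$input_n)
  expect_equal(sum(unlist(rp$discarded_by_reason)), rp$discarded_n)
  expect_equal(rp$discarded_by_reason,
               list(method = 1L, unit = 1L, year = 1L))
  # kept below-limit value substituted with default limit 2
  expect_equal(out$records$value[out$records$sample_id == "e"], 1.0)
  # report survives a JSON round trip
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_filter_report(rp, tf)
  rt <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(rt$kept_n, rp$kept_n)
})

test_that("per-source manifest limits override inference and default", {
  recs <- do.call(rbind, lapply(1:20, function(i)
    make_record(sample_id = paste0("r", i), value = 3 + i)))
  recs$value[1] <- 3.5  # below a manifest limit of 4
  out <- filter_samples(recs,
                        manifest = data.frame(source_id = "src_a",
                                              detection_limit = 4))
  expect_equal(out$detection_limits[["src_a"]], 4)
  expect_equal(out$records$value[1], 2.0)
})
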