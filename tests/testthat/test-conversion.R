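test_that("weighted mean equation is the sample-size-weighted combination", {
  eqs <- rbind(
    conversion_equation("mehlich3", "non_calcareous", 0.33, 6.9, 0.88, 91),
    conversion_equation("mehlich3", "non_calcareous", 0.47, 1.2, 0.79, 180),
    conversion_equation("mehlich3", "non_calcareous", 0.70, -0.6, 0.71, 66))
  wm <- weighted_mean_equation(eqs)
  # independent arithmetic: sum(n_i * x_i) / sum(n_i), computed directly
  expect_equal(wm$slope, (91 * 0.33 + 180 * 0.47 + 66 * 0.70) / 337)
  expect_equal(wm$intercept, (91 * 6.9 + 180 * 1.2 - 66 * 0.6) / 337)
  expect_equal(wm$r_squared, (91 * 0.88 + 180 * 0.79 + 66 * 0.71) / 337)
  expect_equal(wm$n_samples, 337L)

  # a single equation combines to itself
  one <- weighted_mean_equation(eqs[1, ])
  expect_equal(one$slope, 0.33)
  expect_equal(one$n_samples, 91L)

  expect_error(weighted_mean_equation(eqs[0, ]), "no equations")
  expect_error(weighted_mean_equation(rbind(
    eqs[1, ], conversion_equation("bray1", "any", 0.5, 1, 0.5, 10))),
    "incompatible")
})

test_that("weighted mean is order-invariant and split-invariant", {
  eqs <- rbind(
    conversion_equation("bray1", "non_calcareous", 0.43, 2.4, 0.68, 180),
    conversion_equation("bray1", "non_calcareous", 0.68, 3.9, 0.95, 165),
    conversion_equation("bray1", "non_calcareous", 0.30, 2.9, 0.85, 91))
  a <- weighted_mean_equation(eqs)
  b <- weighted_mean_equation(eqs[c(3, 1, 2), ])
  expect_equal(a$slope, b$slope)
  expect_equal(a$intercept, b$intercept)
  # split one component into two halves with identical coefficients
  half <- eqs[1, ]; half$n_samples <- 90L
  half2 <- half
  split_eqs <- rbind(half, half2, eqs[2:3, ])
  s <- weighted_mean_equation(split_eqs)
  expect_equal(s$slope, a$slope)
  expect_equal(s$intercept, a$intercept)
  # convexity: combined coefficients inside the component range
  expect_gte(a$slope, min(eqs$slope)); expect_lte(a$slope, max(eqs$slope))
  expect_gte(a$intercept, min(eqs$intercept))
  expect_lte(a$intercept, max(eqs$intercept))
})

test_that("registry routing handles pH gates, aliases and identity", {
  reg <- default_registry()
  # Bray-I on a calcareous-pH soil is rejected
  r <- resolve_equation("bray1", "non_calcareous", pH = 7.3, registry = reg)
  expect_equal(r$status, "reject")
  expect_equal(r$reason, "pH")
  # Kirsanov aliases to the combined Bray-I equation (same extractant family)
  k <- resolve_equation("kirsanov", "non_calcareous", pH = 5.5,
                        registry = reg)
  expect_equal(k$status, "ok")
  expect_equal(k$equation$slope, 0.49)
  expect_equal(k$equation$intercept, 3.1)
  # and inherits the pH gate
  k7 <- resolve_equation("kirsanov", "non_calcareous", pH = 7.5,
                         registry = reg)
  expect_equal(k7$status, "reject")
  # Olsen needs no conversion
  o <- resolve_equation("olsen", "any", NA, reg)
  expect_equal(o$equation$slope, 1)
  expect_equal(o$equation$intercept, 0)
  # unknown class routes via pH
  m_lo <- resolve_equation("mehlich3", "unknown", pH = 6.0, registry = reg)
  expect_equal(m_lo$equation$soil_class, "non_calcareous")
  m_hi <- resolve_equation("mehlich3", "unknown", pH = 8.0, registry = reg)
  expect_equal(m_hi$equation$soil_class, "calcareous")
  expect_error(resolve_equation("acetate", "any", NA, reg), "no conversion")
})

test_that("conversion applies the linear map, floored and increasing", {
  expect_equal(as.numeric(to_olsen(10, eq_bray())), 8.0)
  expect_equal(as.numeric(to_olsen(20, eq_m3_c())), 9.3)
  reg <- default_registry()
  ident <- resolve_equation("olsen", "any", NA, reg)$equation
  expect_equal(as.numeric(to_olsen(12, ident)), 12)
  # strictly increasing and non-negative
  v <- seq(0, 100, by = 5)
  out <- as.numeric(to_olsen(v, eq_m3_nc()))
  expect_true(all(diff(out) > 0))
  expect_true(all(out >= 0))
  expect_error(to_olsen(-1, eq_bray()), "non-negative")
})

test_that("synthetic round trip through the inverse map is exact", {
  reg <- default_registry()
  set.seed(42)
  olsen_true <- runif(200, 5, 80)
  for (id in c("bray1_any_combined", "mehlich3_non_calcareous_combined",
               "mehlich3_calcareous_combined", "abdpta_any_combined")) {
    eq <- reg$combined[reg$combined$equation_id == id, ]
    raw <- (olsen_true - eq$intercept) / eq$slope
    expect_equal(as.numeric(to_olsen(raw, eq)), olsen_true, tolerance = 1e-12)
  }
})

test_that("convert_samples annotates a mixed-method table", {
  recs <- make_records(
    make_record(sample_id = "a", method = "olsen", value = 12),
    make_record(sample_id = "b", method = "bray1", value = 10, pH = 6),
    make_record(sample_id = "c", method = "bray1", value = 10, pH = 7.4),
    make_record(sample_id = "d", method = "mehlich3", value = 20,
                soil_class = "calcareous", pH = 8),
    make_record(sample_id = "e", method = "kirsanov", value = 10, pH = 5))
  out <- convert_samples(recs)
  expect_equal(out$olsen_p, c(12, 8.0, NA, 9.3, 8.0))
  expect_equal(out$convert_status,
               c("identity", "converted", "rejected_ph", "converted",
                 "converted"))
  expect_equal(out$equation_id[2], "bray1_any_combined")
  expect_equal(out$equation_id[5], "bray1_any_combined")
})

test_that("conversion validation recovers slope 1 on agreeing pairs", {
  eq <- eq_bray()
  set.seed(7)
  raw <- runif(200, 2, 60)
  pred <- as.numeric(to_olsen(raw, eq))
  # exact agreement (lm warns about the intentionally perfect fit)
  v0 <- suppressWarnings(validate_conversion(raw, pred, eq))
  expect_equal(v0$slope, 1.0, tolerance = 1e-10)
  expect_equal(v0$nse, 1.0, tolerance = 1e-10)
  # constant shift: slope 1, intercept 5
  v5 <- suppressWarnings(validate_conversion(raw, pred + 5, eq))
  expect_equal(v5$slope, 1.0, tolerance = 1e-10)
  expect_equal(v5$intercept, 5.0, tolerance = 1e-8)
  # zero-mean noise at 10% of the signal sd: slope within [0.9, 1.1]
  noisy <- pred + rnorm(200, 0, 0.1 * sd(pred))
  vn <- validate_conversion(raw, noisy, eq)
  expect_gt(vn$slope, 0.9); expect_lt(vn$slope, 1.1)
  expect_lt(vn$p_value, 0.001)
  expect_error(validate_conversion(rep(3, 5), runif(5), eq), "no variance")
})

test_that("registry rebuilt from a component CSV matches the default", {
  reg <- default_registry(printed = FALSE)
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write_registry_csv(reg, tf)
  reg2 <- build_registry(tf)
  expect_equal(reg2$combined$slope, reg$combined$slope, tolerance = 1e-12)
  expect_equal(reg2$combined$intercept, reg$combined$intercept,
               tolerance = 1e-12)
  # combined slope within the range of its components, per method
  for (m in unique(reg2$combined$method)) {
    comp <- reg2$components[reg2$components$method == m, ]
    comb <- reg2$combined[reg2$combined$method == m, ]
    expect_true(all(comb$slope >= min(comp$slope) - 1e-12 &
                    comb$slope <= max(comp$slope) + 1e-12))
  }
})
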