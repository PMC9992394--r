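# Shared fixtures: small in-code tables and grids used across test files.

# one-row canonical sample record with overridable fields
make_record <- function(...) {
  rec <- data.frame(
    source_id = "src_a", sample_id = "r1",
    longitude = 10.0, latitude = 45.0, year = 2010L,
    depth_top = 0, depth_bottom = 20,
    method = "olsen", assay = "molybdenum_blue",
    value = 12, unit = "mass", below_detection = FALSE,
    pH = 6.0, soil_class = "non_calcareous",
    country = "aland", province = NA_character_,
    land_use = NA_character_, stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) rec[[nm]] <- ov[[nm]]
  rec
}

make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# 3x3 toy grid with distinct values, cell size 1 deg, origin (0, 0):
# values[row, col] = 10*row + col (row 1 = southernmost)
toy_grid <- function() {
  p_grid(outer(1:3, 1:3, function(r, c) 10 * r + c),
         xmin = 0, ymin = 0, res = 1)
}

# printed combined equations, for arithmetic checks
eq_bray <- function() default_registry()$combined[
  default_registry()$combined$equation_id == "bray1_any_combined", ]
eq_m3_nc <- function() default_registry()$combined[
  default_registry()$combined$equation_id == "mehlich3_non_calcareous_combined", ]
eq_m3_c <- function() default_registry()$combined[
  default_registry()$combined$equation_id == "mehlich3_calcareous_combined", ]
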