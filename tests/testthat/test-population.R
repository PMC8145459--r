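# Growth curves, body composition, perfusion and subject sampling.

test_that("height polynomials return the printed constants at age 0 and
           plausible values across childhood", {
  expect_identical(height_for_age(0, "male"), 52.91366922873476)
  expect_identical(height_for_age(0, "female"), 49.589645987915)
  # independent Horner evaluation of the printed male coefficients at 12 y
  expect_equal(height_for_age(12, "male"), 152.170245, tolerance = 1e-6)
  # and it must lie inside the observed 11-12 y male percentile band
  expect_gt(height_for_age(12, "male"), 131.04)
  expect_lt(height_for_age(12, "male"), 167.00)
  expect_error(height_for_age(19, "male"), "0-18")
  expect_error(height_for_age(1, "boy"), "male")
})

test_that("mean height curves are non-decreasing within the 0.5 cm wiggle
           guard on a fine age grid", {
  grid <- seq(0, 18, by = 0.1)
  for (sx in c("male", "female")) {
    d <- diff(height_for_age(grid, sx))
    expect_gt(min(d), -0.5)
  }
})

test_that("weight model matches independent evaluations", {
  # at age 0 the saturating term vanishes (1 - e^0 = 0): pure exponential
  ht0 <- height_for_age(0, "female")
  expect_equal(weight_for(0, ht0, "female"), exp(0.023 * ht0), tolerance = 1e-12)
  expect_equal(weight_for(0, ht0, "female"), 3.1285, tolerance = 1e-4)
  expect_equal(weight_for(0, 60, "male"), 0 + exp(0.025 * 60), tolerance = 1e-12)
  # combined-exponent reading at the adult end of the range
  expect_equal(weight_for(18, 172, "male"),
               4.665 * (1 - exp(-1.661 * 18)) + exp(0.025 * 172 - 0.015 * 18),
               tolerance = 1e-12)
  expect_equal(weight_for(18, 172, "male"), 60.93, tolerance = 1e-3)
})

test_that("BSA uses Haycock below 15 kg and Du Bois at or above 15 kg", {
  expect_equal(body_surface_area(3.5, 50), 0.224415, tolerance = 1e-5)
  expect_equal(body_surface_area(70, 170), 1.825326, tolerance = 1e-5)
  # boundary is 'equal to or greater': 15 kg takes the Du Bois branch
  expect_identical(body_surface_area(15, 100),
                   15^0.425 * 100^0.725 * 0.007246)
  expect_error(body_surface_area(-1, 100), "positive")
})

test_that("the Haycock/Du Bois branch discontinuity at 15 kg is small where
           the formulas overlap", {
  for (h in seq(90, 110, by = 2.5)) {
    hay <- 15^0.5378 * h^0.3964 * 0.024265
    dub <- 15^0.425 * h^0.725 * 0.007246
    expect_lt(abs(hay - dub) / dub, 0.04)
  }
  # near 100 cm the two formulas nearly agree
  hay <- 15^0.5378 * 100^0.3964 * 0.024265
  dub <- 15^0.425 * 100^0.725 * 0.007246
  expect_lt(abs(hay - dub) / dub, 0.005)
})

test_that("cardiac output follows the double-exponential model", {
  # the two exponentials cancel at age 0
  expect_equal(cardiac_output(0, 0.8), 197.444 * 0.8, tolerance = 1e-12)
  expect_equal(cardiac_output(3, 0.6), 174.4932, tolerance = 1e-4)
  expect_equal(cardiac_output(18, 1.73), 415.99, tolerance = 1e-3)
  # single interior maximum of CO per BSA near 3.6 years
  peak <- optimize(function(a) -cardiac_output(a, 1), c(0, 18))$minimum
  expect_equal(peak, 3.5815, tolerance = 1e-3)
  # asymptote for large ages
  expect_equal(cardiac_output(400, 1), 197.444, tolerance = 1e-6)
})

test_that("recalibrated organ volumes match the printed equations", {
  expect_equal(organ_volume("liver", "male", bsa_m2 = 1), 0.679)
  expect_equal(organ_volume("liver", "female", bsa_m2 = 1), 0.695)
  expect_equal(organ_volume("kidney", "male", weight_kg = 30),
               13.028 * 30^0.713 / 1000)
  expect_equal(organ_volume("kidney", "male", weight_kg = 30), 0.14725,
               tolerance = 1e-4)
  expect_error(organ_volume("muscle", "male", weight_kg = 30),
               "default_tissue_volume")
})

test_that("reference-table tissues interpolate in age and grow with body
           size", {
  expect_equal(default_tissue_volume("muscle", 18, 70), 0.38 * 70)
  # blood volume grows between infancy and late childhood for mean subjects
  wt1 <- weight_for(1, height_for_age(1, "male"), "male")
  wt10 <- weight_for(10, height_for_age(10, "male"), "male")
  expect_gt(default_tissue_volume("blood", 10, wt10),
            default_tissue_volume("blood", 1, wt1))
  expect_error(default_tissue_volume("liver", 5, 20), "not a reference-table")
})

test_that("blood flows close to cardiac output and scale linearly", {
  q <- blood_flows(300, 10)
  venous_return <- c("brain", "heart", "kidney", "liver", "adipose",
                     "muscle", "skin", "bone", "rest")
  expect_equal(sum(q[venous_return]), 300, tolerance = 1e-9)
  expect_equal(unname(q["liver"]),
               unname(q["hepatic_artery"] + q["gut"] + q["spleen"] + q["pancreas"]))
  expect_equal(unname(q["lung"]), 300)
  # adult liver receives about a quarter of cardiac output
  q18 <- blood_flows(100, 18)
  expect_equal(unname(q18["liver"]) / 100, 0.255, tolerance = 1e-9)
  expect_equal(unname(blood_flows(600, 10)), unname(2 * q), tolerance = 1e-12)
})

test_that("GFR maturation is sigmoid in postmenstrual age", {
  # direct evaluation of the configured Hill function at 1 year, 0.40 m2
  expect_equal(gfr_for(1, 0.40), 25.28, tolerance = 1e-3)
  # adult limit approaches the reference 121 mL/min per 1.73 m2
  expect_gt(gfr_for(18, 1.73), 0.95 * 121)
  expect_lt(gfr_for(18, 1.73), 121)
  g <- gfr_for(seq(0, 18, by = 0.25), 1)
  expect_true(all(diff(g) > 0))
})

test_that("haematocrit/albumin sampling honours the observed bands", {
  expect_equal(hematocrit_albumin_for(17.5, "male", sd_scale = 0),
               c(hematocrit_frac = 0.4684, albumin_g_L = 49.88))
  expect_equal(unname(hematocrit_albumin_for(11.5, "female", sd_scale = 0)["albumin_g_L"]),
               47.90)
  # constant defaults below the tabulated bands
  expect_equal(hematocrit_albumin_for(4, "male"),
               c(hematocrit_frac = 0.38, albumin_g_L = 44))
  set.seed(11)
  draws <- replicate(200, hematocrit_albumin_for(12, "male")["hematocrit_frac"])
  expect_true(all(draws >= 0.37 & draws <= 0.473))
})

test_that("zero variability reproduces the deterministic curves and seeds
           give bit-identical populations", {
  spec <- population_spec(8, 8, 3, prop_female = 0, seed = 42,
                          variability = no_var)
  pop <- generate_population(spec)
  expect_equal(unique(pop$height_cm), height_for_age(8, "male"))
  expect_equal(unique(pop$weight_kg),
               weight_for(8, height_for_age(8, "male"), "male"))
  pop2 <- generate_population(spec)
  expect_identical(pop, pop2)
  set.seed(99); s1 <- sample_subject(population_spec(0, 18, 1, seed = NULL))
  set.seed(99); s2 <- sample_subject(population_spec(0, 18, 1, seed = NULL))
  expect_identical(s1, s2)
})

test_that("sampled subjects satisfy the physiological invariants", {
  spec <- population_spec(0, 18, 50, seed = 314)
  pop <- generate_population(spec)
  for (s in population_subjects(pop)) {
    expect_true(all(s$organ_volumes_L > 0))
    expect_true(all(s$blood_flows_L_h > 0))
    expect_gt(s$gfr_mL_min, 0)
    expect_gt(s$mppgl_mg_g, 0)
    venous_return <- c("brain", "heart", "kidney", "liver", "adipose",
                       "muscle", "skin", "bone", "rest")
    expect_equal(sum(s$blood_flows_L_h[venous_return]),
                 s$cardiac_output_L_h, tolerance = 1e-6)
    # whole-body density bound
    expect_lt(sum(s$organ_volumes_L), s$weight_kg / 0.95)
  }
})

test_that("simulated 11-12 y male anthropometry matches the survey within
           one observed SD", {
  pop <- generate_population(population_spec(11, 12, 800, prop_female = 0,
                                             seed = 2024))
  expect_lt(abs(mean(pop$height_cm) - 147.67), 9.15)
  expect_lt(abs(mean(pop$weight_kg) - 40.60), 10.59)
  expect_gt(mean(pop$height_cm >= 131.04 & pop$height_cm <= 167.00), 0.90)
})

test_that("population specs validate and round-trip through YAML", {
  expect_error(population_spec(-1, 5, 10), "age_min")
  expect_error(population_spec(3, 19, 10), "age_min")
  expect_error(population_spec(1, 5, 10, prop_female = 1.2), "prop_female")
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(age_min = 2, age_max = 6, n = 5, prop_female = 0.4,
                        seed = 7, variability = list(cv_height = 0.05)), path)
  sp <- read_population_spec(path)
  expect_equal(sp$age_max_y, 6)
  expect_equal(sp$variability$cv_height, 0.05)
  expect_equal(sp$variability$cv_organ, 0.20)
})
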