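# reference values, coverage percentages, risk classification

test_that("iodine_ul is the exact product and rejects degenerate input", {
  expect_equal(iodine_ul(30, 55), 1650)
  expect_equal(iodine_ul(40, 65), 2600)
  expect_error(iodine_ul(0, 55), "positive")
  expect_error(iodine_ul(30, -1), "positive")
})

test_that("coverage reproduces published percentage cells", {
  refs <- fixture_reference_set()
  cov_npnl <- coverage(
    nutrient_vector(iron = 14.2, niacin = 9.9, basis = "per_day"),
    refs, "npnl")
  expect_equal(cov_npnl$pct_rni[cov_npnl$nutrient == "iron"], 24)   # /58.8
  expect_equal(cov_npnl$pct_ul[cov_npnl$nutrient == "niacin"], 28)  # /35

  cov_pl <- coverage(
    nutrient_vector(folate = 1149, vitamin_a = 60785, basis = "per_day"),
    refs, "pl")
  fol <- cov_pl[cov_pl$nutrient == "folate", ]
  expect_equal(fol$pct_ul, 115)                                     # /1000
  expect_equal(fol$pct_rni, 192)                                    # /600
  expect_equal(fol$class, "above_UL")
  va <- cov_pl[cov_pl$nutrient == "vitamin_a", ]
  expect_equal(va$pct_ul, 2026)                                     # /3000
  expect_equal(va$class, "above_UL")

  zero <- coverage(nutrient_vector(basis = "per_day"), refs, "npnl")
  expect_true(all(zero$pct_ear == 0))
  expect_true(all(zero$class == "below_EAR"))

  # zinc for PL women carries no UL
  zn <- cov_pl[cov_pl$nutrient == "zinc", ]
  expect_true(is.na(zn$pct_ul))
  expect_equal(zn$ul_status, "no_UL_assessment")
})

test_that("classification boundaries and rule order", {
  refs <- reference_set(data.frame(
    nutrient = nutrient_units()$nutrient, group = "npnl",
    ear = 10, rni = 20, ul = c(40, NA, 40, 40, 40, 40)))
  # intake exactly RNI, no UL defined -> adequate
  cv <- coverage(nutrient_vector(zinc = 20, basis = "per_day"), refs, "npnl")
  expect_equal(cv$class[cv$nutrient == "zinc"], "adequate")
  # midpoint of (EAR, RNI)
  cv2 <- coverage(nutrient_vector(iron = 15, basis = "per_day"), refs, "npnl")
  expect_equal(cv2$class[cv2$nutrient == "iron"], "EAR_to_RNI")
  # above_UL iff unrounded intake > UL: exactly UL is not above
  cv3 <- coverage(nutrient_vector(iron = 40, basis = "per_day"), refs, "npnl")
  expect_equal(cv3$class[cv3$nutrient == "iron"], "adequate")
  cv4 <- coverage(nutrient_vector(iron = 40.0001, basis = "per_day"),
                  refs, "npnl")
  expect_equal(cv4$class[cv4$nutrient == "iron"], "above_UL")

  expect_error(ref_get(fixture_reference_set(), "iron", "infant"),
               "missing reference")
})

test_that("classify agrees with a brute-force comparator on random draws", {
  brute <- function(x, ear, rni, ul) {
    if (!is.na(ul) && x > ul) return("above_UL")
    if (x < ear) return("below_EAR")
    if (x < rni) return("EAR_to_RNI")
    "adequate"
  }
  set.seed(77)
  for (i in 1:1000) {
    ear <- runif(1, 1, 50)
    rni <- ear * runif(1, 1, 3)
    ul <- if (runif(1) < 0.25) NA else rni * runif(1, 0.5, 5)
    x <- runif(1, 0, 2 * max(rni, ul, na.rm = TRUE))
    refs <- reference_set(data.frame(
      nutrient = nutrient_units()$nutrient, group = "npnl",
      ear = ear, rni = rni, ul = ul))
    cv <- coverage(nutrient_vector(iron = x, basis = "per_day"), refs, "npnl")
    expect_equal(cv$class[cv$nutrient == "iron"], brute(x, ear, rni, ul))
  }
})

test_that("percentages are homogeneous of degree 1 before rounding", {
  refs <- fixture_reference_set()
  set.seed(9)
  for (i in 1:20) {
    x <- runif(6, 0, 500)
    k <- runif(1, 0.1, 10)
    r1 <- attr(coverage(as_nutrient_vector(x, "per_day"), refs, "npnl"), "raw")
    r2 <- attr(coverage(as_nutrient_vector(k * x, "per_day"), refs, "npnl"),
               "raw")
    expect_equal(r2, k * r1, tolerance = 1e-12)
  }
})

test_that("below_EAR implies pct_RNI < 100 whenever EAR < RNI", {
  refs <- fixture_reference_set()
  set.seed(13)
  for (g in c("npnl", "pl")) {
    for (i in 1:50) {
      cv <- coverage(as_nutrient_vector(runif(6, 0, 800), "per_day"), refs, g)
      raw <- attr(cv, "raw")
      for (n in cv$nutrient) {
        r <- ref_get(refs, n, g)
        if (r$ear < r$rni && cv$class[cv$nutrient == n] == "below_EAR") {
          expect_lt(raw[n, "rni"], 100)
        }
      }
    }
  }
})

test_that("reference CSV round-trips", {
  refs <- fixture_reference_set()
  lines <- write_reference_set(refs)
  back <- read_reference_set(lines)
  expect_equal(back$values$ear, refs$values$ear)
  expect_equal(back$values$ul, refs$values$ul)
  expect_equal(back$values$source, refs$values$source)
})
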