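test_that("diagnosis codes are grouped to the 3 characters before the decimal", {
  expect_equal(normalize_diagnosis_code("E11.9"), "E11")
  expect_equal(normalize_diagnosis_code("I50"), "I50")
  expect_equal(normalize_diagnosis_code("C25.0"), "C25")
  expect_equal(normalize_diagnosis_code("c22.1"), "C22")
  expect_equal(normalize_diagnosis_code("T36.1X5A"), "T36")
  expect_equal(normalize_diagnosis_code("0010.2"), "001")
  expect_error(normalize_diagnosis_code(""), "non-empty")
  expect_error(normalize_diagnosis_code(character(0)), "non-empty")
})

test_that("code mapping is a lookup with identity fallback", {
  m <- code_mapping(c("250.00" = "E11.9", "401.9" = "I10"))
  expect_equal(apply_code_mapping("250.00", m), "E11.9")
  expect_equal(apply_code_mapping("401.9", m), "I10")
  expect_equal(apply_code_mapping("E11.9", code_mapping()), "E11.9")
  expect_equal(apply_code_mapping(c("250.00", "unknown"), m), c("E11.9", "unknown"))
  expect_equal(apply_code_mapping("x", NULL), "x")
})

test_that("code mapping files load with auto-detected delimiter", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target", "250.00,E11.9", "401.9,I10"), f)
  m <- read_code_mapping(f)
  expect_equal(apply_code_mapping("250.00", m), "E11.9")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "250.00\tE11.9"), f2)
  m2 <- read_code_mapping(f2)
  expect_equal(apply_code_mapping("250.00", m2), "E11.9")
  expect_error(read_code_mapping(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("frequencies count each code once per patient", {
  r1 <- make_record(1, visits = list(
    list(date = "2015-01-01", events = dx_events("E11.9")),
    list(date = "2015-06-01", events = dx_events("E11.0")),
    list(date = "2016-01-01", events = dx_events(c("E11", "I50")))))
  r2 <- make_record(2, visits = list(
    list(date = "2015-01-01", events = dx_events("I50"))))
  freq <- compute_code_frequencies(list(r1, r2))
  # E11.9 / E11.0 / E11 all group to E11 and count once for patient 1
  expect_equal(unname(freq[names(freq) == "E11"]), 1L)
  expect_equal(unname(freq[names(freq) == "I50"]), 2L)
  expect_false("J44" %in% names(freq))
})

test_that("the rare-code filter removes strictly-below-threshold codes only", {
  freq <- stats::setNames(c(1L, 2L, 10L), c("A01", "A02", "A03"))
  attr(freq, "domain") <- rep("diagnosis", 3)
  kept <- filter_rare_codes(freq, n_patients = 2000, threshold = 0.001)
  expect_false("A01" %in% names(kept))   # 0.05% -> removed
  expect_true("A02" %in% names(kept))    # exactly 0.1% -> retained
  expect_true("A03" %in% names(kept))
  expect_error(filter_rare_codes(freq, 0), "n_patients")
  expect_error(filter_rare_codes(freq, 100, threshold = 0), "threshold")
})

test_that("raising the threshold never grows the retained set", {
  set.seed(1)
  freq <- stats::setNames(sample(1:50, 30, replace = TRUE), sprintf("C%02d", 1:30))
  prev <- names(filter_rare_codes(freq, 1000, 0.001))
  for (thr in c(0.005, 0.01, 0.02, 0.05)) {
    cur <- names(filter_rare_codes(freq, 1000, thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("decile boundaries equal the brute-force eCDF-inverse computation", {
  set.seed(42)
  brute <- function(x) sort(x)[ceiling((1:9) * length(x) / 10)]
  for (i in 1:10) {
    n <- sample(10:2000, 1)
    x <- switch(1 + i %% 3,
                stats::rlnorm(n, 2, 0.7),
                stats::runif(n, -5, 20),
                stats::rexp(n, 0.1))
    fitted <- fit_lab_deciles(list(lab = x))$lab
    expect_equal(fitted, brute(x))
    expect_true(all(diff(fitted) >= 0))
  }
})

test_that("small or degenerate lab samples are handled with warnings", {
  expect_warning(out <- fit_lab_deciles(list(tiny = c(1, 2, 3))), "excluded")
  expect_null(out$tiny)
  expect_warning(out <- fit_lab_deciles(list(flat = rep(5, 20))), "identical")
  expect_equal(out$flat, rep(5, 9))
  expect_equal(discretize_lab("flat", 5, out), "LAB:flat:0")
})

test_that("lab discretization counts boundaries strictly below, clipped to 0..9", {
  vocab <- list(b = sort(stats::quantile(1:100, (1:9) / 10, type = 1, names = FALSE)))
  expect_equal(discretize_lab("b", -100, vocab), "LAB:b:0")
  expect_equal(discretize_lab("b", 1e9, vocab), "LAB:b:9")
  expect_equal(discretize_lab("b", 55, vocab), "LAB:b:5")
  expect_equal(discretize_lab("b", 10, vocab), "LAB:b:0")   # boundary not strictly below
  expect_error(discretize_lab("zzz", 1, vocab), "unknown lab code")
})

test_that("with n = 10 distinct training values each value gets its own bin", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5, 8, 7, 6)
  b <- fit_lab_deciles(list(l = x))$l
  bins <- vapply(sort(x), function(v) sum(b < v), numeric(1))
  expect_equal(bins, 0:9)
})

test_that("each decile bin receives 5-15% of continuous training values", {
  set.seed(99)
  x <- stats::rlnorm(5000, 3, 0.8)
  b <- fit_lab_deciles(list(l = x))$l
  bins <- vapply(x, function(v) sum(b < v), numeric(1))
  share <- as.numeric(table(factor(bins, levels = 0:9))) / length(x)
  expect_true(all(share >= 0.05 & share <= 0.15))
})

test_that("build_vocabulary filters, fits deciles, and assigns ids deterministically", {
  sim <- small_cohort(n = 40, seed = 11)
  v1 <- build_vocabulary(sim$records)
  v2 <- build_vocabulary(sim$records)
  expect_identical(v1$tokens, v2$tokens)
  # structural tokens first, in fixed order
  expect_equal(v1$tokens[1:6], c("PAD", "SEP", "T0", "T1", "T2", "T3"))
  # bijectivity
  ids <- seq_along(v1$tokens)
  expect_equal(unname(encode_tokens(v1, decode_tokens(v1, ids))), ids)
  # every retained lab contributes exactly 10 decile tokens
  for (code in names(v1$lab_deciles)) {
    expect_equal(sum(startsWith(v1$tokens, paste0("LAB:", code, ":"))), 10L)
    expect_length(v1$lab_deciles[[code]], 9L)
  }
})

test_that("the rare-code threshold controls retained diagnosis tokens", {
  recs <- c(
    lapply(1:5, function(i) make_record(i, visits = list(
      list(date = "2015-01-01", events = dx_events(c("E11", "I50")))))),
    list(make_record(6, visits = list(
      list(date = "2015-01-01", events = dx_events("J44"))))))
  v <- build_vocabulary(recs, threshold = 0.3)
  dx <- v$tokens[startsWith(v$tokens, "DX:")]
  expect_setequal(dx, c("DX:E11", "DX:I50"))  # J44 in 1/6 < 30%
  expect_error(build_vocabulary(recs, threshold = 0.999), "empty")
})

test_that("vocabulary JSON serialization round-trips", {
  sim <- small_cohort(n = 25, seed = 13)
  v <- build_vocabulary(sim$records)
  f <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, f)
  v2 <- read_vocabulary(f)
  expect_identical(v$tokens, v2$tokens)
  expect_equal(v$lab_deciles, v2$lab_deciles)
  expect_equal(v$frequencies, v2$frequencies)
  expect_equal(v$threshold, v2$threshold)
  expect_equal(v$n_patients, v2$n_patients)
})
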