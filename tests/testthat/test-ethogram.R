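test_that("duration profiles count seconds per score and merge duplicates", {
  p <- to_profile(c(rep(-2, 100), rep(0, 60), rep(3, 10)))
  expect_identical(as.integer(p), c(100L, 60L, 10L))
  expect_identical(names(p), c("-2", "0", "3"))
  expect_equal(sum(p), 170)

  expect_equal(sum(to_profile(rep(-4, 170))), 170)
  expect_identical(names(to_profile(rep(-4, 170))), "-4")

  # absorbing kill at second 50 of 170: killing owns seconds 50..170
  s <- c(rep(-1, 49), rep(5, 121))
  p <- to_profile(validate_series(s))
  expect_identical(as.integer(p[["5"]]), 121L)

  merged <- duration_profile(c(`1` = 5, `1` = 7, `0` = 0))
  expect_identical(as.integer(merged), 12L)  # zero entries dropped, dups summed
  expect_error(duration_profile(c(3, 4)), "named")
  expect_error(duration_profile(c(`2` = -1)), "non-negative")
})

test_that("profiles are permutation-invariant for kill-free series", {
  set.seed(42)
  for (i in 1:20) {
    s <- sample(c(-4:4), 40, replace = TRUE)
    expect_identical(to_profile(s), to_profile(sample(s)))
  }
})

test_that("series validation enforces scale membership and killing absorption", {
  expect_error(validate_series(rep(6, 170)), "score 6")
  expect_error(validate_series(rep(0, 169)), "expected 170")
  bad <- c(rep(5, 10), rep(0, 160))
  expect_error(validate_series(bad), "not absorbing")
  repaired <- validate_series(bad, repair_kill = TRUE)
  expect_true(all(repaired == 5))
})

test_that("the original 0..7 scale translates onto the adapted scale", {
  # Fighting -> 4, Allogrooming and trophallaxis -> -3, Ignoring -> 0
  expect_identical(translate_scale(c(7, 3, 0), ds3_scale()), c(4L, -3L, 0L))
  expect_identical(translate_scale(0:7, ds3_scale()),
                   c(0L, -1L, -2L, -3L, 1L, 2L, 3L, 4L))
  expect_error(translate_scale(8, ds3_scale()), "not in translation domain")
  # translation preserves length on a full series
  s <- sample(0:7, 170, replace = TRUE)
  expect_length(translate_scale(s, ds3_scale()), 170)
})

test_that("ethogram CSV round-trips and rejects malformed files", {
  df <- make_ethogram_df(t_obs = 20)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)

  groups <- read_ethogram(f, t_obs = 20)
  expect_length(groups, 1)
  expect_s3_class(groups[[1]], "pairing_group")
  expect_length(groups[[1]]$encounters, 2)
  expect_length(groups[[1]]$encounters[[1]]$series, 2)

  # write o read is the identity modulo row order
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ethogram(groups, f2)
  back <- utils::read.csv(f2, stringsAsFactors = FALSE)
  key <- function(d) do.call(order, d[c("encounter_id", "worker", "second")])
  expect_equal(back[key(back), c("worker", "second", "score")],
               df[key(df), c("worker", "second", "score")],
               ignore_attr = TRUE)
  expect_equal(nrow(back), 2 * 2 * 20)

  # out-of-scale score names the offending row
  bad <- df
  bad$score[7] <- 6
  utils::write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(read_ethogram(f, t_obs = 20), "row 8.*score 6")

  # duplicated second
  bad <- df
  bad$second[2] <- 1
  utils::write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(read_ethogram(f, t_obs = 20), "duplicate second")

  # missing second
  utils::write.csv(df[-3, ], f, row.names = FALSE, quote = FALSE)
  expect_error(read_ethogram(f, t_obs = 20), "missing second 3")

  # non-absorbing killing rejected unless repaired
  bad <- df
  bad$score[bad$worker == "wB" & bad$encounter_id == "e2" & bad$second == 4] <- 5
  utils::write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(read_ethogram(f, t_obs = 20), "not absorbing")
  expect_silent(read_ethogram(f, t_obs = 20, repair_kill = TRUE))
})

test_that("typographic minus signs are normalised on input", {
  df <- make_ethogram_df(t_obs = 20)
  df$score <- sub("^-", "−", as.character(df$score))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  groups <- read_ethogram(f, t_obs = 20)
  expect_identical(groups[[1]]$encounters[[1]]$series$wB, rep(-3L, 20))
})

test_that("empty group list writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_ethogram(list(), f)
  expect_equal(nrow(utils::read.csv(f)), 0)
  expect_identical(names(utils::read.csv(f)),
                   c("pairing_id", "encounter_id", "replicate",
                     "encounter_type", "day", "worker", "second", "score"))
})

test_that("profile CSV round-trips", {
  sim <- simulate_dataset("P+I+A", n_averaged = 2, replicates_per_averaged = 3,
                          seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(sim, f)
  back <- read_profiles(f)
  expect_length(back, 2)
  p0 <- sim[[1]]$encounters[[2]]$profiles$w1
  p1 <- back[[1]]$encounters[[2]]$profiles$w1
  expect_identical(p0, p1)
})

test_that("scale config files round-trip through YAML and JSON", {
  sc <- ds3_scale()
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(scores = sc$entries$score, labels = sc$entries$label,
                        translation = as.list(sc$translation)), fy)
  got <- read_scale(fy)
  expect_identical(got$entries, sc$entries)
  expect_identical(got$translation, sc$translation)

  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(scores = sc$entries$score,
                            labels = sc$entries$label,
                            translation = as.list(sc$translation)),
                       fj, auto_unbox = TRUE)
  got <- read_scale(fj)
  expect_identical(got$entries, sc$entries)
})

test_that("encounters require 1 or 2 workers and consistent pairings", {
  p <- duration_profile(c(`1` = 170))
  expect_error(encounter("e", "p", profiles = list(p, p, p)), "1 or 2 workers")
  e1 <- make_enc(c(`1` = 170), pairing = "a")
  e2 <- make_enc(c(`-1` = 170), pairing = "b")
  expect_error(pairing_group(list(e1, e2)), "mix pairing ids")
  e3 <- encounter("e3", "a", encounter_type = "intranest",
                  profiles = list(p), t_obs = 170)
  expect_error(pairing_group(list(e1, e3)), "mix encounter types")
  expect_error(encounter("e", "p", profiles = list(duration_profile(c(`1` = 3))),
                         t_obs = 170), "totals 3")
})
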