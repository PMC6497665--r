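p_mixed <- duration_profile(c(`-2` = 100, `0` = 60, `3` = 10))

test_that("AI is the duration-weighted mean over interaction seconds", {
  # (-2*100 + 3*10) / (100 + 10); ignoring excluded from both sums
  expect_equal(ai(p_mixed), -170 / 110)
  expect_equal(ai(duration_profile(c(`1` = 170))), 1)
  # killing seconds enter numerator and denominator
  expect_equal(ai(duration_profile(c(`5` = 170))), 5)
  # an all-ignoring encounter has no defined AI: a missing marker, not 0
  expect_identical(ai(duration_profile(c(`0` = 170))), NA_real_)
})

test_that("mmai / mmpi are the extreme scores present for >= 1 s", {
  expect_equal(mmai(duration_profile(c(`-4` = 170))), -4)
  expect_equal(mmai(p_mixed), 3)
  expect_equal(mmpi(p_mixed), -2)
  expect_equal(mmpi(duration_profile(c(`1` = 170))), 1)
  # also computable straight from a series
  expect_equal(mmai(c(rep(-2, 5), rep(1, 3))), 1)
})

test_that("duration summary partitions the encounter seconds", {
  d <- duration_summary(p_mixed)
  expect_equal(d[c("d_pcf", "d_ignore", "d_agg")],
               list(d_pcf = 100, d_ignore = 60, d_agg = 10))
  expect_false(d$killed)
  d <- duration_summary(duration_profile(c(`5` = 170)))
  expect_equal(d$d_agg, 170)
  expect_true(d$killed)
  d <- duration_summary(duration_profile(c(`0` = 170)))
  expect_equal(unlist(d[1:3]), c(d_agg = 0, d_pcf = 0, d_ignore = 170))
})

test_that("the MBI cascade follows the hand-traced branches", {
  expect_equal(mbi(p_mixed, 15), -2)    # peace dominated (d_agg = 10 <= 15)
  expect_equal(mbi(p_mixed, 5), 0.5)    # both exceed t: (3 + -2)/2
  expect_equal(mbi(p_mixed, 120), 0)    # ignoring dominated
  # killing short-circuits every threshold
  killed <- duration_profile(c(`-3` = 100, `5` = 70))
  for (t in c(0, 50, 170)) expect_equal(mbi(killed, t), 5)
  expect_error(mbi(p_mixed, 171), "t must be in")
  expect_error(mbi(p_mixed, -1), "t must be in")
})

test_that("mbi at the boundary thresholds behaves as the strict comparisons imply", {
  set.seed(7)
  for (i in 1:50) {
    s <- sample(-4:4, 170, replace = TRUE)
    p <- to_profile(s)
    # t = 0: any nonzero-score second forces a branch other than the
    # ignoring-dominated one (the midrange branch may still return 0)
    d <- duration_summary(p)
    expected0 <- if (d$d_agg > 0 && d$d_pcf == 0) mmai(p)
                 else if (d$d_pcf > 0 && d$d_agg == 0) mmpi(p)
                 else (mmai(p) + mmpi(p)) / 2
    if (any(s != 0)) expect_equal(mbi(p, 0), expected0)
    # t = T_obs: kill-free encounters are neutral
    expect_equal(mbi(p, 170), 0)
  }
})

test_that("score negation mirrors the indices for kill-free profiles", {
  set.seed(11)
  for (i in 1:50) {
    s <- sample(-4:4, 60, replace = TRUE)
    p <- to_profile(s)
    q <- to_profile(-s)
    expect_equal(mmai(q), -mmpi(p))
    expect_equal(mmpi(q), -mmai(p))
    expect_equal(ai(q), -ai(p))
    t <- sample(0:60, 1)
    expect_equal(mbi(q, t), -mbi(p, t))
  }
})

test_that("mmpi <= ai <= mmai holds on nonzero support", {
  set.seed(13)
  for (i in 1:50) {
    s <- sample(c(-4:-1, 1:4), 60, replace = TRUE)  # no ignoring
    p <- to_profile(s)
    expect_lte(mmpi(p), ai(p))
    expect_lte(ai(p), mmai(p))
  }
  # with ignoring present AI still sits below mmai and above mmpi
  for (i in 1:20) {
    s <- c(sample(c(-4:4), 50, replace = TRUE), 1)  # ensure nonzero support
    p <- to_profile(s)
    expect_lte(mmpi(p), min(ai(p), mmai(p)))
    expect_lte(ai(p), mmai(p))
  }
})

test_that("the cascade matches a literal flowchart transcription exhaustively", {
  # all profiles over scores {-1, 0, 1} with total 1..12 s, every valid t
  for (total in 1:12) {
    for (d_neg in 0:total) {
      for (d_zero in 0:(total - d_neg)) {
        d_pos <- total - d_neg - d_zero
        durs <- c(`-1` = d_neg, `0` = d_zero, `1` = d_pos)
        p <- duration_profile(durs)
        for (t in 0:total) {
          expect_identical(mbi(p, t), oracle_mbi(durs, t))
        }
      }
    }
  }
})

test_that("encounter vectors average workers with equal weight", {
  pA <- duration_profile(c(`3` = 100, `0` = 70))
  pB <- duration_profile(c(`1` = 100, `0` = 70))
  e2 <- encounter("e", "p", profiles = list(wA = pA, wB = pB), t_obs = 170)
  v <- index_vector(e2, t_agg = 10, t_pcf = 10)
  expect_equal(unname(v["mmai"]), 2)  # workers with MMAI 3 and 1
  expect_equal(unname(v["ai"]), (3 + 1) / 2)

  # two identical workers equal the single-worker vector
  e1 <- encounter("e", "p", profiles = list(wA = pA), t_obs = 170)
  e2 <- encounter("e", "p", profiles = list(wA = pA, wB = pA), t_obs = 170)
  expect_equal(index_vector(e1, 10, 10), index_vector(e2, 10, 10))

  # AI missing for one worker: the other worker's AI stands
  pI <- duration_profile(c(`0` = 170))
  e <- encounter("e", "p", profiles = list(wA = pA, wB = pI), t_obs = 170)
  expect_equal(unname(index_vector(e, 10, 10)["ai"]), 3)
  # AI missing for all workers: NA
  e <- encounter("e", "p", profiles = list(wA = pI), t_obs = 170)
  expect_true(is.na(index_vector(e, 10, 10)["ai"]))
})

test_that("pairing means average encounter vectors over replicates", {
  profs <- list(c(`5` = 170), c(`5` = 170), c(`5` = 170), c(`5` = 170))
  encs <- lapply(seq_along(profs), function(i)
    make_enc(profs[[i]], id = paste0("e", i), replicate = i, t_obs = 170))
  pm <- pairing_means(pairing_group(encs), 10, 10)
  expect_equal(pm$mmai, 5)

  # MMAI replicates {4,3,2,1} -> 2.5; one replicate -> identity
  profs <- list(c(`4` = 170), c(`3` = 170), c(`2` = 170), c(`1` = 170))
  encs <- lapply(seq_along(profs), function(i)
    make_enc(profs[[i]], id = paste0("e", i), replicate = i, t_obs = 170))
  pm <- pairing_means(pairing_group(encs), 10, 10)
  expect_equal(pm$mmai, 2.5)
  expect_equal(pm$n_replicates, 4)
  pm1 <- pairing_means(pairing_group(encs[2]), 10, 10)
  expect_equal(pm1$mmai, 3)
})

test_that("near-tie fraction counts strict sub-delta duration differences", {
  e_tied <- make_enc(c(`2` = 50, `-2` = 45, `0` = 75), id = "t1")
  e_clear <- make_enc(c(`2` = 60, `-2` = 45, `0` = 65), id = "t2")
  expect_equal(near_tie_fraction(list(e_tied)), 1)      # |50-45| = 5 < 10
  expect_equal(near_tie_fraction(list(e_clear)), 0)     # 15 >= 10
  expect_equal(near_tie_fraction(list(e_tied, e_clear)), 0.5)
  # boundary: exactly delta is not a near-tie
  e_edge <- make_enc(c(`1` = 30, `-1` = 20, `0` = 120), id = "t3")
  expect_equal(near_tie_fraction(list(e_edge), delta = 10), 0)
})
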