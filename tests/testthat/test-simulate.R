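test_that("block covariance with no blocks and no effects is the identity", {
  spec <- block_spec(1:5, r_within = 0, r_between = 0)
  R <- build_group_covariance(spec, list(), "HC")
  expect_equal(unclass(R), diag(5), ignore_attr = TRUE)
  expect_equal(attr(R, "repair_distance"), 0)
})

test_that("planted effects modify exactly the requested entry per group", {
  spec <- block_spec(1:6, r_within = 0, r_between = 0)
  eff <- list(planted_effect("AD", 2, 5, 0.38),
              planted_effect("EMCI", 2, 5, 0.13))
  R_ad <- build_group_covariance(spec, eff, "AD")
  R_emci <- build_group_covariance(spec, eff, "EMCI")
  expect_equal(R_ad[2, 5], 0.38)
  expect_equal(R_ad[5, 2], 0.38)
  expect_equal(R_emci[2, 5], 0.13)
  diff <- abs(unclass(R_ad) - unclass(R_emci))
  expect_equal(which(diff > 1e-12), c(11L, 26L))  # (5,2) and (2,5) only
  expect_error(planted_effect("AD", 1, 2, 1.2), "target_r")
})

test_that("indefinite requests are repaired to PSD with unit diagonal", {
  spec <- block_spec(1:3, r_within = 0, r_between = 0)
  eff <- list(planted_effect("G", 1, 2, 0.9), planted_effect("G", 2, 3, 0.9),
              planted_effect("G", 1, 3, -0.9))
  R <- build_group_covariance(spec, eff, "G")
  ev <- eigen(unclass(R), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(unclass(R)), rep(1, 3), ignore_attr = TRUE)
  expect_gt(attr(R, "repair_distance"), 0)
})

test_that("subject simulation is a pure function of its seed", {
  cfg <- generator_config(n_per_group = c(A = 2L), n_rois = 4L, seed = 5L)
  R <- diag(4)
  a <- simulate_subject(R, cfg, 123L)
  b <- simulate_subject(R, cfg, 123L)
  c <- simulate_subject(R, cfg, 124L)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("generated series are band-limited: >95% power inside the passband", {
  cfg <- generator_config(n_per_group = c(A = 1L), n_rois = 4L, seed = 2L)
  ts <- simulate_subject(diag(4), cfg, 11L)
  T_ <- nrow(ts); tr <- attr(ts, "tr")
  f <- (0:(T_ - 1)) / (T_ * tr)
  for (j in 1:4) {
    pw <- Mod(fft(ts[, j]))^2
    pos <- 2:floor(T_ / 2)
    inband <- f[pos] >= cfg$passband_hz[1] & f[pos] <= cfg$passband_hz[2]
    expect_gt(sum(pw[pos][inband]) / sum(pw[pos]), 0.95)
  }
})

test_that("generator columns have unit variance and near-zero mean", {
  cfg <- generator_config(n_per_group = c(A = 1L), n_rois = 3L, seed = 3L)
  ts <- simulate_subject(diag(3), cfg, 77L)
  expect_equal(apply(ts, 2, sd), rep(1, 3), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(ts))), 1e-10)
})

test_that("a planted correlation is recovered in the sample mean", {
  spec <- block_spec(1:4, 0, 0)
  eff <- list(planted_effect("A", 1, 2, 0.6))
  R <- build_group_covariance(spec, eff, "A")
  cfg <- generator_config(n_per_group = c(A = 1L), n_rois = 4L, seed = 4L)
  rs <- vapply(1:200, function(s)
    cor(simulate_subject(R, cfg, 1000L + s)[, 1:2])[1, 2], numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.1)
  # identity covariance: mean off-diagonal r consistent with 0
  rs0 <- vapply(1:200, function(s) {
    m <- cor(unclass(simulate_subject(diag(4), cfg, 5000L + s)))
    mean(m[upper.tri(m)])
  }, numeric(1))
  expect_lt(abs(mean(rs0)), 3 * sd(rs0) / sqrt(200))
})

test_that("cohort generation is deterministic and honours group sizes", {
  cfg <- generator_config(n_per_group = c(HC = 3L, AD = 2L), n_rois = 5L,
                          seed = 9L)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_equal(length(coh1$series), 5L)
  expect_equal(as.vector(table(coh1$manifest$group)), c(3L, 2L))
  expect_identical(lapply(coh1$series, unclass), lapply(coh2$series, unclass))
  cfg3 <- generator_config(n_per_group = c(HC = 3L, AD = 2L), n_rois = 5L,
                           seed = 10L)
  coh3 <- simulate_cohort(cfg3)
  expect_false(identical(unclass(coh1$series[[1]]), unclass(coh3$series[[1]])))
})

test_that("the default four-group sizes give the full 128-subject cohort", {
  cfg <- generator_config()
  expect_equal(sum(cfg$n_per_group), 128L)
  expect_equal(names(cfg$n_per_group), c("HC", "EMCI", "LMCI", "AD"))
})

test_that("passbands incompatible with the sampling rate are rejected", {
  expect_error(generator_config(passband_hz = c(0.01, 0.2)), "Nyquist")
  cfg <- generator_config(n_per_group = c(A = 1L), n_rois = 2L,
                          n_timepoints = 10L, passband_hz = c(0.14, 0.15))
  expect_error(simulate_subject(diag(2), cfg, 1L), "passband")
})

test_that("written cohorts read back identically", {
  cfg <- generator_config(n_per_group = c(HC = 2L, AD = 2L), n_rois = 4L,
                          n_timepoints = 30L, seed = 21L)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  mpath <- write_cohort(coh, dir)
  man <- read_manifest(mpath)
  back <- read_cohort(man, tr = 3, base_dir = dir)
  expect_equal(unclass(back$series[["HC_001"]]),
               unclass(coh$series[["HC_001"]]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("exact and Rice crossing predictions sit near the empirical BOLD rate", {
  cfg <- generator_config()
  exact <- expected_upcrossings(cfg)
  rice <- expected_upcrossings(cfg, method = "rice")
  # both within the empirically reported one-SD band (8.5 +/- 2.8 per 420 s)
  expect_gt(exact, 8.5 - 2.8); expect_lt(exact, 8.5 + 2.8)
  expect_gt(rice, 8.5 - 2.8); expect_lt(rice, 8.5 + 2.8)
  # the exact prediction accounts for standardization; they stay close
  expect_lt(abs(exact - rice), 0.5)
})
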