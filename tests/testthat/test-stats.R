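test_that("one-way ANOVA reproduces the hand decomposition", {
  a <- one_way_anova(list(A = c(1, 2), B = c(3, 4)))
  expect_equal(a$F, 8)
  expect_equal(c(a$df_between, a$df_within), c(1L, 2L))
  expect_equal(a$p, pf(8, 1, 2, lower.tail = FALSE))  # ~0.106
  same <- one_way_anova(list(A = c(1, 3), B = c(2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  degen <- one_way_anova(list(A = c(1, 1), B = c(2, 2)))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_error(one_way_anova(list(A = 1:3)), "2 groups")
  expect_error(one_way_anova(list(A = 1, B = 1:2)), "2 values")
})

test_that("ANOVA is invariant to permuting values within groups", {
  set.seed(22)
  g <- list(A = rnorm(5), B = rnorm(4), C = rnorm(6))
  ref <- one_way_anova(g)
  perm <- lapply(g, sample)
  out <- one_way_anova(perm)
  expect_equal(out$F, ref$F)
  expect_equal(out$p, ref$p)
})

test_that("ANOVA agrees with the aov reference on random datasets", {
  set.seed(23)
  for (rep in 1:1000) {
    G <- sample(2:4, 1)
    n_g <- sample(3:7, G, replace = TRUE)
    vals <- lapply(n_g, function(n) rnorm(n, mean = runif(1, -1, 1)))
    names(vals) <- paste0("G", seq_len(G))
    ours <- one_way_anova(vals)
    df <- data.frame(y = unlist(vals),
                     g = factor(rep(names(vals), n_g)))
    ref <- summary(stats::aov(y ~ g, df))[[1]]
    expect_equal(ours$F, ref[1, "F value"], tolerance = 1e-9)
    expect_equal(ours$p, ref[1, "Pr(>F)"], tolerance = 1e-9)
  }
})

test_that("post-hoc comparisons match pairwise.t.test with pooled SD", {
  set.seed(24)
  for (rep in 1:25) {
    G <- sample(3:4, 1)
    n_g <- sample(4:8, G, replace = TRUE)
    vals <- lapply(n_g, function(n) rnorm(n, mean = runif(1, -1, 1)))
    names(vals) <- paste0("G", seq_len(G))
    cmp <- posthoc_pairwise(vals)
    df <- data.frame(y = unlist(vals), g = factor(rep(names(vals), n_g)))
    ref <- stats::pairwise.t.test(df$y, df$g, p.adjust.method = "bonferroni",
                                  pool.sd = TRUE)
    for (k in seq_len(nrow(cmp))) {
      ref_p <- ref$p.value[cmp$group_b[k], cmp$group_a[k]]
      expect_equal(cmp$p_adjusted[k], ref_p, tolerance = 1e-9)
    }
    expect_equal(nrow(cmp), G * (G - 1) / 2)
    expect_true(all(cmp$p_adjusted >= cmp$p_raw))
  }
})

test_that("Bonferroni adjustment multiplies and clamps", {
  vals <- list(A = c(0, 0.1), B = c(5, 5.1), C = c(0.05, 0.12), D = c(2, 2.2))
  cmp <- posthoc_pairwise(vals)
  expect_equal(nrow(cmp), 6L)
  expect_equal(cmp$p_adjusted, pmin(1, cmp$p_raw * 6))
  expect_true(any(cmp$p_adjusted == 1))
})

test_that("the edge-wise screen recovers a planted group difference", {
  spec <- block_spec(rep(1:2, each = 4), 0.3, 0.1)
  eff <- list(planted_effect("EMCI", "ROI002", "ROI006", 0.13),
              planted_effect("AD", "ROI002", "ROI006", 0.7))
  cfg <- generator_config(n_per_group = c(EMCI = 15L, AD = 15L), n_rois = 8L,
                          seed = 25L)
  coh <- simulate_cohort(cfg, spec, eff)
  mats <- lapply(coh$series, pearson_fc)
  fit <- edgewise_anova(mats, coh$manifest$group)
  top <- fit$table[1, ]
  expect_equal(c(top$roi_i, top$roi_j), c("ROI002", "ROI006"))
  ph <- fit$posthoc
  row <- ph[ph$roi_i == "ROI002" & ph$roi_j == "ROI006", ]
  expect_equal(nrow(row), 1L)
  expect_lt(row$p_adjusted, 0.05)
  expect_lt(row$direction, 0)  # EMCI mean below AD mean
})

test_that("duplicated identical groups yield no corrected significance", {
  set.seed(26)
  mats <- lapply(1:6, function(i) rand_fc(5, 30, seed = 400 + (i - 1) %% 3))
  fit <- edgewise_anova(mats, rep(c("A", "B"), each = 3),
                        mad_rescreen = FALSE)
  expect_false(any(fit$posthoc$p_adjusted < 0.05))
  expect_true(all(fit$table$F < 1e-6))
})

test_that("family scope moves the Bonferroni factor between families", {
  set.seed(27)
  mats <- lapply(1:12, function(i) rand_fc(6, 20, seed = 500 + i))
  g <- rep(c("A", "B", "C"), each = 4)
  f_ph <- edgewise_anova(mats, g, family_scope = "posthoc_only",
                         mad_rescreen = FALSE)
  f_ed <- edgewise_anova(mats, g, family_scope = "edges_bonferroni",
                         mad_rescreen = FALSE)
  f_no <- edgewise_anova(mats, g, family_scope = "none",
                         mad_rescreen = FALSE)
  # edge-family correction can only shrink the screened set
  expect_lte(sum(f_ed$table$screened), sum(f_ph$table$screened))
  expect_equal(sum(f_no$table$screened), sum(f_ph$table$screened))
  expect_equal(f_ed$table$p_edges_adjusted,
               pmin(1, f_ed$table$p * f_ed$n_edges))
  # post-hoc p-values are raw under scope "none"
  if (nrow(f_no$posthoc)) expect_equal(f_no$posthoc$p_adjusted,
                                       f_no$posthoc$p_raw)
  expect_error(edgewise_anova(mats[1:2], c("A", "B")), "at least 2")
})

test_that("mixed metric kinds are rejected", {
  fc <- rand_fc(4, 30, seed = 28)
  sdm <- fc_variability(windowed_fc(rand_ts(30, 4, seed = 28), 10))
  expect_error(edgewise_anova(list(fc, sdm, fc, sdm), c("A", "A", "B", "B")),
               "mixed metric kinds")
})

test_that("post-hoc significance is a subset of uncorrected significance", {
  set.seed(29)
  mats <- lapply(1:16, function(i) {
    base <- rand_ts(40, 5, seed = 600 + i)
    pearson_fc(base)
  })
  g <- rep(c("A", "B", "C", "D"), each = 4)
  fit <- edgewise_anova(mats, g, alpha = 1, family_scope = "posthoc_only",
                        mad_rescreen = FALSE)
  ph <- fit$posthoc
  expect_true(all(ph$p_raw[ph$p_adjusted < 0.05] < 0.05))
})

test_that("scalar tables flag planted shifts with the right direction", {
  set.seed(30)
  df <- data.frame(
    measure = rep(c("m1", "m2"), each = 30),
    value = c(rnorm(30), c(rnorm(10), rnorm(10) + 3, rnorm(10))),
    group = factor(rep(rep(c("HC", "EMCI", "AD"), each = 10), 2),
                   levels = c("HC", "EMCI", "AD")))
  tab <- scalar_anova_table(df)
  expect_equal(nrow(tab), 2L)
  m2 <- tab[tab$measure == "m2", ]
  expect_lt(m2$p, 0.001)
  expect_match(m2$significant_pairs, "HC<EMCI")
  expect_match(m2$significant_pairs, "EMCI>AD")
  m1 <- tab[tab$measure == "m1", ]
  expect_equal(m1$significant_pairs, "")
})

test_that("MAD rescreen reports post-removal statistics on screened edges", {
  spec <- block_spec(1:5, 0, 0)
  eff <- list(planted_effect("B", 1, 2, 0.8))
  cfg <- generator_config(n_per_group = c(A = 10L, B = 10L), n_rois = 5L,
                          seed = 31L)
  coh <- simulate_cohort(cfg, spec, eff)
  mats <- lapply(coh$series, pearson_fc)
  fit <- edgewise_anova(mats, coh$manifest$group, mad_rescreen = TRUE)
  scr <- fit$table[fit$table$screened, ]
  expect_true(all(!is.na(scr$p_clean)))
  expect_true(all(is.na(fit$table$p_clean[!fit$table$screened])))
})
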