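# exact published instrument sets (SEs back-derived from beta and p)
pub <- published_instruments()

test_that("Wald ratios follow the first-order construction", {
  wr <- wald_ratios(pub$TP)
  i <- match("chr06_1578700", wr$SNP)
  expect_equal(wr$ratio[i], (-1.691) / (-0.639), tolerance = 1e-12)
  expect_equal(wr$ratio[i], 2.646, tolerance = 1e-3)
  expect_equal(wr$weight, pub$TP$instruments$BETA_X^2 /
                 pub$TP$instruments$SE_Y^2, tolerance = 1e-12)

  s0 <- make_instruments(bx = c(2, 1, 4), sex = rep(0.1, 3),
                         px = rep(1e-8, 3), by = c(0, 1, 2),
                         sey = c(0.5, 0.5, 0.5), py = c(0.9, 0.1, 0.1))
  wr0 <- wald_ratios(s0)
  expect_equal(wr0$ratio[1], 0)
  expect_true(is.finite(wr0$se_ratio[1]))

  # homogeneity: scaling (beta_x, se_x) by c scales ratio by 1/c, weight by c^2
  s1 <- s0
  s1$instruments$BETA_X <- s0$instruments$BETA_X * 3
  s1$instruments$SE_X <- s0$instruments$SE_X * 3
  wr1 <- wald_ratios(s1)
  expect_equal(wr1$ratio, wr0$ratio / 3)
  expect_equal(wr1$weight, wr0$weight * 9)

  s_bad <- s0
  s_bad$instruments$BETA_X[2] <- 0
  expect_error(wald_ratios(s_bad), s_bad$instruments$SNP[2])
})

test_that("IVW with one instrument is its Wald ratio and stays in range", {
  one <- instrument_set("TP", "YD", pub$TP$instruments[2, ])
  r <- mr_ivw(one)
  wr <- wald_ratios(one)
  expect_equal(r$estimate, wr$ratio)
  expect_equal(r$se, wr$se_ratio)
  expect_equal(r$scale_factor, 1)

  for (s in pub) {
    wr <- wald_ratios(s)
    est <- mr_ivw(s)$estimate
    expect_gte(est, min(wr$ratio))
    expect_lte(est, max(wr$ratio))
  }
})

test_that("IVW matches the brute-force weighted-ratio oracle", {
  for (s in pub) {
    tab <- s$instruments
    est_oracle <- sum(tab$BETA_X * tab$BETA_Y / tab$SE_Y^2) /
      sum(tab$BETA_X^2 / tab$SE_Y^2)
    expect_equal(mr_ivw(s)$estimate, est_oracle, tolerance = 1e-12)
  }
})

test_that("estimators are sign-equivariant in the outcome", {
  for (s in pub) {
    s_neg <- s
    s_neg$instruments$BETA_Y <- -s$instruments$BETA_Y
    expect_equal(mr_ivw(s_neg)$estimate, -mr_ivw(s)$estimate)
    expect_equal(mr_weighted_median(s_neg, 200, 1)$estimate,
                 -mr_weighted_median(s, 200, 1)$estimate)
    expect_equal(mr_egger(s_neg)$estimate, -mr_egger(s)$estimate,
                 tolerance = 1e-12)
  }
})

test_that("rescaling exposure units rescales estimates, not p-values", {
  c0 <- 2.5
  for (s in pub) {
    s2 <- s
    s2$instruments$BETA_X <- s$instruments$BETA_X * c0
    s2$instruments$SE_X <- s$instruments$SE_X * c0
    r1 <- mr_ivw(s); r2 <- mr_ivw(s2)
    expect_equal(r2$estimate, r1$estimate / c0, tolerance = 1e-12)
    expect_equal(r2$p, r1$p, tolerance = 1e-12)
    e1 <- mr_egger(s); e2 <- mr_egger(s2)
    expect_equal(e2$estimate, e1$estimate / c0, tolerance = 1e-9)
    expect_equal(e2$intercept, e1$intercept, tolerance = 1e-9)
  }
})

test_that("confidence intervals are estimate +/- 1.959964 se", {
  for (s in pub) {
    r <- mr_ivw(s)
    expect_lt(abs(r$ci_low - (r$estimate - 1.959964 * r$se)), 1e-9)
    expect_lt(abs(r$ci_high - (r$estimate + 1.959964 * r$se)), 1e-9)
  }
})

test_that("weighted median interpolates the cumulative-weight grid", {
  # equal ratios: estimate equals the common ratio
  s <- make_instruments(bx = c(1, 2, 4), sex = rep(0.1, 3),
                        px = rep(1e-8, 3), by = c(0.5, 1, 2),
                        sey = c(0.2, 0.3, 0.4), py = rep(0.01, 3))
  r <- mr_weighted_median(s, n_boot = 500, seed = 3)
  expect_equal(r$estimate, 0.5)
  # bootstrap SE is on the per-ratio scale
  expect_gt(r$se, 0.01)
  expect_lt(r$se, 1)
  expect_error(mr_weighted_median(instrument_set("GPP", "YD",
                                                 s$instruments[1:2, ])),
               "k >= 3")

  # hand-evaluated 3-instrument interpolation oracle
  wr <- wald_ratios(pub$TP)
  o <- order(wr$ratio)
  w <- wr$weight[o] / sum(wr$weight)
  cum <- cumsum(w) - w / 2
  j <- max(which(cum < 0.5))
  hand <- wr$ratio[o][j] + (wr$ratio[o][j + 1] - wr$ratio[o][j]) *
    (0.5 - cum[j]) / (cum[j + 1] - cum[j])
  expect_equal(mr_weighted_median(pub$TP, 100, 1)$estimate, hand,
               tolerance = 1e-12)
})

test_that("weighted median bootstrap SE is seed-reproducible", {
  r1 <- mr_weighted_median(pub$GPP, 1000, seed = 7)
  r2 <- mr_weighted_median(pub$GPP, 1000, seed = 7)
  expect_identical(r1$se, r2$se)
})

test_that("MR-Egger recovers an exact proportional relationship", {
  bx <- c(1, 2, 3, 5)
  s <- make_instruments(bx = bx, sex = rep(0.1, 4), px = rep(1e-8, 4),
                        by = 1.7 * bx, sey = rep(0.3, 4), py = rep(0.01, 4))
  e <- mr_egger(s)
  expect_equal(e$estimate, 1.7, tolerance = 1e-9)
  expect_equal(e$intercept, 0, tolerance = 1e-9)
  expect_error(mr_egger(instrument_set("GPP", "YD", s$instruments[1:2, ])),
               "k >= 3")
  s_sing <- make_instruments(bx = c(2, -2, 2), sex = rep(0.1, 3),
                             px = rep(1e-8, 3), by = c(1, 1, 1),
                             sey = rep(0.3, 3), py = rep(0.01, 3))
  expect_error(mr_egger(s_sing), "singular")
})

test_that("MR-Egger equals a hand-rolled weighted regression after orientation", {
  s <- pub$GPP
  tab <- s$instruments
  fl <- sign(tab$BETA_X)
  bx <- tab$BETA_X * fl; by <- tab$BETA_Y * fl
  w <- 1 / tab$SE_Y^2
  # weighted normal equations
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  slope <- (sw * swxy - swx * swy) / (sw * swxx - swx^2)
  inter <- (swy - slope * swx) / sw
  e <- mr_egger(s)
  expect_equal(e$estimate, slope, tolerance = 1e-12)
  expect_equal(e$intercept, inter, tolerance = 1e-12)
})

test_that("heterogeneity over Wald ratios flags duplicates as homogeneous", {
  s <- make_instruments(bx = c(1, 1, 1), sex = rep(0.1, 3),
                        px = rep(1e-8, 3), by = c(2, 2, 2),
                        sey = rep(0.3, 3), py = rep(0.01, 3))
  h <- mr_heterogeneity(s)
  expect_equal(h$Q, 0)
  expect_equal(h$i2, 0)
})

test_that("sign split sends zero ratios to the positive subset", {
  s <- make_instruments(bx = c(1, -2, 3), sex = rep(0.1, 3),
                        px = rep(1e-8, 3), by = c(0, 1, 2),
                        sey = rep(0.3, 3), py = c(0.9, 0.1, 0.1))
  halves <- split_by_ratio_sign(s)
  expect_setequal(halves$positive$instruments$SNP,
                  s$instruments$SNP[c(1, 3)])
  expect_equal(halves$negative$instruments$SNP, s$instruments$SNP[2])

  all_pos <- make_instruments(bx = c(1, 2), sex = rep(0.1, 2),
                              px = rep(1e-8, 2), by = c(1, 2),
                              sey = rep(0.3, 2), py = rep(0.1, 2))
  expect_equal(n_instruments(split_by_ratio_sign(all_pos)$negative), 0L)
})

test_that("the published KGW set splits 7 positive / 4 negative", {
  halves <- split_by_ratio_sign(pub$KGW)
  expect_equal(n_instruments(halves$positive), 7L)
  expect_equal(n_instruments(halves$negative), 4L)
})

test_that("weighted median tolerates minority pleiotropy that biases IVW", {
  set.seed(17)
  truth <- 1.9
  # 12 equally weighted instruments, 2 of them (17% of total weight)
  # with strong directional pleiotropy
  cover_wm <- shift_larger <- logical(50)
  for (r in 1:50) {
    k <- 12; k_bad <- 2
    bx <- rep(1, k)
    sey <- rep(0.1, k)
    by <- truth * bx + rnorm(k, 0, sey)
    by[seq_len(k_bad)] <- by[seq_len(k_bad)] + 1.5
    s <- make_instruments(bx = bx, sex = rep(0.05, k),
                          px = rep(1e-8, k), by = by,
                          sey = sey, py = rep(1e-4, k))
    wm <- mr_weighted_median(s, 300, seed = r)
    iv <- mr_ivw(s)
    cover_wm[r] <- abs(wm$estimate - truth) <= 2 * wm$se
    shift_larger[r] <- abs(iv$estimate - truth) > abs(wm$estimate - truth)
  }
  expect_gte(mean(cover_wm), 0.9)
  expect_gt(mean(shift_larger), 0.5)
})
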