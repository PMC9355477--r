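# Centering, fitting, elimination, Type II tests, R2, VIF, median split,
# and the post-hoc contrasts, with emmeans/car as independent cross-checks.

recovery_sim_small <- function() {
  cached("mm_sim", {
    sim <- simulate_block_data(generator_config(), seed = 501,
                               n_participants = 80)
    list(sim = sim, data = centered_model_data(sim))
  })
}

test_that("centering subtracts grand means and is idempotent", {
  d <- data.frame(block = rep(1:28, 2), rs_score = rep(c(30, 50), each = 28),
                  snr_db = rep(c(4, 9), each = 28))
  c1 <- center_predictors(d)
  expect_equal(range(c1$block_c), c(-13.5, 13.5))
  expect_equal(mean(c1$block_c), 0)
  expect_equal(mean(c1$rs_c), 0)
  offs <- attr(c1, "centering")
  expect_equal(offs$center[offs$variable == "snr_db"], 6.5)
  c2 <- center_predictors(c1)
  expect_equal(c2$block_c, c1$block_c)
  expect_equal(c2$snr_c, c1$snr_c)
  dd <- d; dd$snr_db <- 5
  expect_warning(center_predictors(dd), "constant")
})

test_that("the maximal model recovers near-noiseless generating values", {
  cfg <- generator_config(tau0 = 0.05, tau_block = 0, sigma_eps = 1e-4)
  sim <- simulate_block_data(cfg, seed = 502, n_participants = 40)
  d <- centered_model_data(sim)
  fit <- fit_lmm(model_spec("pupil_baseline_mm",
                            fixed = c("block_c", "rs_c", "snr_c",
                                      "rs_c:snr_c"),
                            random = c("intercept", "block_c")), d)
  expect_equal(unname(fit$beta["(Intercept)"]), 3.48, tolerance = 1e-2)
  expect_equal(unname(fit$beta["block_c"]), -0.01, tolerance = 1e-3)
  expect_equal(unname(fit$beta["snr_c"]), -0.09, tolerance = 0.1)
  # a zero-variance random slope raises the singular flag
  expect_true(fit$singular)
  # Wald CI structure: estimate +/- 1.96 SE
  ct <- coef_table(fit)
  expect_equal(ct$ci_upper - ct$estimate, 1.96 * ct$se, tolerance = 1e-12)
})

test_that("backward elimination keeps true structure and prunes null terms", {
  d <- recovery_sim_small()$data
  be <- backward_eliminate(maximal_spec("pupil_baseline_mm"), d)
  expect_setequal(be$fit$spec$fixed,
                  c("block_c", "rs_c", "snr_c", "rs_c:snr_c"))
  expect_setequal(be$fit$spec$random, c("intercept", "block_c"))
  expect_true(all(c("random", "fixed") %in% be$trail$phase))
  # trail records the dropped random slopes
  dropped_random <- be$trail$term[be$trail$phase == "random" &
                                    be$trail$dropped]
  expect_setequal(dropped_random, c("rs_c", "snr_c"))

  # recall model: RS fixed effect with a Block random slope
  be2 <- backward_eliminate(maximal_spec("recall_pct"), d)
  expect_true("rs_c" %in% be2$fit$spec$fixed)
  expect_true("block_c" %in% be2$fit$spec$random)
})

test_that("elimination respects marginality during pruning", {
  d <- recovery_sim_small()$data
  be <- backward_eliminate(maximal_spec("pupil_baseline_mm"), d)
  # rs_c survives although its own p may be large: it is protected by the
  # retained rs_c:snr_c interaction
  expect_true("rs_c" %in% be$fit$spec$fixed)
  # no retained interaction is missing a constituent
  for (tm in be$fit$spec$fixed) {
    parts <- strsplit(tm, ":")[[1]]
    if (length(parts) > 1)
      expect_true(all(parts %in% be$fit$spec$fixed))
  }
})

test_that("a null generator keeps almost nothing", {
  cfg <- generator_config(betas = list(b0 = 3.48, b_block = 0, b_rs = 0,
                                       b_snr = 0, b_rs_snr = 0),
                          tau_block = 0)
  kept <- integer(0)
  for (seed in 1:8) {
    sim <- simulate_block_data(cfg, seed = 510 + seed, n_participants = 30)
    be <- backward_eliminate(maximal_spec("pupil_baseline_mm"),
                             centered_model_data(sim))
    kept <- c(kept, length(be$fit$spec$fixed))
  }
  # null fixed terms are retained at roughly the nominal rate (5% each,
  # with occasional cascades through protected constituents), so the
  # average number of surviving terms stays far below the seven candidates
  expect_lt(mean(kept), 1.5)
})

test_that("Type II Wald tests match the single-coefficient identity and car", {
  d <- recovery_sim_small()$data
  fit <- fit_lmm(model_spec("pupil_baseline_mm",
                            fixed = c("block_c", "rs_c", "snr_c",
                                      "rs_c:snr_c"),
                            random = c("intercept", "block_c")), d)
  an <- anova_type2(fit)
  ct <- coef_table(fit)
  # highest-order term: chi-square equals (beta/SE)^2 from the same fit
  expect_equal(an$chisq[an$term == "rs_c:snr_c"],
               ct$z[ct$term == "rs_c:snr_c"]^2, tolerance = 1e-9)
  expect_true(all(an$df == 1))

  skip_if_not_installed("car")
  ca <- car::Anova(fit$fit, type = "II", test.statistic = "Chisq")
  # car tests the same hypotheses from the full-fit covariance; estimates
  # agree closely on this near-orthogonal (centered) design
  expect_equal(an$chisq[match(rownames(ca), an$term)],
               unname(ca[["Chisq"]]), tolerance = 0.05)
})

test_that("Type II equals Type III on an orthogonal design", {
  # balanced two-level factors coded +/-1 are mutually orthogonal
  set.seed(520)
  g <- expand.grid(a = c(-1, 1), b = c(-1, 1), rep = 1:50,
                   participant = 1:4)
  g$y <- 0.5 * g$a - 0.3 * g$b + 0.2 * g$a * g$b + rnorm(nrow(g), 0, 1)
  g$block_c <- g$a; g$rs_c <- g$b
  g$pupil_baseline_mm <- g$y
  fit <- fit_lmm(model_spec("pupil_baseline_mm",
                            fixed = c("block_c", "rs_c", "block_c:rs_c"),
                            random = "intercept"), g)
  an2 <- anova_type2(fit)
  ct <- coef_table(fit)
  # with orthogonal columns the Type II chi-square of each term equals its
  # full-model Wald chi-square (the Type III statistic)
  for (tm in an2$term)
    expect_equal(an2$chisq[an2$term == tm], ct$z[ct$term == tm]^2,
                 tolerance = 1e-6)
})

test_that("R-squared formulas are exact on constructed components", {
  r2 <- r2_from_components(0.458, 0.488, 0.054)
  expect_equal(unname(r2["marginal"]), 0.458, tolerance = 1e-12)
  expect_equal(unname(r2["conditional"]), 0.946, tolerance = 1e-12)
  # no random-effect variance: conditional equals marginal
  r2n <- r2_from_components(0.3, 0, 0.7)
  expect_equal(unname(r2n["marginal"]), unname(r2n["conditional"]))
  # null model explains nothing
  expect_equal(unname(r2_from_components(0, 0.5, 0.5)["marginal"]), 0)
})

test_that("model R-squared components are coherent", {
  d <- recovery_sim_small()$data
  fit <- fit_lmm(model_spec("pupil_baseline_mm",
                            fixed = c("block_c", "rs_c", "snr_c",
                                      "rs_c:snr_c"),
                            random = c("intercept", "block_c")), d)
  r2 <- r2_nakagawa(fit)
  cmp <- attr(r2, "components")
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  expect_true(all(r2 >= 0 & r2 <= 1))
  # components recombine to the reported ratios
  expect_equal(unname(r2["marginal"]),
               cmp[["sigma2_f"]] / sum(cmp), tolerance = 1e-12)
  # the fixed-effect variance matches a direct evaluation of X beta
  X <- lme4::getME(fit$fit, "X")
  expect_equal(cmp[["sigma2_f"]], var(as.numeric(X %*% fit$beta)),
               tolerance = 1e-12)
})

test_that("VIFs behave at the extremes and stay low for centered draws", {
  set.seed(530)
  X <- cbind(x1 = rnorm(500), x2 = rnorm(500))
  v <- vif_fixed(cbind("(Intercept)" = 1, X))
  expect_true(all(abs(v - 1) < 0.05))
  Xd <- cbind(X, x3 = X[, "x1"])
  expect_true(is.infinite(vif_fixed(Xd)["x3"]))

  # centered RS, SNR and their product are nearly orthogonal
  n <- 10000
  rs <- rnorm(n, 41.72, 11.99); snr <- rnorm(n, 6.65, 3.08)
  rc <- rs - mean(rs); sc <- snr - mean(snr)
  v2 <- vif_fixed(cbind(rs_c = rc, snr_c = sc, int = rc * sc))
  expect_true(all(v2 < 1.3))
})

test_that("the median split puts ties and the median itself in the low group", {
  set.seed(540)
  rs21 <- sample(seq(25, 75, length.out = 21))
  g <- median_split(rs21)
  expect_equal(unname(table(g)["low"]), 11L)
  expect_equal(unname(table(g)["high"]), 10L)
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  tied <- median_split(c(1, 5, 5, 5, 9))
  expect_equal(as.character(tied), c("low", "low", "low", "low", "high"))
  expect_warning(median_split(c(2, 2, 2)), "all scores equal")
})

test_that("simple slopes are the exact linear contrast of the estimates", {
  d <- recovery_sim_small()$data
  fit <- fit_lmm(model_spec("pupil_baseline_mm",
                            fixed = c("block_c", "rs_c", "snr_c",
                                      "rs_c:snr_c"),
                            random = c("intercept", "block_c")), d)
  ss <- simple_slopes(fit)
  b <- fit$beta
  for (g in c("low", "high")) {
    row <- ss$slopes[ss$slopes$group == g, ]
    expect_equal(row$slope,
                 unname(b["snr_c"] + b["rs_c:snr_c"] * row$m_rs_c),
                 tolerance = 1e-12)
  }
  mh <- ss$slopes$m_rs_c[ss$slopes$group == "high"]
  ml <- ss$slopes$m_rs_c[ss$slopes$group == "low"]
  expect_equal(ss$difference$estimate,
               unname(b["rs_c:snr_c"]) * (mh - ml), tolerance = 1e-12)

  skip_if_not_installed("emmeans")
  emm <- emmeans::emtrends(fit$fit, ~ rs_c, var = "snr_c",
                           at = list(rs_c = c(ml, mh)),
                           lmer.df = "asymptotic")
  es <- as.data.frame(emm)
  expect_equal(ss$slopes$slope, es$snr_c.trend, tolerance = 1e-9)
  expect_equal(ss$slopes$se, es$SE, tolerance = 1e-9)
})

test_that("grid contrasts are collinear in SNR and match emmeans", {
  d <- recovery_sim_small()$data
  fit <- fit_lmm(model_spec("pupil_baseline_mm",
                            fixed = c("block_c", "rs_c", "snr_c",
                                      "rs_c:snr_c"),
                            random = c("intercept", "block_c")), d)
  gr <- snr_grid_contrasts(fit)
  expect_equal(gr$snr_c, -5:7)
  # differences are an exact linear function of the grid value
  co <- coef(lm(difference ~ snr_c, gr))
  expect_lt(max(abs(gr$difference - (co[1] + co[2] * gr$snr_c))), 1e-12)

  # no interaction, no RS effect: nothing to detect
  fit0 <- fit_lmm(model_spec("pupil_baseline_mm",
                             fixed = c("block_c", "snr_c"),
                             random = c("intercept", "block_c")), d)
  gr0 <- snr_grid_contrasts(fit0)
  expect_true(all(gr0$difference == 0))

  skip_if_not_installed("emmeans")
  m <- pupilhab:::group_rs_means(fit)
  emm <- emmeans::emmeans(fit$fit, ~ rs_c | snr_c,
                          at = list(rs_c = unname(m), snr_c = c(-5, 0, 7)),
                          lmer.df = "asymptotic")
  cs <- as.data.frame(pairs(emm, reverse = TRUE))
  expect_equal(gr$difference[match(c(-5, 0, 7), gr$snr_c)],
               cs$estimate, tolerance = 1e-9)
  expect_equal(gr$se[match(c(-5, 0, 7), gr$snr_c)], cs$SE, tolerance = 1e-9)
})

test_that("the full workflow wrapper reproduces the component results", {
  simdat <- recovery_sim_small()$sim
  res <- analyze_blocks(simdat$blocks, simdat$participants,
                        outcome = "pupil_baseline_mm")
  expect_s3_class(res$fit, "swir_lmm")
  expect_true(!is.null(res$anova))
  expect_true(res$r2[["conditional"]] > res$r2[["marginal"]])
  if (!is.null(res$slopes)) {
    expect_equal(nrow(res$slopes$slopes), 2)
    expect_equal(nrow(res$grid), 13)
  }
})
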