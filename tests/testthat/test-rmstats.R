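test_that("partial eta-squared follows from F and its degrees of freedom", {
  expect_equal(round(eta_sq_from_f(17.002, 2, 48), 3), 0.415)
  expect_equal(round(eta_sq_from_f(2.739, 2, 48), 3), 0.102)
  expect_equal(eta_sq_from_f(0, 2, 48), 0)
  expect_error(eta_sq_from_f(-1, 2, 48), class = "reachvr_validation_error")
})

test_that("effect sizes classify with strict 0.25 / 0.64 thresholds", {
  expect_equal(classify_effect_size(0.821), "strong")
  expect_equal(classify_effect_size(0.25), "small")
  expect_equal(classify_effect_size(0.30), "moderate")
  expect_equal(classify_effect_size(0.64), "moderate")
  expect_error(classify_effect_size(1.2), class = "reachvr_validation_error")
})

test_that("Shapiro-Wilk wrapper bounds W and flags skewed samples", {
  withr::local_seed(7)
  sw <- shapiro_wilk(rnorm(31))
  expect_lte(sw$W, 1)
  expect_gt(sw$W, 0)
  # power: exponential samples reject far more often than normal ones
  p_exp <- replicate(200, shapiro_wilk(rexp(31))$p_value)
  p_norm <- replicate(200, shapiro_wilk(rnorm(31))$p_value)
  expect_gt(mean(p_exp < 0.05), 0.5)
  expect_lt(mean(p_norm < 0.05), 0.15)
  expect_error(shapiro_wilk(c(1, 2)), class = "reachvr_validation_error")
})

test_that("the two-way decomposition matches a loop-coded oracle to 1e-10", {
  withr::local_seed(13)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    Y <- array(rnorm(n * 3 * 4, sd = 3), c(n, 3, 4))
    tab <- long_from_array(Y)
    fit <- rm_anova(tab, y, participant, c(game, theta_deg))
    or <- oracle_rm_ss(Y)
    got <- tidy(fit)
    expect_equal(got$F, unname(or$F), tolerance = 1e-10)
    expect_equal(got$ss_effect, unname(unlist(or$ss[c("A", "B", "AB")])), tolerance = 1e-10)
    expect_equal(got$ss_error, unname(unlist(or$ss[c("AS", "BS", "ABS")])), tolerance = 1e-10)
    expect_equal(got$df1_uncorrected, unname(unlist(or$df[c("A", "B", "AB")])))
    # partial eta^2 agrees with the F/df identity on every effect
    expect_equal(got$partial_eta_sq,
                 eta_sq_from_f(got$F, got$df1_uncorrected, got$df2_uncorrected),
                 tolerance = 1e-12)
  }
})

test_that("F, corrected dfs, epsilon and Mauchly agree with car::Anova", {
  skip_if_not_installed("car")
  withr::local_seed(29)
  n <- 12
  Y <- array(rnorm(n * 3 * 4), c(n, 3, 4))
  # induce non-sphericity so the GG path is exercised
  Y[, 1, ] <- Y[, 1, ] * 3
  Y[, , 4] <- Y[, , 4] + 2 * Y[, , 1]
  tab <- long_from_array(Y)
  fit <- tidy(rm_anova(tab, y, participant, c(game, theta_deg)))

  wide <- do.call(cbind, lapply(1:3, function(j) Y[, j, ]))  # game slow, theta fast
  idata <- expand.grid(theta = factor(1:4), game = factor(1:3))[, c(2, 1)]
  mlm <- lm(wide ~ 1)
  A <- car::Anova(mlm, idata = idata, idesign = ~ game * theta, type = 3)
  s <- summary(A, multivariate = FALSE)
  uni <- s$univariate.tests
  eff <- c("game", "theta", "game:theta")
  F_car <- uni[eff, "F value"]
  expect_equal(fit$F, unname(F_car), tolerance = 1e-8)
  gg <- s$pval.adjustments
  expect_equal(fit$epsilon_gg, unname(gg[eff, "GG eps"]), tolerance = 1e-8)
  mau <- s$sphericity.tests
  # the second-order term of the chi-square expansion is computed slightly
  # differently in base R's mauchly.test; agreement is to ~1e-4, exact for
  # 2-dimensional effects where the term vanishes
  expect_equal(fit$mauchly_p[1], unname(mau["game", "p-value"]), tolerance = 1e-10)
  expect_true(all(abs(fit$mauchly_p - unname(mau[eff, "p-value"])) < 1e-3))
  # both reach the same accept/reject decisions at alpha = .05
  expect_equal(fit$mauchly_p < 0.05, unname(mau[eff, "p-value"]) < 0.05)
  # GG-corrected p-values
  p_gg <- unname(gg[eff, "Pr(>F[GG])"])
  p_mine <- ifelse(fit$corrected, fit$p,
                   pf(fit$F, fit$epsilon_gg * fit$df1_uncorrected,
                      fit$epsilon_gg * fit$df2_uncorrected, lower.tail = FALSE))
  expect_equal(p_mine, p_gg, tolerance = 1e-8)
})

test_that("flat tables give zero F and epsilon respects its bounds", {
  tab <- long_from_array(array(5, c(4, 3, 4)))
  tab$y <- tab$y + rep(rnorm(4, sd = 2), times = 12)  # subject offsets only
  fit <- tidy(rm_anova(tab, y, participant, c(game, theta_deg)))
  expect_true(all(fit$F < 1e-20))
  expect_true(all(fit$partial_eta_sq < 1e-20))

  withr::local_seed(31)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    Z <- matrix(rnorm(20 * k), 20) %*% matrix(rnorm(k * k), k)
    tab1 <- tidyr::expand_grid(participant = sprintf("S%d", 1:20),
                               cond = paste0("c", seq_len(k)))
    tab1$y <- as.vector(t(Z))
    f1 <- tidy(rm_anova(tab1, y, participant, cond))
    expect_gte(f1$epsilon_gg, 1 / (k - 1) - 1e-12)
    expect_lte(f1$epsilon_gg, 1 + 1e-12)
  }
  # 2-level factors are spherical by construction
  tab2 <- tidyr::expand_grid(participant = sprintf("S%d", 1:10), cond = c("a", "b"))
  withr::with_seed(3, tab2$y <- rnorm(nrow(tab2)))
  f2 <- tidy(rm_anova(tab2, y, participant, cond))
  expect_equal(f2$epsilon_gg, 1)
  expect_true(is.na(f2$mauchly_p))
})

test_that("epsilon approaches 1 for compound-symmetric data as n grows", {
  withr::local_seed(17)
  eps_for_n <- function(n) {
    subj <- rnorm(n, sd = 2)
    tab <- tidyr::expand_grid(participant = seq_len(n), cond = paste0("c", 1:4))
    tab$y <- subj[tab$participant] + rnorm(nrow(tab))
    tidy(rm_anova(tab, y, participant, cond))$epsilon_gg
  }
  expect_gt(mean(replicate(20, eps_for_n(200))), 0.97)
})

test_that("incomplete designs and missing outcomes are rejected", {
  tab <- long_from_array(array(rnorm(3 * 3 * 4), c(3, 3, 4)))
  expect_error(rm_anova(tab[-1, ], y, participant, c(game, theta_deg)),
               class = "reachvr_design_error")
  tab$y[2] <- NA
  expect_error(rm_anova(tab, y, participant, c(game, theta_deg)),
               class = "reachvr_design_error")
})

test_that("LSD pairs are antisymmetric, null on ties and detect shifts", {
  tab <- tidyr::expand_grid(participant = sprintf("S%d", 1:10),
                            cond = c("a", "b", "c"))
  tab$y <- 5  # identical conditions
  withr::local_seed(23)
  tab$y <- tab$y + rep(rnorm(10), each = 3)
  ph <- lsd_posthoc(tab, y, participant, cond)
  expect_equal(nrow(ph), 3L)
  expect_true(all(abs(ph$mean_diff) < 1e-12))
  expect_true(all(ph$p_value == 1))

  # strong shift on one level is detected essentially always
  hits <- replicate(50, {
    tab$y <- rep(rnorm(10), each = 3) + rnorm(30) + ifelse(tab$cond == "c", 2.5, 0)
    ph <- lsd_posthoc(tab, y, participant, cond)
    all(ph$p_value[ph$level_2 == "c" | ph$level_1 == "c"] < 0.05)
  })
  expect_gt(mean(hits), 0.9)

  # antisymmetry: differences negate when the pair order flips
  tab$y <- rnorm(30)
  ph1 <- lsd_posthoc(tab, y, participant, cond)
  tab$cond <- factor(tab$cond, levels = c("c", "b", "a"))
  ph2 <- lsd_posthoc(tab, y, participant, cond)
  d1 <- ph1$mean_diff[ph1$level_1 == "a" & ph1$level_2 == "c"]
  d2 <- ph2$mean_diff[ph2$level_1 == "c" & ph2$level_2 == "a"]
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("simple effects match one-way fits on each height sub-table", {
  withr::local_seed(37)
  Y <- array(rnorm(8 * 3 * 4), c(8, 3, 4))
  Y[, 3, 4] <- Y[, 3, 4] + 3   # game effect only at the lowest target
  tab <- long_from_array(Y)
  se <- simple_effects(tab, y, participant, game, theta_deg)
  expect_equal(nrow(se), 4L)
  expect_equal(se$theta_deg, c(15, 30, 45, 60))
  # equivalence with a direct one-way fit on the restricted table
  sub45 <- tab[tab$theta_deg == 45, ]
  direct <- tidy(rm_anova(sub45, y, participant, game))
  expect_equal(se$F[se$theta_deg == 45], direct$F, tolerance = 1e-12)
  expect_equal(se$p[se$theta_deg == 45], direct$p, tolerance = 1e-12)
  # the injected effect shows up where it was injected
  expect_lt(se$p[se$theta_deg == 60], 0.05)
  expect_true(all(se$p[se$theta_deg != 60] > se$p[se$theta_deg == 60]))
  expect_equal(nrow(se$posthoc[[1]]), 3L)
})

test_that("normality screening runs per design cell", {
  withr::local_seed(41)
  Y <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  ns <- normality_screen(long_from_array(Y), y, c(game, theta_deg))
  expect_equal(nrow(ns), 12L)
  expect_true(all(ns$n == 10))
  expect_true(all(ns$W > 0 & ns$W <= 1))
})
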