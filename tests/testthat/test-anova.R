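rand_table <- function(n_subj, levels, seed) {
  set.seed(seed)
  g <- expand.grid(c(list(s = factor(seq_len(n_subj))),
                     lapply(levels, function(l) factor(seq_len(l)))))
  g$y <- rnorm(nrow(g))
  g
}

test_that("constant responses give zero effect SS and zero F", {
  d <- expand.grid(s = factor(1:4), a = factor(1:2), b = factor(1:3))
  d$y <- as.numeric(d$s)          # varies only between participants
  fit <- rm_anova(d, "y", "s", c("a", "b"))
  expect_true(all(abs(fit$effects$SS) < 1e-12))
  expect_true(all(fit$effects$F == 0))
  expect_true(all(fit$effects$p == 1))
})

test_that("a 2-level within factor reproduces the squared paired t statistic", {
  set.seed(41)
  n <- 9
  d <- data.frame(s = factor(rep(1:n, 2)),
                  a = factor(rep(c("x", "y"), each = n)),
                  y = rnorm(2 * n, mean = rep(c(0, 0.5), each = n)))
  fit <- rm_anova(d, "y", "s", "a")
  tt <- t.test(d$y[d$a == "x"], d$y[d$a == "y"], paired = TRUE)
  expect_equal(fit$effects$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$effects$df, 1)
  expect_equal(fit$errors$df, n - 1)
  expect_equal(fit$effects$p, tt$p.value, tolerance = 1e-10)
})

test_that("the full decomposition agrees with the aov() error-strata oracle", {
  d <- rand_table(5, list(a = 3, b = 2, c = 2), seed = 42)
  fit <- rm_anova(d, "y", "s", c("a", "b", "c"))
  or <- summary(aov(y ~ a * b * c + Error(s / (a * b * c)), data = d))
  for (eff in fit$effects$effect) {
    stratum <- or[[paste0("Error: s:", eff)]][[1]]
    expect_equal(fit$effects$SS[fit$effects$effect == eff],
                 stratum[eff, "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$effects$F[fit$effects$effect == eff],
                 stratum[eff, "F value"], tolerance = 1e-8)
    expect_equal(fit$errors$SS[fit$effects$effect == eff],
                 stratum["Residuals", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$effects$df[fit$effects$effect == eff],
                 stratum[eff, "Df"])
  }
})

test_that("sums of squares are conserved on random balanced tables", {
  for (seed in 1:100) {
    n <- sample(3:6, 1)
    k <- sample(1:3, 1)
    lv <- as.list(sample(2:3, k, replace = TRUE))
    names(lv) <- letters[seq_len(k)]
    d <- rand_table(n, lv, seed)
    fit <- rm_anova(d, "y", "s", names(lv))
    lhs <- sum(fit$effects$SS) + sum(fit$errors$SS) + fit$subject$SS
    expect_lt(abs(lhs - fit$total$SS), 1e-8 * max(1, fit$total$SS))
    expect_true(all(fit$effects$df >= 1) && all(fit$effects$F >= 0))
  }
})

test_that("F statistics are translation-invariant and scale-equivariant", {
  d <- rand_table(6, list(a = 2, b = 3), seed = 7)
  f0 <- rm_anova(d, "y", "s", c("a", "b"))$effects$F
  d1 <- d; d1$y <- d$y + 100
  d2 <- d; d2$y <- d$y * 3.2
  expect_equal(rm_anova(d1, "y", "s", c("a", "b"))$effects$F, f0,
               tolerance = 1e-9)
  expect_equal(rm_anova(d2, "y", "s", c("a", "b"))$effects$F, f0,
               tolerance = 1e-9)
})

test_that("incomplete or unbalanced tables are rejected with the missing cell named", {
  d <- rand_table(4, list(a = 2, b = 2), seed = 9)
  expect_error(rm_anova(d[-3, ], "y", "s", c("a", "b")),
               "not complete/balanced")
  expect_error(rm_anova(d[-3, ], "y", "s", c("a", "b")), "s=3")
  expect_error(rm_anova(rbind(d, d[1, ]), "y", "s", c("a", "b")),
               "not complete/balanced")
})

test_that("pooled-error simple effects reproduce the published df patterns", {
  # drug(2) x eye(2) x session(4), 14 participants:
  # pooled error df = 13 * (1 + 1 + 3 + 3) = 104
  d <- rand_table(14, list(drug = 2, eye = 2, session = 4), seed = 10)
  fit <- rm_anova(d, "y", "s", c("drug", "eye", "session"))
  se <- simple_effects(fit, "eye",
                       at = list(drug = "1", session = as.character(1:4)))
  expect_equal(nrow(se), 4)
  expect_true(all(se$df_den == 104))
  expect_true(all(se$df_num == 1))

  # phase(2) x eye(2) x duration(3), 14 participants, eye within phase:
  # pooled error df = 13 * (1 + 1) = 26
  d2 <- rand_table(14, list(phase = 2, eye = 2, duration = 3), seed = 11)
  fit2 <- rm_anova(d2, "y", "s", c("phase", "eye", "duration"))
  se2 <- simple_effects(fit2, "eye", at = list(phase = c("1", "2")))
  expect_true(all(se2$df_den == 26))

  # latency one-way comparison df pattern: groups 12/11/10 -> df (2, 30)
  ow <- oneway_anova(list(rnorm(12), rnorm(11), rnorm(10)))
  expect_equal(ow$df, c(2, 30))
})

test_that("simple effects reduce to the omnibus test and decompose exactly", {
  d <- rand_table(8, list(a = 3), seed = 12)
  fit <- rm_anova(d, "y", "s", "a")
  se <- simple_effects(fit, "a")
  expect_equal(se$F, fit$effects$F, tolerance = 1e-10)
  expect_equal(se$df_den, fit$errors$df)

  # classic identity: sum of simple-effect SS of a at each b level
  # equals SS_a + SS_{a:b}
  d2 <- rand_table(6, list(a = 3, b = 2), seed = 13)
  fit2 <- rm_anova(d2, "y", "s", c("a", "b"))
  se2 <- simple_effects(fit2, "a", at = list(b = c("1", "2")))
  expect_equal(sum(se2$SS),
               sum(fit2$effects$SS[fit2$effects$effect %in% c("a", "a:b")]),
               tolerance = 1e-10)
  # cell-wise error option uses the slice's own interaction stratum df
  sec <- simple_effects(fit2, "a", at = list(b = "1"), pooled = FALSE)
  expect_equal(sec$df_den, (6 - 1) * (3 - 1))
})

test_that("Greenhouse-Geisser epsilon is 1 for 2-level factors and bounded", {
  d <- rand_table(10, list(a = 2, b = 4), seed = 14)
  fit <- rm_anova(d, "y", "s", c("a", "b"), gg = TRUE)
  ea <- fit$effects$eps_gg[fit$effects$effect == "a"]
  eb <- fit$effects$eps_gg[fit$effects$effect == "b"]
  expect_equal(ea, 1, tolerance = 1e-10)
  expect_gte(eb, 1 / 3)
  expect_lte(eb, 1)
  expect_equal(fit$effects$df_gg, fit$effects$df * fit$effects$eps_gg)
})
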