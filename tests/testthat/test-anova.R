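rand_table <- function(n = 12, levels = list(a = 2, b = 3), seed = 1,
                       effects = NULL) {
  set.seed(seed)
  g <- do.call(expand.grid, c(lapply(levels, function(k)
    paste0("l", seq_len(k))), list(subject = paste0("s", seq_len(n)),
                                   stringsAsFactors = FALSE)))
  g$y <- rnorm(nrow(g))
  if (!is.null(effects)) g$y <- g$y + effects(g)
  g
}

test_that("two-level effects have epsilon exactly 1 and F equals t squared", {
  d <- rand_table(n = 14, levels = list(a = 2), seed = 3)
  fit <- rm_anova(d, dv = "y", within = "a")
  expect_equal(fit$table$eps, 1)
  y1 <- d$y[d$a == "l1"][order(d$subject[d$a == "l1"])]
  y2 <- d$y[d$a == "l2"][order(d$subject[d$a == "l2"])]
  tt <- t.test(y1, y2, paired = TRUE)
  expect_equal(fit$table$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(fit$table$p, tt$p.value, tolerance = 1e-9)
})

test_that("F, epsilon and corrected p agree with the car oracle", {
  d <- rand_table(n = 10, levels = list(a = 2, b = 3), seed = 11,
                  effects = function(g) 0.8 * (g$a == "l1") +
                    0.5 * (g$b == "l2") * (g$a == "l2"))
  fit <- rm_anova(d, dv = "y", within = c("a", "b"))

  # build the multivariate lm in the same cell order as rm_anova
  cells <- expand.grid(a = c("l1", "l2"), b = c("l1", "l2", "l3"),
                       stringsAsFactors = FALSE)
  Y <- sapply(seq_len(nrow(cells)), function(i) {
    sel <- d$a == cells$a[i] & d$b == cells$b[i]
    d$y[sel][order(d$subject[sel])]
  })
  mod <- lm(Y ~ 1)
  idata <- data.frame(a = factor(cells$a), b = factor(cells$b))
  av <- suppressWarnings(car::Anova(mod, idata = idata, idesign = ~ a * b,
                                    type = 3))
  s <- suppressWarnings(summary(av, multivariate = FALSE))  # HF eps notice
  uni <- s$univariate.tests
  gg <- s$pval.adjustments
  for (ef in c("a", "b", "a:b")) {
    mine <- fit$table[fit$table$effect == ef, ]
    expect_equal(mine$F, unname(uni[ef, "F value"]), tolerance = 1e-8)
    expect_equal(mine$p_uncorrected, unname(uni[ef, "Pr(>F)"]),
                 tolerance = 1e-8)
    if (ef %in% rownames(gg)) {
      expect_equal(mine$eps, unname(gg[ef, "GG eps"]), tolerance = 1e-8)
      expect_equal(mine$p, unname(gg[ef, "Pr(>F[GG])"]), tolerance = 1e-8)
    }
  }
})

test_that("epsilon respects its bounds on arbitrary data", {
  for (seed in 1:5) {
    d <- rand_table(n = 8, levels = list(a = 4), seed = seed)
    fit <- rm_anova(d, dv = "y", within = "a")
    expect_gte(fit$table$eps, 1 / 3)
    expect_lte(fit$table$eps, 1 + 1e-12)
  }
})

test_that("incomplete designs are rejected", {
  d <- rand_table(n = 6, levels = list(a = 2))
  d <- d[-1, ]
  expect_error(rm_anova(d, dv = "y", within = "a"), "complete")
  expect_error(rm_anova(d, dv = "z", within = "a"), "column")
})

test_that("Tukey HSD behaves at its limits", {
  # all-equal cell means: p near 1
  d <- rand_table(n = 12, levels = list(a = 3), seed = 2)
  d$y <- rnorm(nrow(d), 0, 0.01) + as.numeric(factor(d$subject))
  fit <- rm_anova(d, dv = "y", within = "a")
  tk <- tukey_hsd(fit, "a")
  expect_true(all(tk$p > 0.5))
  # one displaced cell: its comparisons are overwhelming
  d2 <- rand_table(n = 15, levels = list(a = 3), seed = 4)
  d2$y <- rnorm(nrow(d2), 0, 1) + ifelse(d2$a == "l2", 10, 0)
  fit2 <- rm_anova(d2, dv = "y", within = "a")
  tk2 <- tukey_hsd(fit2, "a")
  hit <- tk2[tk2$cell_a == "l2" | tk2$cell_b == "l2", ]
  expect_true(all(hit$p < 0.001))
  expect_error(tukey_hsd(fit2, "a:b"), "not fitted")
})

test_that("two-cell Tukey p equals the paired t-test p", {
  d <- rand_table(n = 13, levels = list(a = 2), seed = 8,
                  effects = function(g) 0.5 * (g$a == "l1"))
  fit <- rm_anova(d, dv = "y", within = "a")
  tk <- tukey_hsd(fit, "a")
  y1 <- d$y[d$a == "l1"][order(d$subject[d$a == "l1"])]
  y2 <- d$y[d$a == "l2"][order(d$subject[d$a == "l2"])]
  tt <- t.test(y1, y2, paired = TRUE)
  expect_equal(tk$p, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$q, sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-9)
})
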