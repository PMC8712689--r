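test_that("digestibility follows the mass-loss formula", {
  expect_equal(ivcwd(1.0, 0.664), 33.6)
  expect_equal(ivcwd(1, 0), 100)
  expect_equal(ivcwd(1, 1), 0)
  expect_error(ivcwd(1, 1.2), "invalid-input")
  expect_error(ivcwd(0, 0), "invalid-input")
})

test_that("relative phenolics reproduce the printed bracketed values", {
  expect_equal(round(unlist(relative_phenolics(20.13, 1.06, 0.57)), 2),
               c(kl_rel = 92.51, pca_rel = 4.87, fa_rel = 2.62))
  expect_equal(round(unlist(relative_phenolics(20.51, 1.59, 0.62)), 2),
               c(kl_rel = 90.27, pca_rel = 7.00, fa_rel = 2.73))
  eq <- relative_phenolics(1, 1, 1)
  expect_equal(unlist(eq), c(kl_rel = 100, pca_rel = 100, fa_rel = 100) / 3)
  # closure invariant on arbitrary vectors
  set.seed(8)
  r <- relative_phenolics(runif(20, 10, 25), runif(20, 0.5, 3),
                          runif(20, 0.3, 1))
  expect_equal(rowSums(r), rep(100, 20))
  expect_error(relative_phenolics(0, 0, 0), "zero")
})

test_that("summary statistics use the population CV", {
  s <- summary_stats(c(0, 10))
  expect_equal(s$mean, 5)
  expect_equal(s$cv_pct, 100)
  expect_equal(summary_stats(rep(4, 5))$cv_pct, 0)
  expect_error(summary_stats(3), "at least 2")
})

test_that("PCA satisfies its algebraic identities", {
  set.seed(14)
  # two perfectly correlated variables: one component carries everything
  x <- cbind(a = rnorm(12), b = 0)
  x[, "b"] <- 2 * x[, "a"] + 3
  p <- stem_pca(x, standardize = TRUE)
  expect_equal(p$var_explained_pct[1], 100)
  # reconstruction identity
  x2 <- matrix(rnorm(14 * 6), 14)
  p2 <- stem_pca(x2, standardize = TRUE)
  rec <- p2$scores %*% t(p2$loadings)
  expect_equal(rec, scale(x2, p2$center, p2$scale), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(diff(p2$var_explained_pct) <= 1e-8))
  expect_equal(crossprod(p2$loadings), diag(6), ignore_attr = TRUE,
               tolerance = 1e-8)
  # permutation invariance of the spectrum
  perm <- sample(14)
  p3 <- stem_pca(x2[perm, ], standardize = TRUE)
  expect_equal(p3$var_explained_pct, p2$var_explained_pct, tolerance = 1e-8)
  # unstandardised mode keeps variable scales
  p4 <- stem_pca(x2, standardize = FALSE)
  expect_null(p4$correlation_circle)
  expect_error(stem_pca(cbind(x2, 1), standardize = TRUE), "constant")
})

test_that("correlation-circle display rule filters weak variables", {
  set.seed(15)
  z <- rnorm(30)
  x <- cbind(strong = z + rnorm(30, 0, 0.1), weak = rnorm(30),
             strong2 = -z + rnorm(30, 0, 0.2))
  p <- stem_pca(x, TRUE)
  shown <- circle_variables(p, c(1, 2), min_r = 0.5)
  expect_true(all(c("strong", "strong2") %in% shown))
})

test_that("one-way ANOVA matches the closed-form two-group identities", {
  # hand-computed one-way F for two groups of 3
  g <- rep(c("a", "b"), each = 3)
  y <- c(-1, 0, 1, 9, 10, 11)
  a <- stem_anova(data.frame(g = g, y = y), "y", "g")
  n <- 3; ssb <- 2 * n * (5 - 0)^2 / 2 * 1  # n*sum((group mean - grand)^2)
  ssb <- n * ((0 - 5)^2 + (10 - 5)^2)
  ssw <- sum((y[1:3])^2) + sum((y[4:6] - 10)^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  expect_equal(a$F, f_hand)
  # F = t^2 on two-level designs
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # no variation at all: F defined as 0
  a0 <- stem_anova(data.frame(g = g, y = rep(2, 6)), "y", "g")
  expect_equal(a0$F, 0)
  expect_error(stem_anova(data.frame(g = rep("a", 4), y = rnorm(4)),
                          "y", "g"), "fewer than 2")
})

test_that("two-way Type II sums of squares match an external oracle", {
  # fixture frozen from statsmodels anova_lm(typ=2) on the same data
  set.seed(11)
  d <- expand.grid(line = paste0("L", 1:4), tissue = c("r", "b", "p"))
  d <- rbind(d, d[1:5, ])
  d$y <- round(rnorm(nrow(d), mean = as.numeric(factor(d$line)) +
                       2 * (d$tissue == "p")), 4)
  a <- stem_anova(d, "y", c("line", "tissue"))
  expect_equal(a$sum_sq, c(23.620595, 14.044787, 4.747881), tolerance = 1e-6)
  expect_equal(a$F, c(15.853886, 14.140062, 1.593363), tolerance = 1e-6)
  expect_equal(a$p, c(0.005489, 0.008749, 0.312882), tolerance = 1e-4)
  expect_equal(a$stars[1:2], c("**", "**"))
})

test_that("an injected interaction is detected", {
  set.seed(16)
  d <- expand.grid(line = paste0("L", 1:6), tissue = c("r", "p"), rep = 1:4)
  d$y <- rnorm(nrow(d), sd = 1) +
    3 * (d$line == "L2" & d$tissue == "p")   # 3x noise sd
  a <- stem_anova(d, "y", c("line", "tissue"))
  expect_lt(a$p[a$effect == "line:tissue"], 0.05)
})

test_that("Tukey comparisons produce coherent letters", {
  set.seed(17)
  d <- data.frame(g = rep(paste0("L", 1:4), each = 5),
                  y = rnorm(20, sd = 1))
  d$y[d$g == "L4"] <- d$y[d$g == "L4"] + 10   # 10 sd shift
  fit <- stem_anova(d, "y", "g")
  cmp <- emm_compare(fit, "g")
  expect_true(all(cmp$pairs$p_adj >= cmp$pairs$p_raw - 1e-12))
  # the shifted level gets a letter no other level shares
  l4 <- cmp$letters[["L4"]]
  others <- cmp$letters[setdiff(names(cmp$letters), "L4")]
  expect_false(any(vapply(strsplit(l4, "")[[1]],
                          function(ch) any(grepl(ch, others, fixed = TRUE)),
                          logical(1))))
  # all-equal levels share a single letter
  d2 <- data.frame(g = rep(paste0("L", 1:3), each = 4), y = rnorm(12, sd = 1))
  cmp2 <- emm_compare(stem_anova(d2, "y", "g"), "g")
  expect_true(all(cmp2$letters == "a"))
})

test_that("correlation profiles flag the built-in relationships", {
  set.seed(18)
  n <- 14
  rel <- data.frame(line = sprintf("M%02d", 1:n),
                    kl_rel = runif(n, 85, 93))
  rel$pca_rel <- (100 - rel$kl_rel) * 0.75
  rel$fa_rel <- 100 - rel$kl_rel - rel$pca_rel
  chans <- channel_names()
  spectra <- data.frame(line = rel$line, tissue = "rind")
  for (ch in chans) spectra[[ch]] <- rnorm(n)
  # one channel is an affine image of the compound
  spectra$BLg <- 0.05 * rel$kl_rel - 2
  prof <- correlation_profile(spectra, rel)
  blg <- prof[prof$compound == "KL" & prof$channel == "BLg", ]
  expect_equal(blg$r, 1)
  expect_true(blg$significant)
  # permuted compound decorrelates
  rel2 <- rel
  rel2$kl_rel <- sample(rel$kl_rel)
  spectra2 <- spectra; spectra2$BLg <- rnorm(n)
  prof2 <- correlation_profile(spectra2, rel2)
  expect_lt(mean(abs(prof2$r[prof2$compound == "KL"])), 0.5)
  expect_error(correlation_profile(spectra[1:3, ], rel[1:3, ]),
               "insufficient-data")
})

test_that("fixture tables load and are internally consistent", {
  comp <- load_composition_table()
  expect_equal(nrow(comp), 14)
  expect_true(all(comp$kl_pct_cw + comp$pca_pct_cw + comp$fa_pct_cw < 100))
  morpho <- load_morphology_table()
  expect_true(all(c("M01", "M04", "M09", "M14") %in% names(morpho)))
  # printed parenchyma wall densities are the spherical-cell model applied
  # to the printed mean sizes (two decimals); near-rind M09 differs by one
  # rounding unit in print
  pm_cd <- morpho[morpho$code == "Pm_CD", c("M01", "M04", "M09", "M14")]
  pm_sz <- morpho[morpho$code == "Pm_Cd", c("M01", "M04", "M09", "M14")]
  expect_equal(unlist(round(cell_wall_density(unlist(pm_sz)), 2)),
               unlist(pm_cd), ignore_attr = TRUE)
})
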