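#' In vitro cell wall digestibility
#'
#' Mass fraction degraded by the pepsin-cellulase protocol:
#' `(M1 - M2) / M1 * 100`.
#'
#' @param M1 dry mass of the extractive-free sample, g.
#' @param M2 dry mass of the residue after enzymatic degradation, g.
#' @return digestibility, percent.
#' @export
ivcwd <- function(M1, M2) {
  if (any(M1 <= 0)) stop("invalid-input: M1 must be positive")
  if (any(M2 < 0) || any(M2 > M1)) stop("invalid-input: need 0 <= M2 <= M1")
  (M1 - M2) / M1 * 100
}

#' Relative cell wall phenolics
#'
#' Each phenolic compound expressed as percent of the sum of the three
#' (Klason lignin + ester pCA + ester FA). The closure to 100 percent
#' induces negative correlations between the relative amounts, which must
#' be kept in mind downstream.
#'
#' @param kl,pca,fa contents in percent of cell wall (vectors allowed).
#' @return data.frame with `kl_rel`, `pca_rel`, `fa_rel` (rows sum to 100).
#' @export
relative_phenolics <- function(kl, pca, fa) {
  if (any(kl < 0) || any(pca < 0) || any(fa < 0))
    stop("invalid-input: negative phenolic content")
  tot <- kl + pca + fa
  if (any(tot <= 0)) stop("invalid-input: zero phenolic sum")
  data.frame(kl_rel = kl / tot * 100, pca_rel = pca / tot * 100,
             fa_rel = fa / tot * 100)
}

#' Mean and coefficient of variation
#'
#' The CV uses the population standard deviation (divisor n), the
#' convention required to reproduce the published summary table; this
#' differs from R's default sample SD.
#'
#' @param values numeric vector, length at least 2.
#' @return list `mean`, `cv_pct`.
#' @export
summary_stats <- function(values) {
  if (length(values) < 2) stop("invalid-input: need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  s <- sqrt(mean((values - m)^2))
  list(mean = m, cv_pct = s / m * 100)
}

#' Principal component analysis with correlation-circle loadings
#'
#' Centred (and optionally unit-variance scaled) SVD. Morphological
#' descriptors are analysed standardised; pseudospectra are analysed
#' unstandardised so that baseline channels carry no artificial weight.
#' When standardised, `correlation_circle` holds the correlation of each
#' variable with each component (loading times the component standard
#' deviation).
#'
#' @param table numeric matrix or data.frame (samples x variables), no
#'   missing values.
#' @param standardize scale variables to unit variance?
#' @return object of class `stem_pca`: `scores`, `loadings`,
#'   `var_explained_pct`, `correlation_circle` (when standardised),
#'   `center`, `scale`, `standardized`.
#' @export
stem_pca <- function(table, standardize = TRUE) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("invalid-input: non-numeric table")
  if (anyNA(x)) stop("invalid-input: missing values")
  if (nrow(x) < 2) stop("invalid-input: need at least 2 samples")
  if (standardize && any(apply(x, 2, sd) == 0))
    stop("invalid-input: constant variable with standardize = TRUE")
  p <- prcomp(x, center = TRUE, scale. = standardize)
  var_pct <- p$sdev^2 / sum(p$sdev^2) * 100
  cc <- if (standardize)
    sweep(p$rotation, 2, p$sdev, `*`) else NULL
  structure(list(scores = p$x, loadings = p$rotation,
                 var_explained_pct = var_pct,
                 correlation_circle = cc,
                 center = p$center,
                 scale = if (standardize) p$scale else NULL,
                 standardized = standardize),
            class = "stem_pca")
}

#' @export
print.stem_pca <- function(x, ...) {
  cat("stem_pca (", if (x$standardized) "standardised" else "unstandardised",
      "): ", nrow(x$scores), " samples, ", nrow(x$loadings),
      " variables\n", sep = "")
  v <- round(x$var_explained_pct[seq_len(min(4, length(x$var_explained_pct)))])
  cat("  variance explained (%):", paste(v, collapse = ", "), "\n")
  invisible(x)
}

#' Variables to display on a correlation circle
#'
#' Mirrors the display rule of the published correlation circles: only
#' variables correlated above `min_r` with at least one of the two shown
#' components are drawn; the rest are listed as points.
#'
#' @param pca [stem_pca()] result (standardised).
#' @param components indices of the two displayed components.
#' @param min_r display threshold (default 0.5).
#' @return character vector of variable names to display.
#' @export
circle_variables <- function(pca, components = c(1, 2), min_r = 0.5) {
  stopifnot(inherits(pca, "stem_pca"))
  if (is.null(pca$correlation_circle))
    stop("correlation circle requires a standardised PCA")
  cc <- pca$correlation_circle[, components, drop = FALSE]
  rownames(cc)[apply(abs(cc) >= min_r, 1, any)]
}

#' One- and two-way analysis of variance (Type II)
#'
#' One-way for a single factor; two-way with interaction for two factors.
#' Sums of squares are Type II (each main effect adjusted for the other,
#' interaction adjusted for both), appropriate for the unbalanced designs
#' arising when sections are missing or repeated.
#'
#' @param data data.frame holding `response` and the factor columns.
#' @param response name of the numeric response column.
#' @param factors character vector of one or two factor column names.
#' @return object of class `stem_anova`: data.frame with `effect`, `df`,
#'   `sum_sq`, `F`, `p`, `stars`, plus the fitted full model as attribute.
#' @export
stem_anova <- function(data, response, factors) {
  stopifnot(length(factors) %in% c(1, 2))
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("invalid-input: factor '", f, "' has fewer than 2 levels")
  }
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "")))
  y <- data[[response]]
  rss <- function(m) sum(residuals(m)^2)
  if (length(factors) == 1) {
    full <- lm(as.formula(paste(response, "~", factors)), data = data)
    null <- lm(as.formula(paste(response, "~ 1")), data = data)
    ss_a <- rss(null) - rss(full)
    df_a <- null$df.residual - full$df.residual
    mse <- rss(full) / full$df.residual
    # a zero effect sum of squares is "no effect" (F = 0) even when the
    # residual variance is also zero (constant response)
    Fv <- if (ss_a <= 1e-12 * max(rss(null), 1)) 0
          else if (mse == 0) Inf else (ss_a / df_a) / mse
    pv <- if (Fv == 0) 1 else pf_upper(Fv, df_a, full$df.residual)
    res <- data.frame(effect = factors, df = df_a, sum_sq = ss_a,
                      F = Fv, p = pv)
  } else {
    fA <- factors[1]; fB <- factors[2]
    f_full <- lm(as.formula(paste(response, "~", fA, "*", fB)), data = data)
    f_ab <- lm(as.formula(paste(response, "~", fA, "+", fB)), data = data)
    f_a <- lm(as.formula(paste(response, "~", fA)), data = data)
    f_b <- lm(as.formula(paste(response, "~", fB)), data = data)
    df_res <- f_full$df.residual
    mse <- rss(f_full) / df_res
    ss_a <- rss(f_b) - rss(f_ab)
    ss_b <- rss(f_a) - rss(f_ab)
    ss_ab <- rss(f_ab) - rss(f_full)
    df_a <- f_b$df.residual - f_ab$df.residual
    df_b <- f_a$df.residual - f_ab$df.residual
    df_ab <- f_ab$df.residual - df_res
    Fv <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / mse
    dfv <- c(df_a, df_b, df_ab)
    res <- data.frame(effect = c(fA, fB, paste0(fA, ":", fB)),
                      df = dfv, sum_sq = c(ss_a, ss_b, ss_ab), F = Fv,
                      p = pf_upper(Fv, dfv, df_res))
    full <- f_full
  }
  res$stars <- stars(res$p)
  structure(res, class = c("stem_anova", "data.frame"), model = full,
            response = response, factors = factors)
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Tukey pairwise comparisons of estimated marginal means
#'
#' Estimated marginal means of one factor of a fitted ANOVA (averaging
#' predictions over a balanced grid of the other factor, if any), all
#' pairwise differences with Tukey HSD adjustment, and a compact letter
#' display: levels sharing a letter are not significantly different.
#'
#' @param fit [stem_anova()] result.
#' @param factor name of the factor to compare.
#' @param alpha significance level (default 0.05).
#' @return list: `emmeans` (named vector), `pairs` (data.frame with raw and
#'   adjusted p), `letters` (named character vector).
#' @export
emm_compare <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "stem_anova"))
  model <- attr(fit, "model")
  factors <- attr(fit, "factors")
  if (!factor %in% factors) stop("unknown factor: ", factor)
  mf <- model.frame(model)
  levs <- levels(mf[[factor]])
  others <- setdiff(factors, factor)
  grid <- if (length(others)) {
    expand.grid(setNames(list(levs, levels(mf[[others]])), c(factor, others)),
                stringsAsFactors = TRUE)
  } else setNames(data.frame(factor(levs, levels = levs)), factor)
  X <- model.matrix(delete.response(terms(model)), grid)
  beta <- coef(model)
  V <- vcov(model)
  # averaging matrix: one row per level of `factor`
  A <- t(vapply(levs, function(l) {
    w <- as.numeric(grid[[factor]] == l)
    w / sum(w)
  }, numeric(nrow(grid))))
  L <- A %*% X
  em <- drop(L %*% beta)
  names(em) <- levs
  k <- length(levs)
  df_res <- model$df.residual
  pairs <- t(combn(k, 2))
  diffs <- em[pairs[, 1]] - em[pairs[, 2]]
  se <- vapply(seq_len(nrow(pairs)), function(i) {
    cvec <- L[pairs[i, 1], ] - L[pairs[i, 2], ]
    sqrt(drop(t(cvec) %*% V %*% cvec))
  }, numeric(1))
  tstat <- diffs / se
  p_raw <- 2 * pt(abs(tstat), df_res, lower.tail = FALSE)
  p_adj <- ptukey(abs(tstat) * sqrt(2), k, df_res, lower.tail = FALSE)
  pr <- data.frame(level1 = levs[pairs[, 1]], level2 = levs[pairs[, 2]],
                   diff = diffs, se = se, t = tstat,
                   p_raw = p_raw, p_adj = pmax(p_adj, p_raw))
  # compact letter display by the sweep method on mean-sorted levels
  ord <- order(em, decreasing = TRUE)
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(nrow(pr)))
    sig[pairs[i, 1], pairs[i, 2]] <- sig[pairs[i, 2], pairs[i, 1]] <-
      pr$p_adj[i] < alpha
  # for each start, the longest run of mutually non-significant levels;
  # run ends are non-decreasing, so containment reduces to comparing ends
  groups <- list()
  last_end <- 0
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1
    if (j > last_end || i == 1) {
      groups[[length(groups) + 1]] <- ord[i:j]
      last_end <- j
    }
    if (j == k) break
  }
  lett <- setNames(rep("", k), levs)
  for (g in seq_along(groups))
    lett[groups[[g]]] <- paste0(lett[groups[[g]]], letters[g])
  list(emmeans = em, pairs = pr, letters = lett)
}

#' Channel-wise correlation profiles between tissue fluorescence and
#' relative phenolics
#'
#' For every tissue and compound, the Pearson correlation across inbred
#' lines between each of the 11 normalised pseudospectrum channels and the
#' relative compound amount, with per-channel two-sided significance at
#' `alpha` (no multiplicity adjustment, mirroring the per-channel display
#' convention). Spectra of repeated sections are averaged per line first.
#'
#' @param spectra data.frame with columns `line`, `tissue` and the 11
#'   channel columns named as [channel_names()].
#' @param rel_phenolics data.frame with columns `line`, `kl_rel`,
#'   `pca_rel`, `fa_rel`.
#' @param alpha significance level.
#' @return data.frame with one row per tissue x compound x channel:
#'   `tissue`, `compound`, `channel`, `r`, `p`, `significant`.
#' @export
correlation_profile <- function(spectra, rel_phenolics, alpha = 0.05) {
  chans <- channel_names()
  stopifnot(all(chans %in% names(spectra)),
            all(c("line", "tissue") %in% names(spectra)),
            all(c("line", "kl_rel", "pca_rel", "fa_rel") %in%
                  names(rel_phenolics)))
  out <- list()
  for (tis in unique(spectra$tissue)) {
    sub <- spectra[spectra$tissue == tis, , drop = FALSE]
    agg <- aggregate(sub[chans], by = list(line = sub$line), FUN = mean)
    m <- merge(agg, rel_phenolics, by = "line")
    if (nrow(m) < 4)
      stop("insufficient-data: fewer than 4 matched lines for tissue ", tis)
    for (comp in c("KL", "pCA", "FA")) {
      y <- m[[c(KL = "kl_rel", pCA = "pca_rel", FA = "fa_rel")[comp]]]
      for (ch in chans) {
        ct <- suppressWarnings(cor.test(m[[ch]], y))
        out[[length(out) + 1]] <- data.frame(
          tissue = tis, compound = comp, channel = ch,
          r = unname(ct$estimate), p = ct$p.value,
          significant = is.finite(ct$p.value) && ct$p.value < alpha)
      }
    }
  }
  res <- do.call(rbind, out)
  res$channel <- factor(res$channel, levels = chans)
  res
}

#' Load the packaged composition table
#'
#' The per-line composition fixture (cell wall content, Klason lignin,
#' ester-linked p-coumaric and ferulic acid, in vitro cell wall
#' digestibility for 14 inbred lines) transcribed from the published
#' summary table.
#'
#' @return data.frame with columns `line`, `cw_pct_dm`, `kl_pct_cw`,
#'   `pca_pct_cw`, `fa_pct_cw`, `ivcwd_pct`.
#' @export
load_composition_table <- function() {
  f <- system.file("extdata", "composition_14lines.csv", package = "stemhisto")
  read.csv(f, stringsAsFactors = FALSE)
}

#' Load the packaged morphology reference table
#'
#' Printed morphological descriptors of the four example inbred lines
#' (M01, M04, M09, M14), including the grey-level mean cell sizes used by
#' the desk-scale cell-wall-density checks.
#'
#' @return data.frame, one row per descriptor, columns `descriptor`,
#'   `code`, `M01`, `M04`, `M09`, `M14`.
#' @export
load_morphology_table <- function() {
  f <- system.file("extdata", "morphology_4lines.csv", package = "stemhisto")
  read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}
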