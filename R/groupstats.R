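## Cross-group statistics used on per-line frequency/spectrum tables:
## Welch t, ANOVA (one-way, or two-way with Type II sums of squares) with
## Tukey HSD, and Fisher's exact test with Bonferroni correction.

#' Welch two-sample t test
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `t`, `df` (Welch-Satterthwaite), `p` (two-sided),
#'   `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' ANOVA with Tukey HSD pairwise comparisons
#'
#' One-way for a single factor; two-way (with interaction) for two. The
#' two-way table uses Type II sums of squares, appropriate for the
#' unbalanced designs that MA-line extinctions produce (`ss_type` is
#' configurable). Tukey-adjusted pairwise p values come from the cell
#' means and do not depend on the SS type.
#'
#' @param design data.frame containing the factors and the response.
#' @param response name of the response column.
#' @param factors character vector of one or two factor column names, each
#'   with >= 2 levels.
#' @param ss_type `"II"` (default), `"I"`, for the two-way table.
#' @return list with `anova` (data.frame: term, df, sum_sq, F, p) and
#'   `tukey` (data.frame of pairwise comparisons with adjusted p).
#' @export
anova_tukey <- function(design, response, factors, ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  for (f in factors) {
    design[[f]] <- factor(design[[f]])
    if (nlevels(design[[f]]) < 2L) stop(sprintf("factor '%s' has < 2 levels", f))
  }
  y <- design[[response]]
  if (length(factors) == 1L) {
    fml <- stats::as.formula(paste(response, "~", factors))
    fit <- aov(fml, data = design)
    at <- anova(fit)
    tab <- data.frame(term = rownames(at), df = at$Df, sum_sq = at$`Sum Sq`,
                      F = at$`F value`, p = at$`Pr(>F)`)
    tk <- TukeyHSD(fit)[[factors]]
  } else if (length(factors) == 2L) {
    a <- factors[1]; b <- factors[2]
    full <- lm(stats::as.formula(sprintf("%s ~ %s * %s", response, a, b)),
               data = design)
    m_ab <- lm(stats::as.formula(sprintf("%s ~ %s + %s", response, a, b)),
               data = design)
    m_a <- lm(stats::as.formula(sprintf("%s ~ %s", response, a)), data = design)
    m_b <- lm(stats::as.formula(sprintf("%s ~ %s", response, b)), data = design)
    rss <- function(m) sum(stats::residuals(m)^2)
    ## without within-cell replication the saturated interaction model has
    ## no residual df: fall back to the additive model (main effects only)
    has_rep <- stats::df.residual(full) > 0L
    if (!has_rep) full <- m_ab
    dfr <- stats::df.residual(full)
    mse <- rss(full) / dfr
    if (ss_type == "II") {
      ss_a <- rss(m_b) - rss(m_ab)
      ss_b <- rss(m_a) - rss(m_ab)
    } else { # Type I, sequential in the order given
      m0 <- lm(stats::as.formula(paste(response, "~ 1")), data = design)
      ss_a <- rss(m0) - rss(m_a)
      ss_b <- rss(m_a) - rss(m_ab)
    }
    df_a <- nlevels(design[[a]]) - 1L
    df_b <- nlevels(design[[b]]) - 1L
    terms <- c(a, b); sss <- c(ss_a, ss_b); dfs <- c(df_a, df_b)
    if (has_rep) {
      terms <- c(terms, paste0(a, ":", b))
      sss <- c(sss, rss(m_ab) - rss(full))
      dfs <- c(dfs, stats::df.residual(m_ab) - dfr)
    }
    Fv <- (sss / dfs) / mse
    tab <- data.frame(term = terms, df = dfs, sum_sq = sss, F = Fv,
                      p = pf(Fv, dfs, dfr, lower.tail = FALSE))
    fml <- if (has_rep) sprintf("%s ~ %s * %s", response, a, b)
           else sprintf("%s ~ %s + %s", response, a, b)
    fit <- aov(stats::as.formula(fml), data = design)
    tk <- do.call(rbind, lapply(TukeyHSD(fit, which = factors), function(m) m))
  } else stop("one or two factors supported")
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova = tab, tukey = tukey)
}

#' Fisher's exact test with Bonferroni adjustment
#'
#' 2x2 tables use the exact hypergeometric test; larger tables use exact
#' network enumeration up to a total of 200 and a seeded Monte-Carlo p
#' (1e5 draws) above that, with the method stated in the output.
#'
#' @param count_table nonnegative integer matrix.
#' @param m_comparisons number of comparisons in the family (default 1).
#' @param seed seed for the Monte-Carlo branch.
#' @return list with `p`, `p_adj` (`min(1, m * p)`), `method`.
#' @export
fisher_bonferroni <- function(count_table, m_comparisons = 1L, seed = 1L) {
  count_table <- as.matrix(count_table)
  if (any(count_table < 0) || any(count_table != round(count_table))) {
    stop("count table must contain nonnegative integers")
  }
  if (all(dim(count_table) == c(2L, 2L))) {
    p <- fisher.test(count_table)$p.value
    method <- "exact hypergeometric (2x2)"
  } else if (sum(count_table) <= 200) {
    p <- fisher.test(count_table, workspace = 2e7)$p.value
    method <- "exact network enumeration"
  } else {
    p <- with_seed(seed, {
      fisher.test(count_table, simulate.p.value = TRUE, B = 1e5)$p.value
    })
    method <- "Monte-Carlo (1e5 draws)"
  }
  list(p = p, p_adj = min(1, m_comparisons * p), method = method)
}
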