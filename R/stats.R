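# The inferential tests applied to derived cohort summaries.  Group
# samples are participant x phrase summary statistics (15 per cohort at
# full scale), never trial-level values.

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance, `df = n_x + n_y - 2`, one- or
#' two-sided.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param alternative `"two.sided"`, `"greater"` (mean of `x` greater)
#'   or `"less"`.
#' @return A `meg_test` list: `statistic`, `df`, `p`, `alternative` and
#'   per-group summaries.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))$statistic
#' @export
two_sample_t <- function(x, y,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (var(x) == 0 && var(y) == 0) stop("zero pooled variance")
  ht <- t.test(x, y, var.equal = TRUE, alternative = alternative)
  structure(list(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, alternative = alternative,
    groups = data.frame(n = c(length(x), length(y)),
                        mean = c(mean(x), mean(y)),
                        sd = c(sd(x), sd(y)))
  ), class = "meg_test")
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA across k groups; F on (k - 1, N - k)
#' degrees of freedom.  With two groups the F statistic equals the
#' square of the pooled two-sample t.
#'
#' @param groups named list of numeric samples (>= 2 groups, each of
#'   length >= 2).
#' @return A `meg_test` list with `statistic` (F), `df` (length 2), `p`,
#'   group summaries, and the fitted `aov` object (for post-hoc use).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 observations")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  structure(list(
    statistic = tab[["F value"]][1],
    df = c(tab[["Df"]][1], tab[["Df"]][2]),
    p = tab[["Pr(>F)"]][1],
    alternative = "two.sided",
    groups = data.frame(n = lengths(groups),
                        mean = vapply(groups, mean, 0),
                        sd = vapply(groups, sd, 0)),
    fit = fit
  ), class = "meg_test")
}

#' Tukey honestly-significant-difference post-hoc comparisons
#'
#' Studentized-range adjusted pairwise comparisons following a one-way
#' ANOVA.
#'
#' @param groups named list of numeric samples.
#' @param alpha family-wise rejection level.
#' @return Data frame with one row per pair: `pair`, `diff`, adjusted
#'   `p_adj`, and the rejection flag `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  tk <- TukeyHSD(an$fit)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.meg_test <- function(x, ...) {
  cat(sprintf("<meg_test> statistic = %.4g, df = %s, p = %.4g (%s)\n",
              x$statistic, paste(x$df, collapse = ", "), x$p,
              x$alternative))
  invisible(x)
}
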