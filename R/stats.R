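#' Left-right EDVR asymmetry index
#'
#' \eqn{(EDVR_{contralateral} - EDVR_{ipsilateral}) / EDVR_{contralateral}}.
#' The index is signed and admits negative values. The study animals are
#' unlesioned, so the side convention is configurable at the pipeline level;
#' the default maps contralateral to the right striatum, which yields positive
#' indices when the left-striatal EDVR is the lower one.
#'
#' @param contralateralEdvr,ipsilateralEdvr unitless EDVR values;
#'   `contralateralEdvr` must be nonzero.
#' @return the unitless asymmetry index.
#' @examples
#' asymmetryIndex(2, 1)    # 0.5
#' asymmetryIndex(1, 1.4)  # -0.4
#' @export
asymmetryIndex <- function(contralateralEdvr, ipsilateralEdvr) {
  if (any(!is.finite(contralateralEdvr)) || any(!is.finite(ipsilateralEdvr)))
    stop("EDVR values must be finite")
  if (any(contralateralEdvr == 0)) stop("contralateral EDVR must be nonzero")
  (contralateralEdvr - ipsilateralEdvr) / contralateralEdvr
}

#' One-way ANOVA with Tukey HSD multiple comparisons
#'
#' Standard one-way analysis of variance across groups followed by Tukey's
#' honestly-significant-difference test on all pairs (Tukey-Kramer for
#' unbalanced groups). Backed by [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param groups named list of numeric vectors, one per group; at least 2
#'   groups of at least 2 values each.
#' @param alpha significance level used to flag pairs (default 0.05).
#' @return a list of class `"dopaGroupComparison"` with elements
#'   `group_labels`, `F_statistic`, `df`, `p_value`, `alpha` and `pairwise`
#'   (a data.frame with pair, mean difference, adjusted p and a significance
#'   flag; one row per unordered pair).
#' @examples
#' anovaTukey(list(WT = c(1, 2, 3), het = c(1, 2, 3), hom = c(5, 6, 7)))
#' @export
anovaTukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 values")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(pair = rownames(tk),
                         mean_difference = unname(tk[, "diff"]),
                         p_adjusted = unname(tk[, "p adj"]),
                         significant = unname(tk[, "p adj"]) < alpha,
                         stringsAsFactors = FALSE)
  structure(list(group_labels = names(groups),
                 F_statistic = tab[["F value"]][1L],
                 df = unname(tab[["Df"]]),
                 p_value = tab[["Pr(>F)"]][1L],
                 alpha = alpha, pairwise = pairwise),
            class = "dopaGroupComparison")
}

#' @export
print.dopaGroupComparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$F_statistic, x$p_value))
  cat(sprintf("Tukey HSD (alpha = %g):\n", x$alpha))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Two-sided paired t test
#'
#' Paired t statistic on the elementwise differences, backed by
#' [stats::t.test()]. Zero-variance differences are rejected rather than
#' returning an infinite statistic.
#'
#' @param left,right numeric vectors of equal length (>= 2 pairs).
#' @return a list of class `"dopaPairedComparison"` with `t_statistic`,
#'   `degrees_of_freedom` (n - 1) and `p_value`.
#' @export
pairedT <- function(left, right) {
  if (length(left) != length(right)) stop("left and right must pair up")
  if (length(left) < 2L) stop("need at least 2 pairs")
  d <- left - right
  if (stats::sd(d) == 0)
    stop("differences have zero variance; paired t test undefined")
  ht <- stats::t.test(left, right, paired = TRUE)
  structure(list(t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "dopaPairedComparison")
}

#' @export
print.dopaPairedComparison <- function(x, ...) {
  cat(sprintf("Paired t test: t(%d) = %.4g, p = %.4g\n",
              x$degrees_of_freedom, x$t_statistic, x$p_value))
  invisible(x)
}

#' Normal quantile-quantile points
#'
#' Theoretical standard-normal quantiles at the plotting positions
#' (i - 0.5)/n against the ordered sample, the diagnostic used to justify
#' parametric group tests on small samples.
#'
#' @param sample numeric vector, n >= 3.
#' @return a data.frame with columns `theoretical` and `sample`.
#' @export
qqPoints <- function(sample) {
  n <- length(sample)
  if (n < 3L) stop("need at least 3 observations")
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort(sample))
}
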