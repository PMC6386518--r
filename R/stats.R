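#' Pearson chi-square test for a 2 x 2 contingency table
#'
#' Closed-form Pearson statistic without continuity correction,
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with one degree of freedom.
#' Used for comparing proportions of modulated or active neurons between
#' groups.
#'
#' @param table 2 x 2 matrix of non-negative counts (rows: groups,
#'   columns: outcome yes/no).
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("chi-square undefined: a marginal total is zero")
  stat <- n * (a * d - b * c)^2 / prod(marg)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Group comparison with a normality gate
#'
#' Normality of each group is assessed with the Lilliefors test; when
#' every group is consistent with normality (p > 0.05) a t-test (two
#' groups) or one-way ANOVA (three or more) is used, otherwise the
#' Wilcoxon rank-sum or Kruskal-Wallis test. With three or more groups,
#' pairwise contrasts use Tukey-Kramer honest significant differences,
#' applied to rank-transformed data in the non-parametric branch.
#'
#' @param groups Named list of numeric vectors, each of length >= 3.
#' @param alpha Level for the pairwise flags.
#' @return List of class `group_comparison`: `test` (name), `parametric`,
#'   `statistic`, `p_value`, `pairwise` (data frame or `NULL`).
#' @export
group_compare <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("at least two groups are required")
  if (any(lengths(groups) < 3L)) stop("each group needs at least 3 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_len(k))
  if (any(vapply(groups, function(g) stats::sd(g) == 0, logical(1))))
    stop("degenerate group (zero variance)")
  norm_p <- vapply(groups, function(g) {
    if (length(g) < 5L) return(0)      # Lilliefors needs n >= 5; treat as non-normal
    nortest::lillie.test(g)$p.value
  }, numeric(1))
  parametric <- all(norm_p > 0.05)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  pairwise <- NULL
  if (k == 2L) {
    if (parametric) {
      ht <- stats::t.test(groups[[1]], groups[[2]])
      test <- "t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
      test <- "rank-sum"
    }
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    if (parametric) {
      fit <- stats::aov(x ~ g)
      s <- summary(fit)[[1]]
      stat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
      test <- "anova"
      tk <- stats::TukeyHSD(fit)$g
    } else {
      ht <- stats::kruskal.test(x, g)
      stat <- unname(ht$statistic); p <- ht$p.value
      test <- "kruskal-wallis"
      tk <- stats::TukeyHSD(stats::aov(rank(x) ~ g))$g
    }
    pairwise <- data.frame(contrast = rownames(tk),
                           p_adj = tk[, "p adj"],
                           different = tk[, "p adj"] < alpha,
                           row.names = NULL)
  }
  structure(list(test = test, parametric = parametric, statistic = stat,
                 p_value = p, normality_p = norm_p, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s, statistic = %.3f, p = %.3g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Tukey-Kramer):\n")
    print(x$pairwise)
  }
  invisible(x)
}
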