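#' @include AllClasses.R
NULL

#' Two-sample Student t-test (pooled variance)
#'
#' Classical pooled-variance two-sided Student t-test with
#' `df = n_a + n_b - 2`. Degenerate data follow the conventions: zero
#' pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means is an error (the statistic is undefined).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @examples
#' tTest2Sample(c(1, 2, 3), c(4, 5, 6))
#' @export
tTest2Sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2, p = 1))
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' One-way analysis of variance
#'
#' Classical between/within F statistic for two or more groups.
#' Zero within-group variance is flagged rather than reported as a bare
#' infinite F.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `df1`, `df2`, `p` and a character vector `flags`.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(1, 2, 3), c(10, 11, 12)))
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  flags <- character(0)
  if (stats::var(y) == 0)
    return(list(F = 0, df1 = length(groups) - 1,
                df2 = length(y) - length(groups), p = 1,
                flags = "degenerate within-group variance"))
  tab <- stats::anova(stats::lm(y ~ g))
  Fv <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  if (tab$`Mean Sq`[2] == 0) {
    flags <- "degenerate within-group variance"
    if (tab$`Sum Sq`[1] == 0) { Fv <- 0; p <- 1 }
  }
  list(F = Fv, df1 = tab$Df[1], df2 = tab$Df[2], p = p, flags = flags)
}

#' Two-way analysis of variance
#'
#' Crossed two-factor ANOVA using Type-II sums of squares (equal to the
#' classical balanced decomposition when the design is balanced). The
#' interaction is fitted when every cell holds at least two replicates;
#' otherwise an additive model is used. Empty cells are an error.
#'
#' @param table data.frame with columns `value` plus two factor columns
#'   named by `factors`.
#' @param factors character(2), the factor column names (defaults to the
#'   first two non-value columns).
#' @return data.frame with one row per effect: `effect`, `F`, `df1`,
#'   `df2`, `p`.
#' @examples
#' d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
#'                  rep = 1:3, KEEP.OUT.ATTRS = FALSE)
#' d$value <- rnorm(nrow(d))
#' twoWayAnova(d, c("A", "B"))
#' @export
twoWayAnova <- function(table, factors = NULL) {
  if (is.null(factors)) factors <- setdiff(names(table), "value")[1:2]
  stopifnot(length(factors) == 2L, "value" %in% names(table))
  f1 <- factor(table[[factors[1]]])
  f2 <- factor(table[[factors[2]]])
  cells <- table(f1, f2)
  if (any(cells == 0)) stop("empty cells: every factor combination needs data")
  d <- data.frame(value = table$value, f1 = f1, f2 = f2)
  form <- if (all(cells >= 2)) value ~ f1 * f2 else value ~ f1 + f2
  fit <- stats::lm(form, data = d)
  aov2 <- car::Anova(fit, type = 2)
  rows <- setdiff(rownames(aov2), "Residuals")
  dfRes <- aov2["Residuals", "Df"]
  eff <- gsub("f1", factors[1], gsub("f2", factors[2], rows, fixed = TRUE),
              fixed = TRUE)
  data.frame(effect = eff, F = aov2[rows, "F value"], df1 = aov2[rows, "Df"],
             df2 = dfRes, p = aov2[rows, "Pr(>F)"], row.names = NULL)
}

#' Group summaries as mean +/- SD
#'
#' Sample standard deviation (n - 1 denominator); a singleton group reports
#' its SD as not available.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with `group`, `n`, `mean`, `sd` and a formatted
#'   `label` column `"mean +/- SD (n)"`.
#' @examples
#' summarizeGroups(list(ctrl = c(2, 4), treated = c(5)))
#' @export
summarizeGroups <- function(groups) {
  if (!length(groups)) stop("no groups supplied")
  nm <- if (is.null(names(groups))) as.character(seq_along(groups)) else names(groups)
  out <- data.frame(
    group = nm,
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(g) if (length(g) < 2L) NA_real_ else stats::sd(g),
                numeric(1)),
    row.names = NULL
  )
  out$label <- ifelse(is.na(out$sd),
                      sprintf("%.3g ± NA (n=%d)", out$mean, out$n),
                      sprintf("%.3g ± %.3g (n=%d)", out$mean, out$sd, out$n))
  out
}

#' Holm-adjusted pairwise t-tests
#'
#' Optional post-hoc companion to [oneWayAnova()]: all pairwise
#' pooled-variance t-tests with Holm multiplicity adjustment. This is a
#' reporting convenience of this package, not a protocol prescription.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with `group1`, `group2`, `t`, `df`, `p`, `pAdj`.
#' @export
pairwiseTTests <- function(groups) {
  nm <- if (is.null(names(groups))) as.character(seq_along(groups)) else names(groups)
  cmb <- utils::combn(seq_along(groups), 2)
  res <- apply(cmb, 2, function(ij) {
    tt <- tTest2Sample(groups[[ij[1]]], groups[[ij[2]]])
    data.frame(group1 = nm[ij[1]], group2 = nm[ij[2]],
               t = tt$t, df = tt$df, p = tt$p)
  })
  res <- do.call(rbind, res)
  res$pAdj <- stats::p.adjust(res$p, method = "holm")
  res
}
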