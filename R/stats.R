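#' Block-by-treatment metric panel
#'
#' A complete matrix of one metric observed for every block (e.g. VOI or
#' replicate) under every treatment (protocol), the unit of analysis for the
#' dependent-sample comparisons.
#'
#' @param values numeric matrix, blocks in rows, treatments in columns.
#' @param blocks,treatments optional identifiers (default from dimnames).
#' @return a `metric_panel` object.
#' @export
metric_panel <- function(values, blocks = rownames(values),
                         treatments = colnames(values)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_invalid("panel must be complete (no missing cells)")
  if (is.null(blocks)) blocks <- paste0("b", seq_len(nrow(values)))
  if (is.null(treatments)) treatments <- paste0("t", seq_len(ncol(values)))
  dimnames(values) <- list(blocks, treatments)
  structure(list(values = values, blocks = blocks, treatments = treatments),
            class = "metric_panel")
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per treatment group and Levene's test (mean-centered) across
#' treatments, flagging groups that depart from normality at alpha = 0.05.
#' Constant groups cannot be tested and are flagged instead of failing.
#'
#' @param panel a [metric_panel()] with at least 3 blocks.
#' @return list with `shapiro` (data.frame: treatment, p, flag_non_normal,
#'   flag_degenerate) and `levene_p`.
#' @export
distribution_checks <- function(panel) {
  stopifnot(inherits(panel, "metric_panel"))
  v <- panel$values
  if (nrow(v) < 3) stop_invalid("need at least 3 observations per group")
  rows <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    if (length(unique(x)) == 1) {
      data.frame(treatment = panel$treatments[j], p = NA_real_,
                 flag_non_normal = NA, flag_degenerate = TRUE)
    } else {
      p <- shapiro.test(x)$p.value
      data.frame(treatment = panel$treatments[j], p = p,
                 flag_non_normal = p < 0.05, flag_degenerate = FALSE)
    }
  })
  long <- data.frame(
    value = as.vector(v),
    treatment = factor(rep(panel$treatments, each = nrow(v)))
  )
  lev <- if (all(apply(v, 2, function(x) length(unique(x)) > 1)))
    car::leveneTest(value ~ treatment, data = long, center = mean)[1, "Pr(>F)"]
  else NA_real_
  list(shapiro = do.call(rbind, rows), levene_p = lev)
}

#' Dependent-sample omnibus comparison
#'
#' Friedman test across three or more treatments; for exactly two, a
#' two-sided Wilcoxon signed-rank test (exact for 25 or fewer blocks).
#'
#' @param panel a [metric_panel()].
#' @return list with `test` ("friedman" or "wilcoxon"), `statistic`, `p`.
#' @export
compare_dependent <- function(panel) {
  stopifnot(inherits(panel, "metric_panel"))
  v <- panel$values
  if (ncol(v) < 2) stop_invalid("need at least 2 treatments")
  if (ncol(v) == 2) {
    d <- v[, 1] - v[, 2]
    exact <- nrow(v) <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
    ht <- wilcox.test(v[, 1], v[, 2], paired = TRUE, exact = exact)
    list(test = "wilcoxon", statistic = unname(ht$statistic), p = ht$p.value)
  } else if (all(v == v[, 1])) {
    # no within-block variation: rank statistic is 0 by definition
    list(test = "friedman", statistic = 0, p = 1)
  } else {
    ht <- friedman.test(v)
    list(test = "friedman", statistic = unname(ht$statistic), p = ht$p.value)
  }
}

#' Paired contrasts against a reference treatment with Holm adjustment
#'
#' For each non-reference treatment, the paired two-sided t contrast against
#' the reference across blocks; p-values are Bonferroni-Holm adjusted over
#' the family of contrasts. The reference row itself carries a zero delta
#' and p = 1.
#'
#' @param panel a [metric_panel()].
#' @param reference treatment identifier of the reference protocol.
#' @return data.frame: treatment, delta (mean difference vs reference),
#'   p_raw, p_holm, significant (at 0.05).
#' @export
anova_posthoc <- function(panel, reference) {
  stopifnot(inherits(panel, "metric_panel"))
  if (!reference %in% panel$treatments)
    stop_invalid("reference treatment '", reference, "' not in panel")
  v <- panel$values
  ref <- v[, reference]
  others <- setdiff(panel$treatments, reference)
  res <- lapply(others, function(tr) {
    d <- v[, tr] - ref
    p <- if (sd(d) == 0) {
      # constant difference: identical (p = 1) or deterministic shift (p -> 0)
      if (mean(d) == 0) 1 else 0
    } else {
      t.test(d)$p.value
    }
    data.frame(treatment = tr, delta = mean(d), p_raw = p)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out <- rbind(data.frame(treatment = reference, delta = 0, p_raw = 1,
                          p_holm = 1), out)
  out$significant <- out$p_holm < 0.05
  rownames(out) <- NULL
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param p raw p-values.
#' @return adjusted p-values (same order), identical to
#'   `p.adjust(p, "holm")` and exposed for the hand-checkable step-down
#'   rule: sort ascending, multiply by m, m-1, ..., enforce monotonicity,
#'   cap at 1.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * (m - seq_len(m) + 1)
  adj <- pmin(cummax(scaled), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
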