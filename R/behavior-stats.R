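#' Mixed-design repeated-measures ANOVA on reaction-time cell means
#'
#' A 2 (preceding congruency) x 2 (current congruency) x 2 (diagnosis group)
#' mixed ANOVA on per-subject condition cell means, with subjects nested in
#' group. Every subject must contribute all four cells (cC, cI, iC, iI);
#' unequal group sizes are handled by the standard mixed-design
#' partitioning, so the between-within terms have denominator df = N - 2.
#' Computed via `stats::aov` with `Error(subject/(pre * cur))` strata.
#'
#' @param cellMeans data.frame with columns `subject`, `group` (two levels),
#'   `cC`, `cI`, `iC`, `iI` (mean RT in ms).
#' @return data.frame with one row per effect (`group`, `pre`, `pre:group`,
#'   `cur`, `cur:group`, `pre:cur`, `pre:cur:group`) and columns `effect`,
#'   `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`.
#' @export
#' @examples
#' cm <- data.frame(subject = 1:6, group = rep(c("a", "b"), 3),
#'                  cC = rnorm(6, 450), cI = rnorm(6, 510),
#'                  iC = rnorm(6, 460), iI = rnorm(6, 485))
#' rmAnovaRT(cm)
rmAnovaRT <- function(cellMeans) {
  need <- c("subject", "group", "cC", "cI", "iC", "iI")
  miss <- setdiff(need, names(cellMeans))
  if (length(miss)) .fail("cellMeans lacks columns: %s",
                          paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(cellMeans[, c("cC", "cI", "iC", "iI")])
  if (any(bad))
    .fail("subject(s) with a missing cell mean: %s",
          paste(cellMeans$subject[bad], collapse = ", "))
  if (length(unique(cellMeans$group)) != 2L)
    .fail("exactly two groups are required")
  long <- data.frame(
    subject = factor(rep(cellMeans$subject, 4)),
    group = factor(rep(cellMeans$group, 4)),
    pre = factor(rep(c("c", "c", "i", "i"), each = nrow(cellMeans))),
    cur = factor(rep(c("C", "I", "C", "I"), each = nrow(cellMeans))),
    rt = c(cellMeans$cC, cellMeans$cI, cellMeans$iC, cellMeans$iI))
  fit <- stats::aov(rt ~ group * pre * cur + Error(subject / (pre * cur)),
                    data = long)
  sm <- summary(fit)
  rows <- list()
  # strata whose total SS is numerical dust (no condition variance at all)
  # get F = 0 rather than a ratio of rounding errors
  ssScale <- sum((long$rt - mean(long$rt))^2)
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    degenerate <- sum(tab[, "Sum Sq"]) <= 1e-12 * max(ssScale, 1)
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      dfd <- tab[trimws(rownames(tab)) == "Residuals", "Df"]
      Fv <- tab[i, "F value"]
      pv <- tab[i, "Pr(>F)"]
      if (degenerate || (!is.finite(Fv) && tab[i, "Sum Sq"] == 0)) {
        Fv <- 0; pv <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub("group:(pre|cur)", "\\1:group",
                      gsub("pre:cur:group|group:pre:cur", "pre:cur:group",
                           terms[i])),
        F = Fv, df_num = tab[i, "Df"], df_den = dfd,
        p = pv,
        partial_eta_sq = (tab[i, "Df"] * Fv) / (tab[i, "Df"] * Fv + dfd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test of adaptation: iI versus cI mean reaction times
#'
#' Tests, across all subjects pooled over groups, whether responses to
#' incongruent trials preceded by an incongruent trial (iI) differ from
#' those preceded by a congruent trial (cI); df = n - 1.
#'
#' @param cI,iI Per-subject mean RTs (ms), equal length.
#' @return A list with `t`, `df`, `p` (two-sided), `mean_diff` (cI - iI).
#' @export
pairedTTestAdaptation <- function(cI, iI) {
  if (length(cI) != length(iI)) .fail("cI and iI must have equal length")
  if (length(cI) < 2L) .fail("need at least two subjects")
  tt <- stats::t.test(cI, iI, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Two-sample test of group accuracy by congruency
#'
#' Pooled-variance two-sample t-test of per-subject accuracy between the two
#' diagnostic groups, computed separately for congruent and incongruent
#' trials; df = n1 + n2 - 2.
#'
#' @param accuracy data.frame with columns `group` (two levels),
#'   `congruent`, `incongruent` (per-subject accuracies in `[0, 1]`).
#' @return data.frame with rows for `congruent` and `incongruent`, columns
#'   `congruency`, `t`, `df`, `p`.
#' @export
accuracyGroupTest <- function(accuracy) {
  gs <- unique(accuracy$group)
  if (length(gs) != 2L) .fail("exactly two groups are required")
  if (min(table(accuracy$group)) < 2L)
    .fail("each group needs at least two subjects")
  one <- function(col) {
    tt <- stats::t.test(accuracy[[col]][accuracy$group == gs[1]],
                        accuracy[[col]][accuracy$group == gs[2]],
                        var.equal = TRUE)
    data.frame(congruency = col, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }
  out <- rbind(one("congruent"), one("incongruent"))
  rownames(out) <- NULL
  out
}
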