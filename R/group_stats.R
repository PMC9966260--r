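# Per-feature group screening: classic one-way ANOVA across the diagnostic
# groups plus Tukey HSD post hoc pairwise comparisons (Tukey-Kramer for the
# unequal group sizes typical of clinical cohorts).

#' One-way ANOVA
#'
#' Classic fixed-effects one-way analysis of variance (equal-variance F
#' test) of a numeric response across groups.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels, same length.
#' @return List with \code{F}, \code{p}, \code{df_between}, \code{df_within}.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations; sizes: ",
         paste(table(groups), collapse = "/"))
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df_between = unname(ow$parameter[1]),
       df_within = unname(ow$parameter[2]))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range based pairwise p-values for all group pairs
#' (Tukey-Kramer adjustment under unequal group sizes).
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels.
#' @return Named numeric vector of adjusted p-values, names "g2-g1".
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  stats::setNames(tk[, "p adj"], rownames(tk))
}

#' Screen features by group difference
#'
#' Runs one-way ANOVA and Tukey HSD post hoc tests on every feature of a
#' feature matrix, mirroring the per-channel/per-pair significance tables
#' of QEEG group studies. P-values are reported raw per feature by
#' default, i.e. with NO correction across features -- the convention of
#' the per-channel tables this reproduces; set \code{p_adjust = "BH"} for
#' Benjamini-Hochberg across features.
#'
#' @param fm Feature matrix data frame: columns \code{subject_id},
#'   \code{group}, then one numeric column per feature (as returned by
#'   \code{\link{cohort_features}}).
#' @param alpha Significance level for flagging (default 0.05).
#' @param p_adjust "none" (default) or "BH".
#' @return Data frame with one row per feature: \code{feature}, \code{F},
#'   \code{p_anova}, one Tukey p column per group pair,
#'   \code{significant} (ANOVA p below alpha after any adjustment), and
#'   \code{pairs_significant} (comma list of pairs with Tukey p < alpha).
#' @export
screen_features <- function(fm, alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  feats <- setdiff(colnames(fm), c("subject_id", "group"))
  if (!length(feats))
    return(data.frame(feature = character(0), F = numeric(0),
                      p_anova = numeric(0), significant = logical(0),
                      pairs_significant = character(0),
                      stringsAsFactors = FALSE))
  groups <- factor(fm$group)
  rows <- lapply(feats, function(fn) {
    v <- fm[[fn]]
    a <- anova_oneway(v, groups)
    tk <- tukey_hsd(v, groups)
    c(list(feature = fn, F = a$F, p_anova = a$p),
      as.list(stats::setNames(tk, paste0("p_", names(tk)))))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  p_eff <- if (p_adjust == "BH") stats::p.adjust(out$p_anova, "BH") else out$p_anova
  out$significant <- p_eff < alpha
  pair_cols <- grep("^p_.+-", colnames(out), value = TRUE)
  out$pairs_significant <- apply(out[, pair_cols, drop = FALSE], 1, function(p)
    paste(sub("^p_", "", pair_cols[p < alpha]), collapse = ","))
  rownames(out) <- NULL
  out
}
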