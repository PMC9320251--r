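#' Non-parametric group comparison of one variable
#'
#' The study's statistical recipe: a Shapiro-Wilk normality check per group
#' is logged; ordinal variables are described as median (p25-p75) and
#' compared with a Kruskal-Wallis omnibus test across 3+ groups plus
#' pairwise Mann-Whitney U tests (a single Mann-Whitney for 2 groups), or
#' with a paired Wilcoxon signed-rank test for within-subject phase
#' contrasts; nominal variables use a chi-squared test, switching to
#' Fisher's exact test when any expected cell count is below 5. Standard
#' test procedures are delegated to the corresponding `stats` routines.
#' No multiplicity correction is applied by default; `pAdjust = "holm"`
#' enables one for the pairwise p-values.
#'
#' @param data data.frame with one row per observation.
#' @param variable name of the value column.
#' @param grouping name of the group label column.
#' @param paired logical; `TRUE` runs a Wilcoxon signed-rank test between
#'   exactly two groups whose observations are aligned by `id`.
#' @param id name of the subject id column (required when `paired`).
#' @param type `"ordinal"` (default) or `"nominal"`.
#' @param pAdjust p-adjustment method for pairwise tests, default
#'   `"none"`.
#' @return a list with `descriptives` (group, n, median, p25, p75, and the
#'   Shapiro-Wilk p-value), `omnibus` (test name, statistic, p), and
#'   `pairwise` (group pair, statistic, p) where applicable.
#' @export
compareGroups <- function(data, variable, grouping, paired = FALSE,
                          id = NULL, type = c("ordinal", "nominal"),
                          pAdjust = "none") {
  type <- match.arg(type)
  .stopIfNot(is.data.frame(data) &&
               all(c(variable, grouping) %in% names(data)),
             "data must contain the variable and grouping columns")
  v <- data[[variable]]
  g <- as.character(data[[grouping]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    sel <- !(g %in% small)
    v <- v[sel]; g <- g[sel]
    if (paired) data <- data[keep, ][sel, ]
  }
  groups <- sort(unique(g))
  .stopIfNot(length(groups) >= 2, "need at least 2 usable groups")

  if (type == "nominal") {
    tab <- table(g, v)
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    useFisher <- any(expct < 5)
    ht <- if (useFisher) stats::fisher.test(tab) else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(
      descriptives = as.data.frame(tab),
      omnibus = data.frame(
        test = if (useFisher) "fisher_exact" else "chi_squared",
        statistic = if (useFisher) NA_real_ else unname(ht$statistic),
        p_value = ht$p.value),
      pairwise = NULL))
  }

  desc <- do.call(rbind, lapply(groups, function(gr) {
    x <- v[g == gr]
    swp <- if (length(x) >= 3 && sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
    data.frame(group = gr, n = length(x), median = median(x),
               p25 = unname(quantile(x, 0.25)),
               p75 = unname(quantile(x, 0.75)),
               shapiro_p = swp, stringsAsFactors = FALSE)
  }))

  if (paired) {
    .stopIfNot(length(groups) == 2, "paired comparison needs exactly 2 groups")
    .stopIfNot(!is.null(id) && id %in% names(data),
               "paired comparison needs the id column")
    dd <- data[!is.na(data[[variable]]), c(id, variable, grouping)]
    wide <- stats::reshape(dd, idvar = id, timevar = grouping,
                           direction = "wide")
    cols <- paste(variable, groups, sep = ".")
    .stopIfNot(all(cols %in% names(wide)), "could not align paired samples")
    cc <- stats::complete.cases(wide[, cols])
    ht <- stats::wilcox.test(wide[cc, cols[1]], wide[cc, cols[2]],
                             paired = TRUE, exact = FALSE)
    return(list(descriptives = desc,
                omnibus = data.frame(test = "wilcoxon_signed_rank",
                                     statistic = unname(ht$statistic),
                                     p_value = ht$p.value),
                pairwise = NULL))
  }

  if (length(groups) >= 3) {
    kw <- stats::kruskal.test(v, factor(g))
    omni <- data.frame(test = "kruskal_wallis",
                       statistic = unname(kw$statistic),
                       p_value = kw$p.value)
  } else {
    mw <- stats::wilcox.test(v[g == groups[1]], v[g == groups[2]],
                             exact = FALSE)
    omni <- data.frame(test = "mann_whitney",
                       statistic = unname(mw$statistic),
                       p_value = mw$p.value)
  }
  pairs <- utils::combn(groups, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ht <- stats::wilcox.test(v[g == a], v[g == b], exact = FALSE)
    data.frame(group1 = a, group2 = b, test = "mann_whitney",
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = pAdjust)
  list(descriptives = desc, omnibus = omni, pairwise = pw)
}
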