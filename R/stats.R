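#' Normality-gated group comparison of every feature
#'
#' For each feature, each group's values are first screened for normality
#' with a Kolmogorov-Smirnov test against a normal with sample-estimated
#' mean and SD (Lilliefors correction via \pkg{nortest} when n >= 5). If
#' every group passes at `normal_alpha`, parametric tests are used (one-way
#' ANOVA across all groups, Welch t-tests pairwise); otherwise
#' nonparametric ones (Kruskal-Wallis across groups, Mann-Whitney U
#' pairwise). Raw p-values are reported by default, mirroring how such
#' screens are usually published; Benjamini-Hochberg adjustment is
#' available behind `adjust = "BH"`.
#'
#' @param features feature table data frame (`subject_id`, `group`, then
#'   numeric feature columns), e.g. from [feature_table()].
#' @param normal_alpha alpha of the normality gate (0.05).
#' @param adjust `"none"` (default) or `"BH"` applied per test column.
#' @return data frame: one row per feature with the routed method, the
#'   omnibus p-value (if >= 3 groups) and one p-value column per group
#'   pair; constant features are skipped and flagged.
#' @export
feature_group_tests <- function(features, normal_alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  grp <- factor(features$group)
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  if (any(table(grp) < 3)) stop("need at least 3 values per group")
  fcols <- feature_cols(features)
  pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
  pair_names <- vapply(pairs, function(p)
    paste0("p_", p[1], "_", p[2]), character(1))
  out <- data.frame(feature = fcols, method = NA_character_,
                    normal = NA, skipped = FALSE, p_omnibus = NA_real_,
                    stringsAsFactors = FALSE)
  for (pn in pair_names) out[[pn]] <- NA_real_
  for (i in seq_along(fcols)) {
    x <- features[[fcols[i]]]
    ok <- is.finite(x)
    xi <- x[ok]; gi <- droplevels(grp[ok])
    if (length(unique(xi)) <= 1 || nlevels(gi) < 2 ||
        any(table(gi) < 3)) {
      out$skipped[i] <- TRUE
      next
    }
    normal <- all(vapply(levels(gi), function(g) {
      v <- xi[gi == g]
      if (length(unique(v)) < 2) return(FALSE)
      p <- if (length(v) >= 5) nortest::lillie.test(v)$p.value
           else suppressWarnings(
             stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
      p >= normal_alpha
    }, logical(1)))
    out$normal[i] <- normal
    out$method[i] <- if (normal) "anova/t" else "kruskal/mann-whitney"
    if (nlevels(gi) >= 3) {
      out$p_omnibus[i] <- if (normal)
        summary(stats::aov(xi ~ gi))[[1]][["Pr(>F)"]][1]
      else stats::kruskal.test(xi, gi)$p.value
    }
    for (k in seq_along(pairs)) {
      a <- xi[gi == pairs[[k]][1]]; b <- xi[gi == pairs[[k]][2]]
      if (!length(a) || !length(b)) next
      out[[pair_names[k]]][i] <- if (normal)
        stats::t.test(a, b)$p.value
      else suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
  }
  if (adjust == "BH") {
    for (cn in c("p_omnibus", pair_names))
      out[[cn]] <- stats::p.adjust(out[[cn]], method = "BH")
  }
  out
}

#' Kendall correlations between features and covariates
#'
#' Tie-corrected Kendall's tau-b with its p-value for every
#' (feature, covariate) pair, across all subjects and, optionally, within
#' each group. Kendall's tau is used because it is robust to the extreme
#' values these motor features routinely produce. Constant vectors leave
#' tau undefined and are flagged.
#'
#' @param features feature table (`subject_id`, `group`, feature columns).
#' @param covariates data frame with `subject_id` and numeric covariate
#'   columns.
#' @param by_group also compute within-group correlations.
#' @return long data frame: `feature`, `covariate`, `scope` (`"all"` or a
#'   group label), `n`, `tau`, `p`, `flagged`.
#' @export
feature_covariate_correlations <- function(features, covariates,
                                           by_group = TRUE) {
  merged <- merge(features, covariates, by = "subject_id")
  fcols <- feature_cols(features)
  ccols <- setdiff(names(covariates), "subject_id")
  scopes <- c("all", if (by_group) unique(merged$group))
  out <- NULL
  for (sc in scopes) {
    sub <- if (sc == "all") merged else merged[merged$group == sc, ]
    for (fc in fcols) for (cc in ccols) {
      x <- sub[[fc]]; y <- sub[[cc]]
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      flagged <- n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2
      if (flagged) {
        tau <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = "kendall", exact = FALSE))
        tau <- unname(ct$estimate); p <- ct$p.value
      }
      out <- rbind(out, data.frame(feature = fc, covariate = cc,
                                   scope = sc, n = n, tau = tau, p = p,
                                   flagged = flagged))
    }
  }
  rownames(out) <- NULL
  out
}
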