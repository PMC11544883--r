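#' @include AllClasses.R
NULL

safeShapiro <- function(x) {
  if (length(x) < 3L || length(unique(x)) == 1L) return(0)
  if (length(x) > 5000L) x <- sample(x, 5000L)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Normality gate for test selection
#'
#' Shapiro-Wilk W test per group; the comparison is treated as parametric
#' only if every group passes at `alpha` (a conservative joint reading).
#' Groups smaller than 3 force the non-parametric branch with a warning.
#'
#' @param groups list of numeric vectors.
#' @param alpha gate level (default 0.05).
#' @return list: `parametric` flag and `shapiroP` per group.
#' @export
gateNormality <- function(groups, alpha = 0.05) {
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    warning("group with fewer than 3 observations: non-parametric tests used")
    return(list(parametric = FALSE,
                shapiroP = rep(NA_real_, length(groups))))
  }
  p <- vapply(groups, safeShapiro, numeric(1))
  list(parametric = all(p >= alpha), shapiroP = p)
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic `G = max|x - mean| / sd` with the closed-form
#' critical value from the t distribution. Outliers are reported, never
#' removed.
#'
#' @param x numeric vector (n >= 3).
#' @param alpha significance level (default 0.05).
#' @return list: `G`, `critical`, `outlier` flag, `value` (the extreme
#'   observation).
#' @export
grubbsTest <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0)
    return(list(G = NA_real_, critical = NA_real_, outlier = FALSE,
                value = NA_real_))
  dev <- abs(x - mean(x))
  G <- max(dev) / stats::sd(x)
  tq <- stats::qt(1 - alpha / (2 * n), n - 2L)
  crit <- (n - 1L) / sqrt(n) * sqrt(tq^2 / (n - 2L + tq^2))
  list(G = G, critical = crit, outlier = G > crit,
       value = x[which.max(dev)])
}

levenePValue <- function(x, y) {
  df <- data.frame(v = c(x, y),
                   g = factor(rep(c("a", "b"), c(length(x), length(y)))))
  tryCatch(car::leveneTest(v ~ g, data = df)[1L, "Pr(>F)"],
           error = function(e) NA_real_)
}

#' Gated two-group comparison
#'
#' Compares two groups of biomarker medians with the test selected by the
#' normality gate: unpaired comparisons use the unpaired t-test or the
#' Mann-Whitney U test; paired comparisons the paired t-test or the
#' Wilcoxon signed-rank test (the paired analogue of the rank test).
#' Paired comparisons use pairwise deletion of missing data. For unpaired
#' parametric runs, homogeneity of variances (Levene) and single-outlier
#' (Grubbs) diagnostics are attached; outliers are flagged, not removed.
#' Fully tied rank tests report p = 1.
#'
#' @param x,y numeric vectors; for `paired = TRUE` they must be aligned
#'   observations of the same subjects.
#' @param paired logical.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: `test`, `statistic`, `p`, `parametric`,
#'   `shapiroP1`, `shapiroP2`, `leveneP`, `grubbsOutlier`, `n1`, `n2`,
#'   `significant`.
#' @export
compareGroups <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (paired) {
    ok <- is.finite(x) & is.finite(y)      # pairwise deletion
    x <- x[ok]; y <- y[ok]
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
  }
  if (!length(x) || !length(y)) stop("empty group")
  gate <- withCallingHandlers(
    gateNormality(list(x, y), alpha),
    warning = function(w) invokeRestart("muffleWarning"))
  leveneP <- NA_real_
  grubbs <- FALSE
  parametric <- gate$parametric
  if (parametric) {
    if (paired) {
      ht <- tryCatch(stats::t.test(x, y, paired = TRUE),
                     error = function(e) NULL)   # constant differences
      test <- "paired t-test"
    } else {
      leveneP <- levenePValue(x, y)
      grubbs <- grubbsTest(x, alpha)$outlier || grubbsTest(y, alpha)$outlier
      ht <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                     error = function(e) NULL)
      test <- "unpaired t-test"
    }
    if (is.null(ht)) parametric <- FALSE
    else { stat <- unname(ht$statistic); p <- ht$p.value }
  }
  if (!parametric) {
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
    ht <- tryCatch(
      suppressWarnings(stats::wilcox.test(x, y, paired = paired)),
      error = function(e) NULL)
    if (is.null(ht) || is.na(ht$p.value)) {       # all ties / zero diffs
      stat <- NA_real_; p <- 1
    } else {
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  }
  data.frame(test = test, statistic = stat, p = p,
             parametric = parametric,
             shapiroP1 = gate$shapiroP[1L], shapiroP2 = gate$shapiroP[2L],
             leveneP = leveneP, grubbsOutlier = grubbs,
             n1 = length(x), n2 = length(y),
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Spearman correlation against a covariate
#'
#' Spearman rank-order correlation of biomarker medians against a
#' per-specimen covariate (age in years, or time from specimen arrival to
#' imaging in minutes).
#'
#' @param values biomarker medians.
#' @param covariate matched covariate values.
#' @param minN minimum paired observations (default 5).
#' @return list: `rho`, `p`, `n`.
#' @export
correlateCovariate <- function(values, covariate, minN = 5L) {
  ok <- is.finite(values) & is.finite(covariate)
  v <- values[ok]; cv <- covariate[ok]
  if (length(v) < minN) stop("fewer than ", minN, " paired observations")
  if (stats::sd(v) == 0 || stats::sd(cv) == 0) {
    warning("constant input: correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(v)))
  }
  ct <- suppressWarnings(stats::cor.test(v, cv, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(v))
}

#' Bilateral percentage differences
#'
#' Mean percentage difference between left and right fallopian-tube
#' biomarker medians in paired specimens: per pair
#' `100 * |L - R| / ((L + R) / 2)` (symmetric in L/R), averaged over pairs.
#' Pairs with a missing side are dropped (pairwise deletion); pairs with
#' `L + R = 0` are skipped.
#'
#' @param tbl data.frame with columns `patient`, `side` (`"left"` /
#'   `"right"`), `site`, `biomarker`, `value`.
#' @return data.frame: `site`, `biomarker`, `meanPctDiff`, `nPairs`.
#' @export
bilateralDiff <- function(tbl) {
  stopifnot(all(c("patient", "side", "site", "biomarker", "value") %in%
                names(tbl)))
  out <- list()
  for (site in unique(tbl$site)) {
    for (bm in unique(tbl$biomarker)) {
      sub <- tbl[tbl$site == site & tbl$biomarker == bm, ]
      pts <- unique(sub$patient)
      L <- sub$value[sub$side == "left"][match(pts, sub$patient[sub$side == "left"])]
      R <- sub$value[sub$side == "right"][match(pts, sub$patient[sub$side == "right"])]
      ok <- is.finite(L) & is.finite(R) & (L + R) != 0
      if (!any(ok)) next
      pct <- 100 * abs(L[ok] - R[ok]) / ((L[ok] + R[ok]) / 2)
      out[[length(out) + 1L]] <- data.frame(
        site = site, biomarker = bm, meanPctDiff = mean(pct),
        nPairs = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(site = character(), biomarker = character(),
                      meanPctDiff = numeric(), nPairs = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the full statistical battery on a cohort table
#'
#' Applies the standard question set to a cohort of per-volume biomarker
#' medians: (1) disease state across volumes (unpaired); (2) lesion vs
#' non-lesion areas within lesion-containing volumes (paired by specimen);
#' (3) pairwise region comparisons in volumes without a lesion (paired);
#' (4) left vs right tubes in patients with paired imaging (paired by
#' patient); (5, 6) Spearman correlations of non-lesion volume medians
#' against age and time-to-imaging. Questions lacking the needed columns
#' or groups are skipped. No multiple-comparison correction is applied.
#'
#' @param cohort data.frame with columns `specimen`, `biomarker`, `scope`,
#'   `level`, `median`, and per-specimen metadata columns `diseaseState`
#'   (`"lesion"`/`"no_lesion"`), `patient`, `side`, `age`,
#'   `timeToImaging` (any of the metadata may be absent).
#' @param alpha significance level (default 0.05).
#' @return data.frame of results, one row per (question, biomarker[,
#'   contrast]).
#' @export
runStatsBattery <- function(cohort, alpha = 0.05) {
  res <- list()
  add <- function(question, biomarker, contrast, row) {
    res[[length(res) + 1L]] <<- cbind(
      data.frame(question = question, biomarker = biomarker,
                 contrast = contrast, stringsAsFactors = FALSE), row)
  }
  whole <- cohort[cohort$scope == "whole", ]
  bms <- unique(cohort$biomarker)

  if ("diseaseState" %in% names(whole) &&
      length(unique(whole$diseaseState)) == 2L) {
    for (bm in bms) {
      sub <- whole[whole$biomarker == bm, ]
      g <- split(sub$median, sub$diseaseState)
      if (any(lengths(g) == 0L)) next
      add("disease_state", bm, paste(names(g), collapse = " vs "),
          compareGroups(g[[1L]], g[[2L]], paired = FALSE, alpha = alpha))
    }
  }

  diag <- cohort[cohort$scope == "diagnosis", ]
  if (nrow(diag)) {
    for (bm in bms) {
      sub <- diag[diag$biomarker == bm, ]
      sp <- intersect(sub$specimen[sub$level == "lesion"],
                      sub$specimen[sub$level == "no_lesion"])
      if (length(sp) < 2L) next
      L <- sub$median[sub$level == "lesion"][
        match(sp, sub$specimen[sub$level == "lesion"])]
      NL <- sub$median[sub$level == "no_lesion"][
        match(sp, sub$specimen[sub$level == "no_lesion"])]
      add("lesion_vs_nonlesion", bm, "lesion vs no_lesion",
          compareGroups(L, NL, paired = TRUE, alpha = alpha))
    }
  }

  reg <- cohort[cohort$scope == "region", ]
  if ("diseaseState" %in% names(reg))
    reg <- reg[reg$diseaseState == "no_lesion", ]
  if (nrow(reg)) {
    regions <- intersect(c("isthmus", "ampulla", "fimbriae"),
                         unique(reg$level))
    if (length(regions) >= 2L) {
      prs <- utils::combn(regions, 2L, simplify = FALSE)
      for (bm in bms) {
        sub <- reg[reg$biomarker == bm, ]
        for (pr in prs) {
          sp <- intersect(sub$specimen[sub$level == pr[1L]],
                          sub$specimen[sub$level == pr[2L]])
          if (length(sp) < 2L) next
          a <- sub$median[sub$level == pr[1L]][
            match(sp, sub$specimen[sub$level == pr[1L]])]
          b <- sub$median[sub$level == pr[2L]][
            match(sp, sub$specimen[sub$level == pr[2L]])]
          add("region", bm, paste(pr, collapse = " vs "),
              compareGroups(a, b, paired = TRUE, alpha = alpha))
        }
      }
    }
  }

  if (all(c("patient", "side") %in% names(whole))) {
    for (bm in bms) {
      sub <- whole[whole$biomarker == bm, ]
      pts <- intersect(sub$patient[sub$side == "left"],
                       sub$patient[sub$side == "right"])
      if (length(pts) < 2L) next
      L <- sub$median[sub$side == "left"][
        match(pts, sub$patient[sub$side == "left"])]
      R <- sub$median[sub$side == "right"][
        match(pts, sub$patient[sub$side == "right"])]
      add("left_right", bm, "left vs right",
          compareGroups(L, R, paired = TRUE, alpha = alpha))
    }
  }

  for (cov in c("age", "timeToImaging")) {
    if (!cov %in% names(whole)) next
    noLesion <- if ("diseaseState" %in% names(whole))
      whole[whole$diseaseState == "no_lesion", ] else whole
    for (bm in bms) {
      sub <- noLesion[noLesion$biomarker == bm, ]
      if (sum(is.finite(sub$median) & is.finite(sub[[cov]])) < 5L) next
      ct <- correlateCovariate(sub$median, sub[[cov]])
      add(cov, bm, "",
          data.frame(test = "Spearman rank-order", statistic = ct$rho,
                     p = ct$p, parametric = FALSE, shapiroP1 = NA_real_,
                     shapiroP2 = NA_real_, leveneP = NA_real_,
                     grubbsOutlier = FALSE, n1 = ct$n, n2 = ct$n,
                     significant = is.finite(ct$p) && ct$p < alpha,
                     stringsAsFactors = FALSE))
    }
  }
  if (!length(res)) return(data.frame())
  do.call(rbind, res)
}
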