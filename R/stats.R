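#' Significance stars
#'
#' The reporting convention used throughout the cohort tables:
#' \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05, empty
#' otherwise.
#'
#' @param p p-values in [0, 1] (NA allowed).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  out <- ifelse(is.na(p), "",
                ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  as.character(out)
}

#' Bonferroni adjustment for m planned comparisons
#'
#' @param p raw p-values.
#' @param m number of planned comparisons.
#' @return \code{pmin(p * m, 1)}.
#' @export
bonferroni_adjust <- function(p, m) pmin(p * m, 1)

#' Percent change of a test mean relative to a reference mean
#'
#' \eqn{100 (test - reference)/reference}; reported values are rounded to
#' the nearest integer percent, half away from zero.
#'
#' @param reference reference mean (non-zero).
#' @param test test mean.
#' @param round_pct round to the nearest percent (default TRUE).
#' @return Percent change.
#' @export
#' @examples
#' percent_change(100, 57)  # -43
percent_change <- function(reference, test, round_pct = TRUE) {
  if (any(reference == 0)) stop("reference mean must be non-zero")
  pc <- 100 * (test - reference) / reference
  if (round_pct) sign(pc) * floor(abs(pc) + 0.5) else pc
}

#' Group comparisons in the cohort-report style
#'
#' Computes per-group means +/- SEM and the test the source tables use:
#' classic (equal-variance) Student t-tests, paired t-tests, or one-/two-way
#' ANOVA with Bonferroni-adjusted pairwise contrasts against the reference
#' (first) group.  Star annotations follow [significance_stars()] applied
#' to the adjusted p-value.
#'
#' @param data data frame in tidy form.
#' @param response name of the response column.
#' @param group name of the grouping column; its first unique value is the
#'   reference group.
#' @param test one of \code{"t_unpaired"}, \code{"t_paired"},
#'   \code{"anova1_bonferroni"}, \code{"anova2_bonferroni"}.
#' @param group2 second factor column (required for
#'   \code{"anova2_bonferroni"}; contrasts are computed within each of its
#'   levels).
#' @param paired_by unit-identifier column for \code{"t_paired"}.
#' @param m_comparisons number of planned comparisons for the Bonferroni
#'   adjustment; defaults to the number of contrasts performed.
#' @return Data frame of class \code{"group_comparison"}: one row per
#'   contrast with \code{mean_ref}, \code{sem_ref}, \code{mean_test},
#'   \code{sem_test}, \code{statistic}, \code{p_value}, \code{p_adjusted},
#'   \code{stars} and \code{zero_variance}.  For the two-way ANOVA the
#'   term-level F tests are attached as attribute \code{"anova_terms"}.
#' @export
compare_groups <- function(data, response, group,
                           test = c("t_unpaired", "t_paired",
                                    "anova1_bonferroni", "anova2_bonferroni"),
                           group2 = NULL, paired_by = NULL,
                           m_comparisons = NULL) {
  test <- match.arg(test)
  y <- data[[response]]
  g <- factor(data[[group]], levels = unique(data[[group]]))
  lev <- levels(g)
  msem <- function(v) c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  contrast_row <- function(ref_lab, test_lab, stat, p, zv = FALSE) {
    a <- msem(y[g == ref_lab]); b <- msem(y[g == test_lab])
    data.frame(reference = ref_lab, test_group = test_lab,
               mean_ref = a["mean"], sem_ref = a["sem"],
               mean_test = b["mean"], sem_test = b["sem"],
               statistic = stat, p_value = p, row.names = NULL,
               zero_variance = zv)
  }

  anova_terms <- NULL
  if (test %in% c("t_unpaired", "t_paired")) {
    if (length(lev) != 2L) stop("t-tests require exactly 2 groups")
    ya <- y[g == lev[1]]; yb <- y[g == lev[2]]
    if (min(length(ya), length(yb)) < 2L)
      stop("need at least 2 observations per group")
    if (test == "t_paired") {
      if (is.null(paired_by)) stop("paired t-test needs 'paired_by'")
      ids <- data[[paired_by]]
      ida <- ids[g == lev[1]]; idb <- ids[g == lev[2]]
      yb <- yb[match(ida, idb)]
      if (anyNA(yb)) stop("paired_by identifiers do not match across groups")
      diffs <- ya - yb
      if (stats::sd(diffs) == 0) {
        rows <- contrast_row(lev[1], lev[2], NA_real_, NA_real_, zv = TRUE)
      } else {
        tt <- stats::t.test(ya, yb, paired = TRUE)
        rows <- contrast_row(lev[1], lev[2], unname(tt$statistic), tt$p.value)
      }
    } else {
      if (stats::sd(ya) == 0 && stats::sd(yb) == 0) {
        rows <- contrast_row(lev[1], lev[2], NA_real_, NA_real_, zv = TRUE)
      } else {
        tt <- stats::t.test(ya, yb, var.equal = TRUE)
        rows <- contrast_row(lev[1], lev[2], unname(tt$statistic), tt$p.value)
      }
    }
  } else if (test == "anova1_bonferroni") {
    if (length(lev) < 2L) stop("ANOVA requires at least 2 groups")
    fit <- stats::aov(y ~ g)
    anova_terms <- summary(fit)[[1]]
    rows <- do.call(rbind, lapply(lev[-1], function(l) {
      ya <- y[g == lev[1]]; yb <- y[g == l]
      tt <- stats::t.test(ya, yb, var.equal = TRUE)
      contrast_row(lev[1], l, unname(tt$statistic), tt$p.value)
    }))
  } else {
    if (is.null(group2)) stop("two-way ANOVA needs 'group2'")
    g2 <- factor(data[[group2]], levels = unique(data[[group2]]))
    fit <- stats::aov(y ~ g * g2)
    anova_terms <- summary(fit)[[1]]
    rows <- do.call(rbind, lapply(levels(g2), function(l2) {
      sub <- g2 == l2
      do.call(rbind, lapply(lev[-1], function(l) {
        ya <- y[sub & g == lev[1]]; yb <- y[sub & g == l]
        tt <- stats::t.test(ya, yb, var.equal = TRUE)
        r <- contrast_row(lev[1], l, unname(tt$statistic), tt$p.value)
        # recompute strata means on the subset
        r$mean_ref <- mean(ya); r$sem_ref <- stats::sd(ya) / sqrt(length(ya))
        r$mean_test <- mean(yb); r$sem_test <- stats::sd(yb) / sqrt(length(yb))
        r$stratum <- l2
        r
      }))
    }))
  }
  m <- if (is.null(m_comparisons)) nrow(rows) else m_comparisons
  rows$p_adjusted <- bonferroni_adjust(rows$p_value, m)
  rows$stars <- significance_stars(rows$p_adjusted)
  attr(rows, "anova_terms") <- anova_terms
  attr(rows, "test") <- test
  class(rows) <- c("group_comparison", "data.frame")
  rows
}

#' Assemble a machine-readable cohort report
#'
#' Merges named module outputs into one report structure with per-section
#' provenance and renders deterministic JSON (fixed key order, fixed digit
#' handling), so re-running with the same inputs yields byte-identical
#' output.
#'
#' @param sections named list of module outputs (data frames, lists of
#'   scalars, or objects with an \code{unclass}-able list structure).
#' @param config optional configuration list echoed into the report.
#' @return Object of class \code{"cohort_report"}: list with
#'   \code{sections}, \code{provenance} (section name -> originating
#'   operation, taken from each element's \code{"operation"} attribute or
#'   its class) and \code{json} (the serialized report string).
#' @export
build_report <- function(sections, config = list()) {
  if (length(sections) == 0L) stop("at least one module output is required")
  if (is.null(names(sections)) || any(names(sections) == ""))
    stop("sections must be named")
  provenance <- vapply(sections, function(s) {
    op <- attr(s, "operation")
    if (!is.null(op)) op else class(s)[1]
  }, character(1))
  plain <- lapply(sections, function(s) {
    if (is.data.frame(s)) s else
      lapply(unclass(s), function(el) if (is.function(el)) NULL else el)
  })
  body <- list(sections = plain, provenance = as.list(provenance),
               config = config)
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = 10,
                           null = "null", force = TRUE)
  structure(list(sections = sections, provenance = provenance,
                 config = config, json = as.character(json)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort report with sections:\n")
  for (nm in names(x$sections))
    cat(sprintf("  %s  (from %s)\n", nm, x$provenance[[nm]]))
  invisible(x)
}
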