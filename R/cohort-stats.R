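#' Flag low-binder donors
#'
#' A donor is a "low binder" when end-point surface coverage stays below 1%
#' at each of 150, 300 and 750 1/s. The highest shear rate (1500 1/s) is
#' excluded from the rule because average coverage there is close to 1% even
#' in normal responders. The classification is idempotent and independent of
#' row order.
#'
#' @param table Cohort table (one row per donor x shear rate) with columns
#'   `donor_id`, `shear_rate`, `sc_end`.
#' @param required_shears Shear rates the rule is evaluated at.
#' @param threshold Coverage threshold, percent.
#' @return `table` with a logical `low_binder` column added (or replaced).
#' @export
classify_low_binders <- function(table,
                                 required_shears = c(150, 300, 750),
                                 threshold = 1.0) {
  stopifnot(is.data.frame(table),
            all(c("donor_id", "shear_rate", "sc_end") %in% names(table)))
  flags <- table |>
    dplyr::filter(.data$shear_rate %in% required_shears) |>
    dplyr::summarise(
      n_shears = dplyr::n_distinct(.data$shear_rate),
      low_binder = all(.data$sc_end < threshold),
      .by = "donor_id")
  missing <- flags$donor_id[flags$n_shears < length(required_shears)]
  covered <- unique(table$donor_id)
  missing <- union(missing, setdiff(covered, flags$donor_id))
  if (length(missing))
    stop("donors missing required shear rates: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  table$low_binder <- NULL
  dplyr::left_join(table, flags[c("donor_id", "low_binder")],
                   by = "donor_id")
}

#' Covariate-quartile summary of surface coverage
#'
#' Donors are binned into quartiles of a numeric covariate (edges at the
#' 25/50/75th percentiles, lower-inclusive so ties go to the lower quartile)
#' and the mean and standard error of an outcome are reported per quartile
#' per shear rate — the standard display of how, e.g., plasma VWF level
#' stratifies platelet accumulation.
#'
#' @param table Cohort table with `donor_id`, `shear_rate` and the columns
#'   named below.
#' @param covariate Name of the numeric covariate (default `"vwf_level"`).
#' @param outcome Name of the numeric outcome (default `"sc_end"`).
#' @return A tibble: `shear_rate`, `quartile` (factor Q1-Q4), `n`, `mean`,
#'   `se`.
#' @export
quartile_summary <- function(table, covariate = "vwf_level",
                             outcome = "sc_end") {
  stopifnot(is.data.frame(table),
            covariate %in% names(table), outcome %in% names(table))
  x <- table[[covariate]]
  if (!is.numeric(x))
    stop("covariate must be numeric", call. = FALSE)
  donors <- unique(table[c("donor_id", covariate)])
  if (length(unique(donors[[covariate]])) < 4)
    stop("covariate needs at least 4 distinct values across donors",
         call. = FALSE)
  edges <- quantile(donors[[covariate]], c(0.25, 0.5, 0.75),
                    names = FALSE, type = 7)
  assign_q <- function(v) 1L + findInterval(v, edges, left.open = TRUE)
  table$.q <- factor(paste0("Q", assign_q(table[[covariate]])),
                     levels = paste0("Q", 1:4))
  table |>
    dplyr::filter(!is.na(.data[[outcome]])) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[outcome]]),
      se = sd(.data[[outcome]]) / sqrt(dplyr::n()),
      .by = c("shear_rate", ".q")) |>
    dplyr::rename(quartile = ".q") |>
    dplyr::arrange(.data$shear_rate, .data$quartile)
}

.mw_test <- function(y, g) {
  groups <- split(y, g)
  n1 <- length(groups[[1]]); n2 <- length(groups[[2]])
  if (all(y == y[1]))  # every observation tied: no evidence of a difference
    return(list(statistic = n1 * n2 / 2, p = 1))
  exact <- n1 <= 8 && n2 <= 8 && !any(duplicated(y))
  wt <- suppressWarnings(
    wilcox.test(groups[[1]], groups[[2]], exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Cohort association test battery
#'
#' For each outcome at each shear rate, runs the nonparametric battery used
#' for flow-assay cohorts, all two-sided:
#' \itemize{
#'   \item Spearman rank correlation for numeric covariates;
#'   \item Mann-Whitney U for two-level categorical covariates (exact
#'     enumeration when both groups have <= 8 untied observations, otherwise
#'     the tie-corrected normal approximation);
#'   \item Kruskal-Wallis for categorical covariates with 3+ levels,
#'     followed by Tukey HSD pairwise comparisons (on rank-transformed data
#'     by default, switchable to the raw scale);
#'   \item optionally, two-way ANOVA interaction p-values for pairs of
#'     categorical covariates.
#' }
#' Rows whose outcome is undefined (runs that never exceeded 1% coverage
#' have no lag or velocity) are dropped per outcome. Tests with fewer than
#' two observations in a group are skipped and logged. P-values are reported
#' raw (no multiplicity correction), with optional Benjamini-Hochberg via
#' `p_adjust = "BH"`.
#'
#' @param table Cohort table (one row per donor x shear rate).
#' @param outcomes Outcome columns to test.
#' @param covariates Covariate columns (numeric -> Spearman; character or
#'   factor -> rank tests).
#' @param interactions Optional list of 2-element character vectors of
#'   categorical covariates for two-way ANOVA interaction tests.
#' @param tukey_on Scale for Tukey HSD after Kruskal-Wallis: `"ranks"`
#'   (default) or `"raw"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A tibble: `outcome`, `shear_rate`, `covariate`, `test`,
#'   `statistic`, `estimate` (Spearman rho where applicable), `p_value`,
#'   `note`. Skipped tests appear with `NA` statistics and the reason in
#'   `note`.
#' @export
association_tests <- function(table,
                              outcomes = c("sc_end", "lag_time_s",
                                           "v_plt_pct_per_s"),
                              covariates = c("vwf_level", "hematocrit",
                                             "platelet_count", "sex",
                                             "gp6_genotype"),
                              interactions = NULL,
                              tukey_on = c("ranks", "raw"),
                              p_adjust = c("none", "BH")) {
  stopifnot(is.data.frame(table), "shear_rate" %in% names(table))
  tukey_on <- match.arg(tukey_on)
  p_adjust <- match.arg(p_adjust)
  miss <- setdiff(c(outcomes, covariates, unlist(interactions)), names(table))
  if (length(miss))
    stop("columns not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- tibble::tibble(...)
  for (sr in sort(unique(table$shear_rate))) {
    sub_all <- table[table$shear_rate == sr, , drop = FALSE]
    for (oc in outcomes) {
      sub <- sub_all[!is.na(sub_all[[oc]]), , drop = FALSE]
      y <- sub[[oc]]
      for (cv in covariates) {
        x <- sub[[cv]]
        if (is.numeric(x)) {
          if (length(y) < 3) {
            add(outcome = oc, shear_rate = sr, covariate = cv,
                test = "spearman", statistic = NA_real_,
                estimate = NA_real_, p_value = NA_real_,
                note = "skipped: fewer than 3 observations")
            next
          }
          ct <- suppressWarnings(
            cor.test(x, y, method = "spearman", exact = FALSE))
          add(outcome = oc, shear_rate = sr, covariate = cv,
              test = "spearman", statistic = unname(ct$statistic),
              estimate = unname(ct$estimate), p_value = ct$p.value,
              note = NA_character_)
        } else {
          g <- factor(x)
          sizes <- table(g[!is.na(y)])
          if (any(sizes < 2) || nlevels(g) < 2) {
            add(outcome = oc, shear_rate = sr, covariate = cv,
                test = if (nlevels(g) <= 2) "mann_whitney"
                       else "kruskal_wallis",
                statistic = NA_real_, estimate = NA_real_,
                p_value = NA_real_,
                note = "skipped: a group has fewer than 2 observations")
            next
          }
          if (nlevels(g) == 2L) {
            mw <- .mw_test(y, g)
            add(outcome = oc, shear_rate = sr, covariate = cv,
                test = "mann_whitney", statistic = mw$statistic,
                estimate = NA_real_, p_value = mw$p,
                note = NA_character_)
          } else {
            kw <- kruskal.test(y, g)
            add(outcome = oc, shear_rate = sr, covariate = cv,
                test = "kruskal_wallis", statistic = unname(kw$statistic),
                estimate = NA_real_, p_value = kw$p.value,
                note = NA_character_)
            yy <- if (tukey_on == "ranks") rank(y) else y
            tk <- TukeyHSD(aov(yy ~ g))$g
            for (pair in rownames(tk))
              add(outcome = oc, shear_rate = sr,
                  covariate = paste0(cv, ":", pair),
                  test = paste0("tukey_hsd_", tukey_on),
                  statistic = tk[pair, "diff"], estimate = NA_real_,
                  p_value = tk[pair, "p adj"], note = NA_character_)
          }
        }
      }
      for (ia in interactions) {
        a <- factor(sub[[ia[1]]]); b <- factor(sub[[ia[2]]])
        ok <- complete.cases(y, a, b)
        if (nlevels(droplevels(a[ok])) < 2 || nlevels(droplevels(b[ok])) < 2 ||
            sum(ok) < 4) {
          add(outcome = oc, shear_rate = sr,
              covariate = paste(ia, collapse = "*"),
              test = "two_way_anova_interaction", statistic = NA_real_,
              estimate = NA_real_, p_value = NA_real_,
              note = "skipped: not enough levels or observations")
          next
        }
        fit <- aov(y[ok] ~ a[ok] * b[ok])
        tab <- summary(fit)[[1]]
        irow <- grep(":", rownames(tab))
        pv <- if (length(irow)) tab[irow[1], "Pr(>F)"] else NA_real_
        add(outcome = oc, shear_rate = sr,
            covariate = paste(ia, collapse = "*"),
            test = "two_way_anova_interaction",
            statistic = if (length(irow)) tab[irow[1], "F value"]
                        else NA_real_,
            estimate = NA_real_, p_value = pv,
            note = if (length(irow)) NA_character_
                   else "interaction not estimable")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (p_adjust == "BH")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
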