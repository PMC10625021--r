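#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic sum((O - E)^2 / E) on a contingency table with
#' expected counts from the product of margins; df = (r-1)(c-1), p from
#' the upper chi-square tail.  No continuity correction (matching how
#' large claims tables are tested).
#'
#' @param counts contingency table (matrix of non-negative counts).
#' @return list(statistic, df, p_value, expected).
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal row/column in contingency table")
  expected <- outer(rs, cs) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' One-way analysis of variance
#'
#' F = between-group mean square / within-group mean square, with
#' df1 = g - 1 and df2 = n - g; p from the upper F tail.  Size-one groups
#' contribute to the between sum of squares and are absorbed by the pooled
#' residual.  When all values are identical, F = 0 and p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 distinct groups).
#' @return list(F, df1, df2, p_value).
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  g <- nlevels(droplevels(groups))
  n <- length(values)
  if (g < 2L) stop("need at least 2 groups")
  if (n - g < 1L) stop("need at least 1 residual degree of freedom")
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- g - 1L; df2 <- n - g
  if (ssw == 0 && ssb == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p_value = 1))
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Charlson comorbidity category
#'
#' Weighted sum of comorbidity flags binned into the four categories used
#' in claims descriptive tables: 0, 1-2, 3-4, >=5.  The weight table is
#' configuration: supply one weight per flag (classic 1987-style integer
#' weights by default for the generator's flag set; illustrative, since
#' the flags here are simplified condition groups).
#'
#' @param flags named logical/0-1 vector (or data.frame of such columns)
#'   of comorbidity indicators.
#' @param weights named numeric vector mapping every flag to its weight.
#' @return factor with levels \code{"0", "1-2", "3-4", ">=5"}.
#' @export
charlson_category <- function(flags, weights = default_charlson_weights()) {
  if (is.data.frame(flags)) flags <- as.matrix(flags)
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L,
                                           dimnames = list(NULL, names(flags)))
  missing_w <- setdiff(colnames(flags), names(weights))
  if (length(missing_w) > 0L)
    stop("no Charlson weight for flag(s): ", paste(missing_w, collapse = ", "))
  score <- as.vector(flags %*% weights[colnames(flags)])
  cut(score, breaks = c(-Inf, 0.5, 2.5, 4.5, Inf),
      labels = c("0", "1-2", "3-4", ">=5"))
}

#' @rdname charlson_category
#' @export
default_charlson_weights <- function() {
  c(undernutrition = 1, morbid_obesity = 0, sleep_apnoea = 0,
    hypertension_cvd = 1, diabetes = 1, psychiatric = 1)
}

#' Describe one profiling variable
#'
#' @param variable display name.
#' @param kind "categorical" or "continuous".
#' @param source where values come from: a covariate column name, or
#'   \code{"event:<type>"} to count that event type per patient in the
#'   pre-index window.
#' @param breaks for categorical variables built from counts: right-closed
#'   bin edges (e.g. \code{c(-1, 0, 2, 5, 10, 20, Inf)} for the
#'   0 / 1-2 / 3-5 / 6-10 / 11-20 / >20 consultation bins); NULL to use
#'   the observed levels.
#' @param labels optional bin labels.
#' @return a \code{profile_spec} list.
#' @export
profile_spec <- function(variable, kind = c("categorical", "continuous"),
                         source = variable, breaks = NULL, labels = NULL) {
  kind <- match.arg(kind)
  structure(list(variable = variable, kind = kind, source = source,
                 breaks = breaks, labels = labels), class = "profile_spec")
}

profile_values <- function(spec, covariates, events) {
  src <- spec$source
  if (startsWith(src, "event:")) {
    type <- sub("^event:", "", src)
    cnt <- table(factor(events$patient_id[events$event_type == type],
                        levels = covariates$patient_id))
    v <- as.integer(cnt)
  } else {
    if (!src %in% colnames(covariates))
      stop("profile spec references missing column: ", src)
    v <- covariates[[src]]
  }
  if (spec$kind == "categorical" && !is.null(spec$breaks)) {
    v <- cut(v, breaks = spec$breaks, labels = spec$labels)
  } else if (spec$kind == "categorical") {
    v <- factor(v)
  }
  v
}

#' Stratified descriptive profile of clusters
#'
#' Builds the familiar by-cluster descriptive table: for categorical
#' variables, count and percentage per cluster plus a chi-square test
#' across clusters; for continuous variables, median and interquartile
#' range per cluster plus a one-way ANOVA.  Percentages are carried at
#' full precision in \code{pct} and rounded half-up to integers in
#' \code{pct_display}, matching how such tables are printed.
#'
#' @param covariates covariate table (one row per patient).
#' @param events long event table (used by \code{"event:"} sources).
#' @param labels cluster label per covariate row.
#' @param specs list of [profile_spec()] objects.
#' @param p_adjust "none" (default) or "BH" for Benjamini-Hochberg across
#'   the profiled variables.
#' @return data.frame in long form: variable, level (or statistic name),
#'   cluster ("all" plus 1..C), n, pct, pct_display (categorical) or
#'   median, q1, q3 (continuous), with per-variable test statistic, df and
#'   p-value repeated on each row.
#' @export
profile_clusters <- function(covariates, events, labels, specs,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (length(labels) != nrow(covariates))
    stop("labels must cover all patients")
  cl <- factor(labels)
  out <- list()
  for (spec in specs) {
    v <- profile_values(spec, covariates, events)
    if (spec$kind == "categorical") {
      tab <- table(v, cl)
      # empty bins or empty clusters carry no information for the test but
      # stay in the descriptive output
      test_tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      tst <- if (all(dim(test_tab) >= 2)) chi_square(test_tab) else
        list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
      for (grp in c("all", levels(cl))) {
        cnt <- if (grp == "all") rowSums(tab) else tab[, grp]
        tot <- sum(cnt)
        out[[length(out) + 1L]] <- data.frame(
          variable = spec$variable, level = rownames(tab), cluster = grp,
          n = as.integer(cnt), pct = 100 * cnt / tot,
          pct_display = round_half_up(100 * cnt / tot),
          statistic = tst$statistic, df = tst$df, p_value = tst$p_value,
          stringsAsFactors = FALSE)
      }
    } else {
      tst <- one_way_anova(v, cl)
      for (grp in c("all", levels(cl))) {
        x <- if (grp == "all") v else v[cl == grp]
        qs <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          variable = spec$variable, level = "median_iqr", cluster = grp,
          n = length(x), median = qs[[2]], q1 = qs[[1]], q3 = qs[[3]],
          statistic = tst$F, df = tst$df1, p_value = tst$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, lapply(out, function(d) {
    for (col in c("pct", "pct_display", "median", "q1", "q3"))
      if (is.null(d[[col]])) d[[col]] <- NA_real_
    if (is.null(d$n)) d$n <- NA_integer_
    d[, c("variable", "level", "cluster", "n", "pct", "pct_display",
          "median", "q1", "q3", "statistic", "df", "p_value")]
  }))
  rownames(res) <- NULL
  if (p_adjust == "BH") {
    pv <- tapply(res$p_value, res$variable, function(p) p[1])
    adj <- stats::p.adjust(pv, method = "BH")
    res$p_adjusted <- adj[res$variable]
  }
  res
}
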