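#' Two-way ANCOVA with Type III sums of squares
#'
#' Fits the group-difference model for one TE outcome: sex and
#' family-history group (FH+ vs FH-; FH+/- subjects are dropped from all
#' categorical models) as factors with their interaction as the effect of
#' interest, plus covariates (age, race/ethnicity, income, parental
#' education, parental mental health, prenatal exposure, scanner model,
#' in-scanner motion, pubertal stage) and the two additional interactions
#' sex x puberty and FH x income. Categorical predictors use sum-to-zero
#' contrasts and each term is tested by Type III (partial) sums of squares;
#' effect sizes are partial eta squared. Ordinal covariates enter as
#' numeric scores. Rows with missing values are dropped with a logged
#' count.
#'
#' @param data data.frame joining covariates and one outcome column.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names; the
#'   default matches the study protocol.
#' @param interactions additional interaction terms beyond sex:fh_group.
#' @return data.frame of class `ancova_result` with one row per term:
#'   `term`, `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`, and attribute
#'   `n_dropped`.
#' @export
fit_ancova <- function(data, outcome,
                       covariates = c("age_months", "race_ethnicity",
                                      "income_level", "parental_education",
                                      "parental_mental_health",
                                      "prenatal_exposure", "scanner_model",
                                      "mean_fd", "puberty_stage"),
                       interactions = c("sex:puberty_stage",
                                        "fh_group:income_level")) {
  stopifnot(outcome %in% names(data))
  data <- data[data$fh_group %in% c("FH+", "FH-"), , drop = FALSE]
  covariates <- intersect(covariates, names(data))
  used <- unique(c(outcome, "sex", "fh_group", covariates))
  complete <- stats::complete.cases(data[, used])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L)
    message("fit_ancova: dropped ", n_dropped, " row(s) with missing values")
  d <- data[complete, , drop = FALSE]
  d$sex <- factor(d$sex)
  d$fh_group <- factor(d$fh_group)
  if (any(table(d$sex, d$fh_group) < 2L))
    stop("need at least 2 subjects per sex x FH cell")
  for (v in covariates)
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  rhs <- paste(c("sex * fh_group", covariates, interactions),
               collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  contrasts_list <- list()
  for (v in all.vars(form)[-1L])
    if (is.factor(d[[v]])) contrasts_list[[v]] <- "contr.sum"
  mm <- stats::model.matrix(form, data = d,
                            contrasts.arg = contrasts_list)
  y <- d[[outcome]]
  qr_full <- qr(mm)
  if (qr_full$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_full$pivot[(qr_full$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit_full <- stats::lm.fit(mm, y)
  rss_full <- sum(fit_full$residuals^2)
  df_den <- nrow(mm) - ncol(mm)
  term_labels <- attr(stats::terms(form), "term.labels")
  asgn <- attr(mm, "assign")
  degenerate <- rss_full <= 1e-12 * max(1, sum(y^2))
  if (degenerate)
    warning("outcome is (numerically) perfectly fit; all F set to 0")
  res <- lapply(seq_along(term_labels), function(i) {
    cols <- which(asgn == i)
    red <- stats::lm.fit(mm[, -cols, drop = FALSE], y)
    ss <- max(sum(red$residuals^2) - rss_full, 0)
    df_num <- length(cols)
    Fval <- if (degenerate) 0 else (ss / df_num) / (rss_full / df_den)
    data.frame(term = term_labels[i],
               F = Fval,
               df_num = df_num, df_den = df_den,
               p = stats::pf(Fval, df_num, df_den, lower.tail = FALSE),
               partial_eta_sq = if (ss + rss_full > 0)
                 ss / (ss + rss_full) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_used") <- nrow(d)
  class(out) <- c("ancova_result", "data.frame")
  out
}

#' Post-hoc FH+ vs FH- t-tests within each sex
#'
#' Classic pooled-variance, unpaired, two-sided t-tests (Welch available
#' via `welch = TRUE`) comparing FH+ against FH- separately within females
#' and males, with Cohen's d (pooled SD). The sign convention is
#' first-listed minus second: positive t and d mean FH+ > FH-.
#'
#' @param data data.frame with `sex`, `fh_group` and the outcome.
#' @param outcome outcome column name.
#' @param welch use Welch's unequal-variance t-test.
#' @return data.frame with one row per sex: `contrast`, `sex`, `t`, `df`,
#'   `p`, `cohens_d`, `n_fh_pos`, `n_fh_neg`.
#' @export
posthoc_within_sex <- function(data, outcome, welch = FALSE) {
  stopifnot(outcome %in% names(data))
  data <- data[data$fh_group %in% c("FH+", "FH-"), , drop = FALSE]
  res <- lapply(sort(unique(data$sex)), function(sx) {
    d <- data[data$sex == sx, , drop = FALSE]
    g1 <- d[[outcome]][d$fh_group == "FH+"]
    g2 <- d[[outcome]][d$fh_group == "FH-"]
    if (length(g1) < 2L || length(g2) < 2L)
      stop("fewer than 2 subjects in an FH group for sex = ", sx)
    tt <- stats::t.test(g1, g2, var.equal = !welch)
    sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                  (length(g2) - 1) * stats::var(g2)) /
                 (length(g1) + length(g2) - 2))
    data.frame(contrast = "FH+ vs FH-", sex = sx,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               cohens_d = (mean(g1) - mean(g2)) / sp,
               n_fh_pos = length(g1), n_fh_neg = length(g2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Spearman correlation between a TE outcome and family-history density
#'
#' Rank correlation (average ranks for ties, two-sided asymptotic p) of an
#' outcome with the continuous FHD score across all three FH groups —
#' FH+/- subjects, excluded from categorical models, are included here.
#'
#' @param data data.frame with `fhd` and the outcome (and `sex` when
#'   stratifying).
#' @param outcome outcome column name.
#' @param stratify_by_sex compute one correlation per sex.
#' @return data.frame with `stratum`, `spearman_rho`, `p`, `n`.
#' @export
spearman_fhd <- function(data, outcome, stratify_by_sex = FALSE) {
  stopifnot(outcome %in% names(data), "fhd" %in% names(data))
  strata <- if (stratify_by_sex) split(data, data$sex) else list(all = data)
  res <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) < 3L) stop("fewer than 3 subjects in stratum ", nm)
    if (stats::sd(d[[outcome]]) == 0)
      stop("constant outcome in stratum ", nm, "; rho undefined")
    ct <- suppressWarnings(
      stats::cor.test(d[[outcome]], d$fhd, method = "spearman",
                      exact = FALSE))
    data.frame(stratum = nm, spearman_rho = unname(ct$estimate),
               p = ct$p.value, n = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg FDR adjustment within families of tests
#'
#' Step-up BH adjustment applied separately within each family (e.g. the 9
#' network means form one family, the 86 regional means another).
#'
#' @param p numeric p-values in [0, 1].
#' @param q FDR level for the rejection flags (default 0.05).
#' @param family optional grouping vector; `NULL` = one family.
#' @return data.frame with `p`, `family`, `p_fdr`, `reject`.
#' @export
bh_fdr <- function(p, q = 0.05, family = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(family)) family <- rep("all", length(p))
  stopifnot(length(family) == length(p))
  p_fdr <- numeric(length(p))
  for (f in unique(family)) {
    i <- family == f
    p_fdr[i] <- stats::p.adjust(p[i], method = "BH")
  }
  data.frame(p = p, family = family, p_fdr = p_fdr, reject = p_fdr <= q)
}
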