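#' Survey-weighted prevalence with a design-based confidence interval
#'
#' Point estimate is the Hajek ratio `sum(w*y)/sum(w)`. The variance is
#' estimated by Taylor linearization over the stratified cluster design
#' (strata and primary sampling units taken from the `stratum` and `psu`
#' columns), and the confidence interval is a logit-transformed Wald
#' interval back-transformed to the proportion scale, which keeps it inside
#' `[0, 1]` — the convention of DHS-style survey software. With equal
#' weights the estimate reproduces the unweighted proportion exactly.
#'
#' @param data a `survey_dataset` or a data.frame with columns
#'   `outcome`-like binary variable, `weight`, `stratum`, `psu`.
#' @param outcome_col name of the binary outcome column.
#' @param conf_level confidence level (default 0.95).
#' @param single_psu how to handle a stratum with a single PSU:
#'   `"fail"` (error naming the stratum; the variance is undefined) or
#'   `"certainty"` (treat the unit as sampled with certainty: it
#'   contributes no between-PSU variance).
#' @return An object of class `prevalence_estimate`: list with `proportion`,
#'   `ci_low`, `ci_high`, `se`, `n` (unweighted count), `method`.
#' @export
weighted_prevalence <- function(data, outcome_col = "outcome",
                                conf_level = 0.95,
                                single_psu = c("fail", "certainty")) {
  single_psu <- match.arg(single_psu)
  rec <- as_records(data)
  y <- rec[[outcome_col]]
  if (is.null(y)) stop("no column '", outcome_col, "'")
  keep <- !is.na(y)
  if (sum(!keep) > 0) message("dropping ", sum(!keep), " records with missing outcome")
  rec <- rec[keep, , drop = FALSE]
  y <- as.numeric(rec[[outcome_col]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  w <- rec$weight
  if (is.null(w)) w <- rep(1, length(y))
  if (any(w <= 0)) stop("weights must be positive")
  n <- length(y)
  W <- sum(w)
  p <- sum(w * y) / W
  v <- taylor_var_ratio_mean(y, w, rec$stratum, rec$psu, single_psu)
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (p <= 0 || p >= 1 || se == 0) {
    ci <- c(p, p)
    if (se > 0) warning("degenerate proportion; CI collapsed to the estimate")
  } else {
    l <- stats::qlogis(p)
    se_l <- se / (p * (1 - p))
    ci <- stats::plogis(l + c(-1, 1) * z * se_l)
  }
  structure(list(proportion = p, ci_low = ci[1], ci_high = ci[2], se = se,
                 n = n, method = "taylor-linearization, logit-Wald CI"),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("prevalence %.3f (95%% CI %.3f-%.3f), n = %d [%s]\n",
              x$proportion, x$ci_low, x$ci_high, x$n, x$method))
  invisible(x)
}

# Taylor-linearized variance of the weighted mean (Hajek ratio) of y under
# a stratified cluster design. u_i = w_i (y_i - p) / sum(w); PSU totals are
# contrasted within strata with the n_h/(n_h - 1) factor.
taylor_var_ratio_mean <- function(y, w, stratum, psu, single_psu = "fail") {
  if (is.null(stratum)) stratum <- rep(1L, length(y))
  if (is.null(psu)) psu <- seq_along(y)
  W <- sum(w)
  p <- sum(w * y) / W
  u <- w * (y - p) / W
  v <- 0
  for (h in unique(stratum)) {
    sel <- stratum == h
    z_hc <- tapply(u[sel], psu[sel], sum)
    nh <- length(z_hc)
    if (nh < 2) {
      if (single_psu == "fail") {
        stop("stratum '", h, "' has a single PSU; variance undefined ",
             "(use single_psu = \"certainty\" to treat it as a certainty unit)")
      }
      next
    }
    v <- v + nh / (nh - 1) * sum((z_hc - mean(z_hc))^2)
  }
  v
}

# design effect of a weighted proportion of the indicator y, with the
# simple-random-sampling reference variance p(1-p)/(n-1) so that the
# trivial design (equal weights, one PSU per record, one stratum) gives
# deff = 1 exactly
prop_deff <- function(ind, w, stratum, psu, single_psu) {
  n <- length(ind)
  p <- sum(w * ind) / sum(w)
  v_des <- taylor_var_ratio_mean(ind, w, stratum, psu, single_psu)
  v_srs <- p * (1 - p) / (n - 1)
  if (v_srs == 0) return(1)
  v_des / v_srs
}

#' Design-based (Rao-Scott first-order) chi-square test
#'
#' Pearson's chi-square computed on the survey-weighted contingency table of
#' outcome by factor, corrected for the sampling design by the first-order
#' Rao-Scott adjustment: the statistic is divided by a generalized design
#' effect built from Taylor-linearized design effects of the cell and
#' marginal proportions, and referred to the usual chi-square distribution
#' with `(R-1)(C-1)` degrees of freedom. Under a trivial design (equal
#' weights, one PSU per observation, single stratum) the corrected statistic
#' equals the classical Pearson chi-square exactly.
#'
#' @param data a `survey_dataset` or data.frame of records.
#' @param outcome_col,factor_col column names; the factor needs at least 2
#'   observed levels.
#' @param single_psu see [weighted_prevalence()].
#' @return list with `statistic` (corrected X^2), `pearson` (uncorrected,
#'   design-weighted), `delta_bar` (generalized design effect), `df`,
#'   `p_value`, `table` (weighted counts), `method`.
#' @export
design_chisq <- function(data, outcome_col = "outcome", factor_col,
                         single_psu = c("fail", "certainty")) {
  single_psu <- match.arg(single_psu)
  rec <- as_records(data)
  y <- rec[[outcome_col]]; f <- rec[[factor_col]]
  if (is.null(y) || is.null(f)) stop("missing outcome or factor column")
  keep <- !is.na(y) & !is.na(f)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " records with missing values")
    rec <- rec[keep, , drop = FALSE]
    y <- rec[[outcome_col]]; f <- rec[[factor_col]]
  }
  w <- rec$weight; if (is.null(w)) w <- rep(1, length(y))
  y <- factor(y); f <- factor(f)
  if (nlevels(f) < 2 || nlevels(y) < 2) {
    stop("degenerate table: factor or outcome has fewer than 2 observed levels")
  }
  n <- length(y)
  tw <- tapply(w, list(y, f), sum)
  tw[is.na(tw)] <- 0
  if (any(rowSums(tw) == 0) || any(colSums(tw) == 0)) {
    stop("degenerate table: empty row or column after weighting")
  }
  P <- tw / sum(tw)
  pr <- rowSums(P); pc <- colSums(P)
  E <- outer(pr, pc)
  X2 <- n * sum((P - E)^2 / E)
  R <- nrow(P); C <- ncol(P)
  df <- (R - 1) * (C - 1)
  # first-order Rao-Scott generalized design effect
  dd <- function(ind) prop_deff(ind, w, rec$stratum, rec$psu, single_psu)
  d_cell <- matrix(0, R, C)
  for (r in seq_len(R)) for (c in seq_len(C)) {
    d_cell[r, c] <- dd(as.numeric(y == levels(y)[r] & f == levels(f)[c]))
  }
  d_row <- vapply(levels(y), function(l) dd(as.numeric(y == l)), 0)
  d_col <- vapply(levels(f), function(l) dd(as.numeric(f == l)), 0)
  delta_bar <- (sum(d_cell * (1 - P)) - sum(d_row * (1 - pr)) -
                  sum(d_col * (1 - pc))) / df
  if (!is.finite(delta_bar) || delta_bar <= 0) delta_bar <- 1
  stat <- X2 / delta_bar
  list(statistic = stat, pearson = X2, delta_bar = delta_bar, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), table = tw,
       method = "Rao-Scott first-order corrected Pearson chi-square")
}

#' Conventional maximum-likelihood logistic regression
#'
#' Fits a logistic model by iteratively reweighted least squares
#' (`stats::glm`, binomial family) with treatment contrasts (first factor
#' level = reference) and returns a tidy coefficient table with Wald
#' p-values and odds ratios. Listwise deletion of missing values is applied
#' with a message. Coefficients with `|estimate| > 15` on the logit scale
#' are flagged as likely separation.
#'
#' @param data a `survey_dataset` or data.frame.
#' @param outcome_col binary outcome column name.
#' @param covariates character vector of covariate column names.
#' @return data.frame with columns `term`, `covariate`, `estimate`,
#'   `std_error`, `z`, `p_value`, `or`, `separation_flag`; the fitted `glm`
#'   object is attached as attribute `"fit"`.
#' @export
fit_logistic_ml <- function(data, outcome_col = "outcome", covariates) {
  rec <- as_records(data)
  stopifnot(length(covariates) >= 1)
  cols <- c(outcome_col, covariates)
  miss <- setdiff(cols, names(rec))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- rec[, cols, drop = FALSE]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message("listwise deletion: dropping ", sum(!cc), " records")
  d <- d[cc, , drop = FALSE]
  for (v in covariates) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  constant <- vapply(covariates, function(v) length(unique(d[[v]])) < 2, TRUE)
  if (any(constant)) {
    stop("rank deficiency: constant covariate(s): ",
         paste(covariates[constant], collapse = ", "))
  }
  form <- stats::reformulate(covariates, response = outcome_col)
  fit <- stats::glm(form, data = d, family = stats::binomial())
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank deficiency: collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  asg <- attr(stats::model.matrix(fit), "assign")
  covariate <- c("(Intercept)", covariates)[asg + 1L]
  sep <- abs(sm[, 1]) > 15
  if (any(sep)) {
    warning("possible separation: ",
            paste(rownames(sm)[sep], collapse = ", "))
  }
  out <- data.frame(term = rownames(sm), covariate = covariate,
                    estimate = sm[, 1], std_error = sm[, 2], z = sm[, 3],
                    p_value = sm[, 4], or = exp(sm[, 1]),
                    separation_flag = sep, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Screen covariates for the spatial model
#'
#' Fits the multivariable logistic model on all candidates and retains every
#' covariate whose minimum Wald p-value across its dummy levels is at most
#' `alpha` (default 0.2, the conventional liberal screening threshold).
#' Covariates in `always_keep` bypass the threshold (literature-informed
#' forcing). Univariate p-values are also computed and attached for
#' transparency.
#'
#' @param data a `survey_dataset` or data.frame.
#' @param outcome_col binary outcome column.
#' @param candidates character vector of candidate covariates (nonempty).
#' @param alpha screening threshold on the nominal p-value.
#' @param always_keep covariates retained regardless of p-value.
#' @return character vector of selected covariates (in candidate order),
#'   with attribute `"details"`: data.frame of per-covariate multivariable
#'   and univariate minimum p-values.
#' @export
screen_covariates <- function(data, outcome_col = "outcome", candidates,
                              alpha = 0.2, always_keep = character(0)) {
  stopifnot(length(candidates) >= 1)
  tab <- fit_logistic_ml(data, outcome_col, candidates)
  tab <- tab[tab$covariate != "(Intercept)", , drop = FALSE]
  pmin_multi <- vapply(candidates, function(v) {
    min(tab$p_value[tab$covariate == v])
  }, 0)
  pmin_uni <- vapply(candidates, function(v) {
    ut <- fit_logistic_ml(data, outcome_col, v)
    min(ut$p_value[ut$covariate == v])
  }, 0)
  sel <- candidates[pmin_multi <= alpha | candidates %in% always_keep]
  attr(sel, "details") <- data.frame(covariate = candidates,
                                     p_multivariable = pmin_multi,
                                     p_univariate = pmin_uni,
                                     selected = candidates %in% sel,
                                     row.names = NULL)
  sel
}
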