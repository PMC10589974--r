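# linear-predictor draws for a subset of retained draws (rows)
eta_draws <- function(fit, rows) {
  th <- fit$draws$theta[rows, , drop = FALSE]
  idx <- fit$param_index
  m <- fit$model
  eta <- th[, idx$fixed, drop = FALSE] %*% t(m$X)
  if (ncol(m$B)) {
    spl_cols <- unlist(idx$spline, use.names = FALSE)
    eta <- eta + th[, spl_cols, drop = FALSE] %*% t(m$B)
  }
  if (m$inc_str) eta <- eta + th[, idx$f_str, drop = FALSE][, m$dist_idx,
                                                           drop = FALSE]
  if (m$inc_unstr) eta <- eta + th[, idx$f_unstr, drop = FALSE][, m$dist_idx,
                                                                drop = FALSE]
  eta
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

bernoulli_deviance <- function(y, eta) {
  # -2 * sum(y*eta - log(1+exp(eta)))
  -2 * (sum(y * eta) - sum(log1pexp(eta)))
}

#' Deviance information criterion
#'
#' `D(param) = -2 sum_i log Bernoulli(y_i | p_i)`; `DIC = Dbar + pD` with
#' `pD = Dbar - D(posterior mean)`, the posterior mean taken on the
#' linear-predictor scale. Lower DIC indicates the better-supported model;
#' `pD` is the effective number of parameters.
#'
#' @param fit a [fit_star()] result.
#' @param data ignored (the fit stores its data); accepted for call symmetry.
#' @param chunk draws processed per block (memory control).
#' @return list with `dic`, `pd`, `mean_deviance`, `deviance_at_mean`.
#' @export
compute_dic <- function(fit, data = NULL, chunk = 200) {
  stopifnot(inherits(fit, "star_fit"))
  y <- fit$model$y
  ndraw <- nrow(fit$draws$theta)
  n <- fit$model$n
  dev <- numeric(ndraw)
  eta_sum <- numeric(n)
  for (start in seq(1, ndraw, by = chunk)) {
    rows <- start:min(start + chunk - 1, ndraw)
    eta <- eta_draws(fit, rows)
    dev[rows] <- apply(eta, 1, function(e) bernoulli_deviance(y, e))
    eta_sum <- eta_sum + colSums(eta)
  }
  eta_bar <- eta_sum / ndraw
  dbar <- mean(dev)
  dhat <- bernoulli_deviance(y, eta_bar)
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, mean_deviance = dbar,
       deviance_at_mean = dhat)
}

#' Structured share of the spatial variance
#'
#' The convolution model splits the district effect into a structured
#' (CAR) and an unstructured (iid) component; the structured share is
#' `phi = v_str / (v_str + v_unstr)`. Given a fit, the point estimate uses
#' the posterior mean variance components and a credible interval is formed
#' from the per-draw shares. Scalar variance components can be supplied
#' directly instead of a fit.
#'
#' @param fit a `star_fit` with both spatial components, or a numeric
#'   scalar `v_str`.
#' @param v_unstr unstructured variance (when `fit` is a scalar).
#' @param conf_level credible level for the per-draw interval.
#' @return An object of class `variance_decomposition`: list with `v_str`,
#'   `v_unstr`, `phi_structured` (proportion), `phi_structured_pct` and
#'   `phi_unstructured_pct` (percentages rounded to 1 decimal), and for
#'   fits `ci_structured_pct` (equal-tailed per-draw interval).
#' @export
variance_decomposition <- function(fit, v_unstr = NULL, conf_level = 0.95) {
  ci <- NULL
  if (inherits(fit, "star_fit")) {
    tn <- colnames(fit$draws$tau2)
    if (!all(c("tau2_str", "tau2_unstr") %in% tn)) {
      stop("variance decomposition needs both spatial components in the fit")
    }
    ts <- fit$draws$tau2[, "tau2_str"]
    tu <- fit$draws$tau2[, "tau2_unstr"]
    v_str <- mean(ts); v_unstr <- mean(tu)
    phi_draws <- ts / (ts + tu)
    a <- (1 - conf_level) / 2
    ci <- 100 * unname(stats::quantile(phi_draws, c(a, 1 - a)))
  } else {
    v_str <- as.numeric(fit)
    if (is.null(v_unstr)) stop("supply v_unstr with a scalar v_str")
    stopifnot(v_str >= 0, v_unstr >= 0)
  }
  tot <- v_str + v_unstr
  if (tot == 0) {
    warning("both variance components are zero; share undefined")
    phi <- NA_real_
  } else {
    phi <- v_str / tot
  }
  structure(list(v_str = v_str, v_unstr = v_unstr, phi_structured = phi,
                 phi_structured_pct = round(100 * phi, 1),
                 phi_unstructured_pct = round(100 * (1 - phi), 1),
                 ci_structured_pct = ci),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("structured share: %.1f%% (v_str = %.4g, v_unstr = %.4g)\n",
              x$phi_structured_pct, x$v_str, x$v_unstr))
  if (!is.null(x$ci_structured_pct)) {
    cat(sprintf("  per-draw 95%% interval: %.1f%% - %.1f%%\n",
                x$ci_structured_pct[1], x$ci_structured_pct[2]))
  }
  invisible(x)
}

#' Adjusted odds ratio table
#'
#' One row per fixed-effect level: `aOR = exp(posterior mean coefficient)`
#' (mean posterior adjusted odds ratio) with equal-tailed credible bounds
#' `exp` of the coefficient quantiles. Reference levels are shown with
#' `aOR = 1` and no interval. Values are rounded to `digits` decimals.
#'
#' @param fit a `star_fit`.
#' @param conf_level credible level (default 0.95).
#' @param digits rounding for the returned table (default 2).
#' @return data.frame with columns `covariate`, `level`, `aor`, `ci_low`,
#'   `ci_high`, `reference`.
#' @export
posterior_odds_table <- function(fit, conf_level = 0.95, digits = 2) {
  stopifnot(inherits(fit, "star_fit"))
  m <- fit$model
  th <- fit$draws$theta[, fit$param_index$fixed, drop = FALSE]
  a <- (1 - conf_level) / 2
  rows <- list()
  for (ti in seq_along(m$fixed_terms)) {
    term <- m$fixed_terms[ti]
    lev <- m$xlevels[[term]]
    cols <- which(m$assign_x == ti)
    if (!is.null(lev)) {
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = term, level = lev[1], aor = 1, ci_low = NA_real_,
        ci_high = NA_real_, reference = TRUE, stringsAsFactors = FALSE)
    }
    for (k in seq_along(cols)) {
      d <- th[, cols[k]]
      lvl <- if (!is.null(lev)) lev[k + 1L] else colnames(th)[cols[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = term, level = lvl,
        aor = round(exp(mean(d)), digits),
        ci_low = round(exp(unname(stats::quantile(d, a))), digits),
        ci_high = round(exp(unname(stats::quantile(d, 1 - a))), digits),
        reference = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(covariate = character(0), level = character(0),
                      aor = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), reference = logical(0)))
  }
  do.call(rbind, rows)
}

#' District-level predicted prevalence and district-associated odds
#'
#' For each district: the mean over its individuals of the posterior mean of
#' `inverse-logit(eta)` (predicted prevalence adjusted for all model terms),
#' and the district-associated odds `exp(f_str + f_unstr)` (posterior means),
#' centred so the geometric mean across districts is 1. Districts with no
#' individuals get `NA` prevalence (flagged) but still report odds.
#'
#' @param fit a `star_fit` with a spatial term.
#' @param chunk draws processed per block.
#' @return data.frame with columns `district`, `n`, `prevalence`, `odds`,
#'   `f_str`, `f_unstr`.
#' @export
predicted_district_prevalence <- function(fit, chunk = 200) {
  stopifnot(inherits(fit, "star_fit"))
  m <- fit$model
  if (is.null(m$graph)) stop("fit has no spatial term")
  ndraw <- nrow(fit$draws$theta)
  pbar <- numeric(m$n)
  for (start in seq(1, ndraw, by = chunk)) {
    rows <- start:min(start + chunk - 1, ndraw)
    eta <- eta_draws(fit, rows)
    pbar <- pbar + colSums(stats::plogis(eta))
  }
  pbar <- pbar / ndraw
  J <- m$graph$n
  cnt <- tabulate(m$dist_idx, nbins = J)
  prev <- rep(NA_real_, J)
  agg <- tapply(pbar, m$dist_idx, mean)
  prev[as.integer(names(agg))] <- agg
  f_str <- if (m$inc_str) {
    colMeans(fit$draws$theta[, fit$param_index$f_str, drop = FALSE])
  } else rep(0, J)
  f_unstr <- if (m$inc_unstr) {
    colMeans(fit$draws$theta[, fit$param_index$f_unstr, drop = FALSE])
  } else rep(0, J)
  spat <- f_str + f_unstr
  odds <- exp(spat - mean(spat))  # geometric mean 1
  if (any(cnt == 0)) {
    warning("district(s) with no individuals: ",
            paste(m$graph$labels[cnt == 0], collapse = ", "))
  }
  data.frame(district = m$graph$labels, n = cnt, prevalence = prev,
             odds = odds, f_str = unname(f_str), f_unstr = unname(f_unstr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export raw posterior draws
#'
#' Writes all retained draws (location parameters and variance components)
#' to a columnar text file with a header naming each parameter, plus a
#' `chain` column.
#'
#' @param fit a `star_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "star_fit"))
  out <- data.frame(chain = fit$chain, fit$draws$theta, fit$draws$tau2,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Posterior smooth curve
#'
#' Evaluates the posterior of a fitted P-spline smooth on a grid (centred as
#' in the model: the smooth averages to zero over the estimation sample).
#'
#' @param fit a `star_fit`.
#' @param term smooth term name (defaults to the first).
#' @param newx evaluation points (default: 100-point grid over the data
#'   range).
#' @param conf_level credible level.
#' @return data.frame with columns `x`, `mean`, `lo`, `hi`.
#' @export
smooth_effect <- function(fit, term = NULL, newx = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "star_fit"))
  if (is.null(term)) term <- names(fit$model$spl_blocks)[1]
  bas <- fit$model$spl_blocks[[term]]
  if (is.null(bas)) stop("no smooth term '", term, "'")
  if (is.null(newx)) newx <- seq(bas$range[1], bas$range[2], length.out = 100)
  Bx <- eval_pspline_basis(bas, newx)
  g <- fit$draws$theta[, fit$param_index$spline[[term]], drop = FALSE]
  curves <- g %*% t(Bx)
  a <- (1 - conf_level) / 2
  qs <- apply(curves, 2, stats::quantile, probs = c(a, 1 - a))
  data.frame(x = newx, mean = colMeans(curves), lo = qs[1, ], hi = qs[2, ])
}
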