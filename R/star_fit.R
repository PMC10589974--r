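#' Model specification for the structured additive logistic regression
#'
#' Declares the terms of the Bernoulli-logit structured additive predictor:
#' an intercept (always present), categorical fixed effects (treatment
#' coding, first level = reference), P-spline smooths for continuous
#' covariates, and a spatial convolution term on districts — a spatially
#' structured intrinsic-CAR effect plus a spatially unstructured iid
#' Gaussian effect. Every variance component (one per smooth, one per
#' spatial component) carries an inverse-gamma `IG(a, b)` hyperprior;
#' the default `a = b = 0.001` is the historical default of the structured
#' additive regression software family. Fixed effects and the intercept get
#' independent `N(0, prior_var_fixed)` priors.
#'
#' @param fixed_terms character vector of categorical covariate names (may
#'   be empty for an intercept-only model).
#' @param smooth_terms smooth declarations: either a character vector of
#'   continuous covariate names (defaults: 20 knot segments, cubic,
#'   second-order penalty) or a named list of lists with elements `knots`,
#'   `degree`, `penalty_order`.
#' @param spatial_term `NULL`, or a list with `district` (column name),
#'   `graph` (a [district_graph()]), and logical `structured`,
#'   `unstructured` flags (both default `TRUE`).
#' @param hyper_a,hyper_b inverse-gamma hyperprior shape and scale (> 0).
#' @param prior_var_fixed prior variance of intercept and fixed effects on
#'   the log-odds scale.
#' @return an object of class `star_spec`.
#' @export
star_spec <- function(fixed_terms = character(0), smooth_terms = list(),
                      spatial_term = NULL, hyper_a = 0.001, hyper_b = 0.001,
                      prior_var_fixed = 100) {
  stopifnot(hyper_a > 0, hyper_b > 0, prior_var_fixed > 0)
  if (is.character(smooth_terms)) {
    smooth_terms <- stats::setNames(
      rep(list(list(knots = 20, degree = 3, penalty_order = 2)),
          length(smooth_terms)), smooth_terms)
  }
  for (nm in names(smooth_terms)) {
    st <- utils::modifyList(list(knots = 20, degree = 3, penalty_order = 2),
                            smooth_terms[[nm]])
    if (st$knots < st$penalty_order + 1) {
      stop("smooth '", nm, "': knots must be >= penalty_order + 1")
    }
    if (st$degree < 1) stop("smooth '", nm, "': degree must be >= 1")
    smooth_terms[[nm]] <- st
  }
  if (!is.null(spatial_term)) {
    spatial_term <- utils::modifyList(
      list(district = "district", structured = TRUE, unstructured = TRUE),
      spatial_term)
    if (!inherits(spatial_term$graph, "district_graph")) {
      stop("spatial_term$graph must be a district_graph")
    }
    if (!spatial_term$structured && !spatial_term$unstructured) {
      spatial_term <- NULL
    }
  }
  structure(list(fixed_terms = fixed_terms, smooth_terms = smooth_terms,
                 spatial_term = spatial_term, hyper_a = hyper_a,
                 hyper_b = hyper_b, prior_var_fixed = prior_var_fixed),
            class = "star_spec")
}

#' MCMC settings
#'
#' Defaults (12000 iterations, 2000 burn-in, thinning 10, 2 chains) are a
#' conservative choice for the data sizes this package targets; convergence
#' is reported via split-R-hat in the fit summaries.
#'
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param n_chains number of independent chains.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 12000, burn_in = 2000, thin = 10,
                        n_chains = 2, seed = 1L) {
  stopifnot(burn_in >= 0, burn_in < n_iter, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Draw Polya-Gamma variates
#'
#' Exact PG(1, z) draws by the alternating-series rejection sampler; the
#' latent-variable law of the logistic data augmentation. `E[PG(1,z)] =
#' tanh(z/2) / (2 z)`.
#'
#' @param n number of draws (ignored when `z` has length > 1).
#' @param z tilting parameter(s).
#' @return numeric vector of draws.
#' @export
rpg <- function(n, z = 0) {
  if (length(z) == 1) z <- rep(z, n)
  .rpg_cpp(as.numeric(z))
}

# number of connected components (BFS over the adjacency list)
n_components <- function(graph) {
  n <- graph$n
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0) {
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges[r, 1]; j <- graph$edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  comps
}

#' Fit the Bayesian structured additive logistic regression
#'
#' Gibbs sampler with Polya-Gamma data augmentation: (i) latent
#' `omega_i ~ PG(1, eta_i)`; (ii) a joint Gaussian update of all location
#' parameters (intercept, fixed effects, spline coefficients, structured and
#' unstructured district effects) from the full conditional precision
#' system; (iii) inverse-gamma updates of each variance component. The CAR
#' field and each spline block are centred to sum/average zero after every
#' sweep, with the offset absorbed into the intercept, which identifies them
#' against the intercept. Records are canonicalised by sorting before
#' sampling so posterior summaries are invariant to input row order.
#'
#' Survey weights are not used by default (the Bayesian model is fitted to
#' the sample as observed); `use_weights = TRUE` switches to a weighted
#' pseudo-likelihood in which record `i` contributes its log-likelihood
#' times `weight_i` (Polya-Gamma draws with non-integer shape are then taken
#' from a truncated sum-of-gammas representation).
#'
#' @param data a `survey_dataset` or data.frame of records.
#' @param spec a [star_spec()].
#' @param mcmc an [mcmc_config()].
#' @param outcome_col binary outcome column name.
#' @param use_weights logical; weighted pseudo-likelihood flag.
#' @return An object of class `star_fit` with elements `draws` (matrices
#'   `theta` — all location parameters — and `tau2`), `summaries` (posterior
#'   mean, sd, quantiles, ESS, split-R-hat per parameter), `chain`, `model`
#'   (design information), `spec`, `mcmc`, `diagnostics`.
#' @export
fit_star <- function(data, spec, mcmc = mcmc_config(),
                     outcome_col = "outcome", use_weights = FALSE) {
  stopifnot(inherits(spec, "star_spec"), inherits(mcmc, "mcmc_config"))
  rec <- as_records(data)
  dist_col <- if (!is.null(spec$spatial_term)) spec$spatial_term$district
  used <- c(outcome_col, spec$fixed_terms, names(spec$smooth_terms), dist_col,
            if (use_weights) "weight")
  missing_cols <- setdiff(used, names(rec))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  rec <- rec[, used, drop = FALSE]
  cc <- stats::complete.cases(rec)
  if (any(!cc)) {
    message("listwise deletion: dropping ", sum(!cc), " records")
    rec <- rec[cc, , drop = FALSE]
  }
  y <- rec[[outcome_col]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  # canonical row order: summaries invariant to input permutation
  ord <- do.call(order, unname(as.list(rec)))
  rec <- rec[ord, , drop = FALSE]
  y <- as.numeric(rec[[outcome_col]])
  n <- length(y)

  for (v in spec$fixed_terms) {
    if (is.character(rec[[v]]) || is.logical(rec[[v]])) {
      rec[[v]] <- factor(rec[[v]])
    }
  }
  X <- if (length(spec$fixed_terms)) {
    stats::model.matrix(stats::reformulate(spec$fixed_terms), data = rec)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  assign_x <- attr(X, "assign")
  xlevels <- lapply(rec[spec$fixed_terms], function(v) {
    if (is.factor(v)) levels(v) else NULL
  })

  spl_blocks <- list()
  B <- matrix(0, n, 0)
  spl_sizes <- integer(0); spl_ranks <- numeric(0)
  Kspl <- matrix(0, 0, 0)
  for (nm in names(spec$smooth_terms)) {
    st <- spec$smooth_terms[[nm]]
    bas <- build_pspline_basis(rec[[nm]], knots = st$knots,
                               degree = st$degree,
                               penalty_order = st$penalty_order)
    k <- ncol(bas$B)
    spl_blocks[[nm]] <- bas
    spl_sizes <- c(spl_sizes, k)
    spl_ranks <- c(spl_ranks, k - st$penalty_order)
    B <- cbind(B, bas$B)
    Kold <- Kspl
    Kspl <- matrix(0, nrow(Kold) + k, ncol(Kold) + k)
    if (nrow(Kold)) Kspl[seq_len(nrow(Kold)), seq_len(ncol(Kold))] <- Kold
    Kspl[nrow(Kold) + seq_len(k), ncol(Kold) + seq_len(k)] <- bas$penalty
  }

  inc_str <- FALSE; inc_unstr <- FALSE
  dist_idx <- integer(0); Kcar <- matrix(0, 0, 0); rank_car <- 0
  graph <- NULL
  if (!is.null(spec$spatial_term)) {
    graph <- spec$spatial_term$graph
    inc_str <- isTRUE(spec$spatial_term$structured)
    inc_unstr <- isTRUE(spec$spatial_term$unstructured)
    dist_idx <- match(as.character(rec[[dist_col]]), graph$labels)
    if (anyNA(dist_idx)) {
      bad <- unique(as.character(rec[[dist_col]])[is.na(dist_idx)])
      stop("district label(s) not in graph: ", paste(bad, collapse = ", "))
    }
    Kcar <- car_precision(graph)
    rank_car <- graph$n - n_components(graph)
  }
  w <- if (use_weights) as.numeric(rec$weight) else rep(1, n)
  if (use_weights && any(w <= 0)) stop("weights must be positive")

  theta_list <- list(); tau2_list <- list(); chain_id <- integer(0)
  n_div <- 0L
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    res <- .star_gibbs_cpp(y, w, use_weights, X, B, spl_sizes, Kspl,
                           spl_ranks,
                           if (length(dist_idx)) dist_idx - 1L else integer(0),
                           Kcar, rank_car, inc_str, inc_unstr,
                           spec$prior_var_fixed, spec$hyper_a, spec$hyper_b,
                           mcmc$n_iter, mcmc$burn_in, mcmc$thin)
    theta_list[[ch]] <- res$theta
    tau2 <- cbind(res$tau2_spline,
                  if (inc_str) res$tau2_str,
                  if (inc_unstr) res$tau2_unstr)
    tau2_list[[ch]] <- tau2
    chain_id <- c(chain_id, rep(ch, nrow(res$theta)))
    n_div <- n_div + res$n_divergent
  }
  theta <- do.call(rbind, theta_list)
  tau2 <- do.call(rbind, tau2_list)

  d_fix <- ncol(X); d_spl <- ncol(B)
  J <- if (!is.null(graph)) graph$n else 0L
  nm_theta <- colnames(X)
  idx <- list(fixed = seq_len(d_fix))
  pos <- d_fix
  for (nm in names(spl_blocks)) {
    k <- ncol(spl_blocks[[nm]]$B)
    idx$spline[[nm]] <- pos + seq_len(k)
    nm_theta <- c(nm_theta, sprintf("s(%s).%d", nm, seq_len(k)))
    pos <- pos + k
  }
  if (inc_str) {
    idx$f_str <- pos + seq_len(J)
    nm_theta <- c(nm_theta, paste0("f_str.", graph$labels))
    pos <- pos + J
  }
  if (inc_unstr) {
    idx$f_unstr <- pos + seq_len(J)
    nm_theta <- c(nm_theta, paste0("f_unstr.", graph$labels))
    pos <- pos + J
  }
  colnames(theta) <- nm_theta
  tau2_names <- c(if (length(spl_blocks)) paste0("tau2_spline_",
                                                 names(spl_blocks)),
                  if (inc_str) "tau2_str", if (inc_unstr) "tau2_unstr")
  if (ncol(tau2)) colnames(tau2) <- tau2_names

  if (n_div > 0) {
    warning(n_div, " Gibbs updates had |linear predictor| > 40 ",
            "(draws retained)")
  }

  all_draws <- cbind(theta, tau2)
  summaries <- summarize_draws(all_draws, chain_id)

  fit <- structure(list(
    draws = list(theta = theta, tau2 = tau2),
    chain = chain_id,
    param_index = idx,
    summaries = summaries,
    model = list(y = y, X = X, B = B, spl_blocks = spl_blocks,
                 dist_idx = dist_idx, graph = graph,
                 fixed_terms = spec$fixed_terms, assign_x = assign_x,
                 xlevels = xlevels, inc_str = inc_str,
                 inc_unstr = inc_unstr, n = n, order = ord,
                 outcome_col = outcome_col, use_weights = use_weights,
                 weights = w),
    spec = spec, mcmc = mcmc,
    diagnostics = list(n_divergent = n_div,
                       rhat_max = suppressWarnings(
                         max(summaries$rhat, na.rm = TRUE)))),
    class = "star_fit")
  fit
}

#' @export
print.star_fit <- function(x, ...) {
  cat("star_fit:", x$model$n, "records,",
      nrow(x$draws$theta), "retained draws over",
      x$mcmc$n_chains, "chain(s)\n")
  fx <- x$summaries[x$summaries$parameter %in%
                      colnames(x$draws$theta)[x$param_index$fixed], ]
  print(fx, digits = 3, row.names = FALSE)
  if (ncol(x$draws$tau2)) {
    tx <- x$summaries[x$summaries$parameter %in% colnames(x$draws$tau2), ]
    print(tx, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

# posterior summary table with ESS and split R-hat
summarize_draws <- function(draws, chain_id) {
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
             ess = apply(draws, 2, ess_chain),
             rhat = apply(draws, 2, split_rhat, chain_id = chain_id),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-based ESS with Geyer's initial positive sequence
#' truncation.
#'
#' @param x numeric vector of draws.
#' @return estimated effective sample size.
#' @export
ess_chain <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 250), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0; k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

# split R-hat over chains (each chain halved)
split_rhat <- function(x, chain_id) {
  pieces <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    v <- v[!is.na(v)]
    m <- length(v) %/% 2
    if (m < 2) return(NA_real_)
    pieces <- c(pieces, list(v[seq_len(m)], v[m + seq_len(m)]))
  }
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, stats::var, 0)
  m <- length(pieces); nn <- length(pieces[[1]])
  W <- mean(vars)
  Bv <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + Bv / nn) / W)
}
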