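#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `S0 = sum(W)`. The null expectation is `-1/(n-1)`. Significance is
#' assessed by random permutation of the values over the districts; the
#' p-value counts the observed statistic among the permuted ones,
#' `p = (1 + #{extreme}) / (n_perm + 1)`. Two-sided by default (extreme =
#' `|I*| >= |I|`); one-sided variants are computed and reported alongside.
#'
#' @param values numeric vector, one value per district (may be named by
#'   district label; names, if present, must match the graph).
#' @param graph a `district_graph` with `n >= 3`.
#' @param style weight style, see [moran_weights()].
#' @param n_perm number of permutations (values below 99 trigger a warning).
#' @param seed optional integer seed for the permutations.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`; selects which
#'   permutation p-value is reported as `p_value` (all three are returned).
#' @return An object of class `moran_result`: `statistic`,
#'   `expectation_null`, `p_value`, `alternative`, `p_two_sided`,
#'   `p_greater`, `p_less`, `n_perm`, `style`, `n`.
#' @export
global_moran <- function(values, graph, style = c("row_standardized", "binary"),
                         n_perm = 999, seed = NULL,
                         alternative = c("two.sided", "greater", "less")) {
  style <- match.arg(style)
  alternative <- match.arg(alternative)
  v <- align_district_values(values, graph)
  n <- graph$n
  if (n < 3) stop("global Moran's I needs at least 3 districts")
  if (diff(range(v)) == 0) stop("Moran's I undefined for constant values")
  if (n_perm < 99) warning("n_perm < 99 gives a coarse permutation p-value")
  W <- moran_weights(graph, style)
  S0 <- sum(W)
  I_of <- function(x) {
    z <- x - mean(x)
    (n / S0) * sum(z * (W %*% z)) / sum(z^2)
  }
  I <- I_of(v)
  if (!is.null(seed)) set.seed(seed)
  Iperm <- vapply(seq_len(n_perm), function(k) I_of(sample(v)), 0)
  p2 <- (1 + sum(abs(Iperm) >= abs(I))) / (n_perm + 1)
  pg <- (1 + sum(Iperm >= I)) / (n_perm + 1)
  pl <- (1 + sum(Iperm <= I)) / (n_perm + 1)
  p <- switch(alternative, two.sided = p2, greater = pg, less = pl)
  structure(list(statistic = I, expectation_null = -1 / (n - 1),
                 p_value = p, alternative = alternative, p_two_sided = p2,
                 p_greater = pg, p_less = pl, n_perm = n_perm,
                 style = style, n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g [%s, %d perms]\n",
              x$statistic, x$expectation_null, x$p_value, x$alternative,
              x$n_perm))
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation and cluster labels
#'
#' `I_i = z_i * sum_j w_ij z_j / (sum_k z_k^2 / n)` with `z` the deviations
#' from the mean. Each unit's p-value comes from conditional permutation:
#' unit i's value is held fixed while the remaining values are shuffled over
#' its neighbours. Units significant at `alpha` are labelled by their
#' Moran-scatter quadrant: HH (high surrounded by high), LL, HL (high
#' surrounded by low), LH; all others NS. Isolated districts get `I_i = 0`,
#' p-value 1, label NS.
#'
#' @inheritParams global_moran
#' @param alpha significance level for cluster labelling.
#' @return data.frame with columns `district`, `value`, `z`, `lag`,
#'   `local_i`, `p_value` (two-sided), `cluster`.
#' @export
local_moran <- function(values, graph, style = c("row_standardized", "binary"),
                        n_perm = 999, seed = NULL, alpha = 0.05) {
  style <- match.arg(style)
  v <- align_district_values(values, graph)
  n <- graph$n
  if (n < 3) stop("local Moran's I needs at least 3 districts")
  if (diff(range(v)) == 0) stop("Moran's I undefined for constant values")
  if (n_perm < 99) warning("n_perm < 99 gives a coarse permutation p-value")
  W <- moran_weights(graph, style)
  z <- v - mean(v)
  m2 <- sum(z^2) / n
  lag <- as.vector(W %*% z)
  Ii <- z * lag / m2
  deg <- graph_degrees(graph)
  if (!is.null(seed)) set.seed(seed)
  pvals <- rep(1, n)
  for (i in seq_len(n)) {
    if (deg[i] == 0) next
    wi <- W[i, ]
    nb <- which(wi > 0)
    zi_other <- z[-i]
    Istar <- vapply(seq_len(n_perm), function(k) {
      zs <- sample(zi_other, length(nb))
      z[i] * sum(wi[nb] * zs) / m2
    }, 0)
    pvals[i] <- (1 + sum(abs(Istar) >= abs(Ii[i]))) / (n_perm + 1)
  }
  cluster <- rep("NS", n)
  sig <- pvals <= alpha & deg > 0
  cluster[sig & z > 0 & lag > 0] <- "HH"
  cluster[sig & z < 0 & lag < 0] <- "LL"
  cluster[sig & z > 0 & lag < 0] <- "HL"
  cluster[sig & z < 0 & lag > 0] <- "LH"
  data.frame(district = graph$labels, value = v, z = z, lag = lag,
             local_i = Ii, p_value = pvals, cluster = cluster,
             row.names = NULL, stringsAsFactors = FALSE)
}

# align a per-district vector with the graph's label order
align_district_values <- function(values, graph) {
  if (!is.null(names(values))) {
    missing <- setdiff(graph$labels, names(values))
    extra <- setdiff(names(values), graph$labels)
    if (length(missing) || length(extra)) {
      stop("district mismatch; missing: ",
           paste(missing, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "))
    }
    values <- values[graph$labels]
  } else if (length(values) != graph$n) {
    stop("values length ", length(values), " != number of districts ",
         graph$n)
  }
  as.numeric(values)
}
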