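# shared fixtures built in code

quick_mcmc <- function(n_iter = 2000, burn_in = 500, thin = 2,
                       n_chains = 1, seed = 42) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
              n_chains = n_chains, seed = seed)
}

path_graph <- function(n, labels = sprintf("d%02d", seq_len(n))) {
  district_graph(labels, cbind(seq_len(n - 1), 2:n))
}

cycle_graph <- function(n) {
  district_graph(sprintf("c%02d", seq_len(n)),
                 rbind(cbind(seq_len(n - 1), 2:n), c(1L, n)))
}

random_graph <- function(n, p_edge = 0.3) {
  labels <- sprintf("d%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  district_graph(labels, pairs[keep, , drop = FALSE])
}

# a records data.frame for the printed 2x2 toy table
# [[10, 20], [5, 40]] (rows: outcome 1/0; cols: exposed yes/no)
toy_2x2_records <- function(a = 10, b = 20, c = 5, d = 40) {
  n <- a + b + c + d
  data.frame(
    outcome = c(rep(1, a + b), rep(0, c + d)),
    exposed = c(rep("yes", a), rep("no", b), rep("yes", c), rep("no", d)),
    weight = rep(1, n),
    stratum = rep(1L, n),
    psu = seq_len(n),
    stringsAsFactors = FALSE)
}
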