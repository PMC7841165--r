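# Shared fixture builders for the suite. Everything is generated in code;
# nothing is read from disk except through the package's own writers.

# A tiny deterministic two-group log2 matrix with named samples.
make_log_matrix <- function(n_genes = 50, n_per_group = 5, sd = 0.5,
                            seed = 42) {
  set.seed(seed)
  samples <- c(sprintf("case_%d", seq_len(n_per_group)),
               sprintf("control_%d", seq_len(n_per_group)))
  m <- matrix(rnorm(n_genes * length(samples), mean = 8, sd = sd),
              nrow = n_genes,
              dimnames = list(sprintf("G%05d", seq_len(n_genes)), samples))
  m
}

make_groups <- function(m) {
  setNames(ifelse(startsWith(colnames(m), "case"), "case", "control"),
           colnames(m))
}

# A fully analysed small cohort; cached per test file via local memoising.
quiet_run_de <- function(m, groups, cfg) {
  suppressMessages(suppressWarnings(run_de(m, groups, cfg)))
}

quiet_run_cohort <- function(...) {
  suppressMessages(suppressWarnings(run_cohort(...)))
}

# Independent brute-force upper-tail hypergeometric P(X >= k).
brute_hyper_tail <- function(k, K, n, N) {
  mn <- min(K, n)
  if (k > mn) return(0)
  sum(dhyper(max(k, 0):mn, K, N - K, n))
}
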