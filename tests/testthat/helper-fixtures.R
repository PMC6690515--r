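# shared fixtures: small deterministic datasets built in code

fixture_params <- param_table()

# one simulated dataset under the workhorse scenario (het_cs, rho = .3, n = 12)
fixture_scenario <- function(hypothesis = "null", n_per_group = 12,
                             truth = "het_cs", rho = 0.3, n_reps = 20,
                             base_seed = 20190801) {
  scenario(truth, n_per_group, rho, hypothesis,
           n_reps = n_reps, base_seed = base_seed)
}

fixture_dataset <- function(rep_index = 1, ...) {
  simulate_dataset(fixture_params, fixture_scenario(...), rep_index)
}

# tiny two-arm, two-subject toy with hand-checkable sums of squares
toy_two_arm <- function() {
  tibble::tibble(
    subject = rep(c("a1", "a2", "b1", "b2"), each = 1),
    treatment = factor(rep(c("A", "A", "B", "B"), each = 1)),
    time_index = 1L,
    week = 1L,
    response = c(0, 2, 4, 6)
  )
}

# balanced long dataset from an explicit response matrix (rows = subjects)
long_from_matrix <- function(y, group) {
  n_t <- ncol(y)
  tibble::tibble(
    subject = rep(sprintf("s%02d", seq_len(nrow(y))), each = n_t),
    treatment = factor(rep(group, each = n_t)),
    time_index = rep(seq_len(n_t), nrow(y)),
    week = rep(seq_len(n_t), nrow(y)),
    response = as.vector(t(y))
  )
}
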