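## Shared fixtures, built in code and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

fig1_scenario <- function() preset_scenarios("fig1")[[1]]

## Noiseless forward profiles of the natural-stoichiometry condition at
## omega = 1, 3, 10 rad/s, plus the underlying trajectory.
fig1_profiles <- function() {
  if (is.null(.fixture_env$fig1))
    .fixture_env$fig1 <- scenario_profiles(fig1_scenario())
  .fixture_env$fig1
}

fig1_params <- function() scenario_params(fig1_scenario())

## Brute-force run-length sums (independent oracles for the closed forms).
brute_interval_probability <- function(R, l_i, l_j, cap = 1e6) {
  m <- l_i:min(l_j - 1, cap)
  sum(R^(m - 1) * (1 - R)^2)
}

brute_bound_site_fraction <- function(R, l_i, l_j, cap = 1e6) {
  m <- l_i:min(l_j - 1, cap)
  sum(m * R^(m - 1) * (1 - R)^2)
}
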