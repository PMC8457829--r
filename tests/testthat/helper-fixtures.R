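# shared fixtures: parameter sets used across test files

# SDD parameters with a given lambda/L, in canonical units (lcell = kd = 1)
sdd_rel <- function(lam_rel, L = 1, lcell = L / 50, jin = 1, vcell = 1) {
  sdd_params(L = L, lcell = lcell, vcell = vcell,
             D = (lam_rel * L)^2, kd = 1, jin = jin)
}

# large-system fixture: L = 50 lambda
sdd_large <- function(lam = 1, jin = 1) {
  sdd_params(L = 50 * lam, lcell = 1, vcell = 1, D = lam^2, kd = 1, jin = jin)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
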