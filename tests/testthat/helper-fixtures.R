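# Small builders shared across test files.  All fixtures are constructed in
# code; nothing is read from disk unless a test writes it first.

# homogeneous proteome: one common speed, no degradation
uniformParams <- function(n = 5, k = 4.8e4, mR = 1.4e6, phi0 = 0.08) {
  ProteomeParams(k = rep(k, n), alpha = rep(0, n), mR = mR, phi0 = phi0)
}

# the parameter set used throughout the study conditions (yeast means)
studyParams <- function() {
  ProteomeParams(k = c(2.07e4, 4.8e4), alpha = c(4.83e-4, 1.1e-3),
                 mR = 1.4e6, phi0 = 0.08)
}

# environment with given chi_R and uniform non-ribosomal allocation
uniformEnv <- function(n, chiR = 0.3) {
  CellEnvironment(c(chiR, rep((1 - chiR) / (n - 1), n - 1)))
}

# random solvable instance: chi_R kept high enough that the ribosomal
# fraction can exceed phi0, so a steady state exists (low allocations are
# genuinely unsustainable and the solver correctly reports them)
solvableConfig <- function(nGenes, seed, ...) {
  ensembleConfig(nGenes = nGenes, seed = seed,
                 chiRRange = c(0.25, 0.45), ...)
}
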