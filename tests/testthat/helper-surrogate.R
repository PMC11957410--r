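# Expensive shared fixtures for the acceptance suite: the 200-spectrum
# training library and the trained surrogate. Built once per test run
# (about 11 minutes) and shared by the fidelity and recovery tests.

trained_surrogate <- function() {
  cached("surrogate", {
    lib <- cached("library200", make_library(200, grid_n = 64, n_real = 8,
                                             seed = 1))
    kan_train(kan_surrogate(seed = 1), lib, epochs = 1200, seed = 1)
  })
}

surrogate_library <- function() {
  trained_surrogate()
  cached("library200", stop("library not built"))
}
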