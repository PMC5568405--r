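# Run the whole suite even when several end-to-end checks fail: some
# stochastic claims are known to sit outside the model's measured behavior
# and must still be reported alongside the passing unit tests.
options(testthat.progress.max_fails = 10000L)
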