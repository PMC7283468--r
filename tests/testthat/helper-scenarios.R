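# Scaled-down study scenarios shared by the acceptance tests: one initialized
# cell reused across runs (initialization is condition-independent), two
# replicate seeds per scenario.

phase_runs <- function() memo("phase_runs", function() {
  p <- fixture_params()
  init <- fixture_init()
  run <- function(cnd, setup, hours, seed)
    simulate_cell(cnd, setup, duration = hours * 3600, seed = seed,
                  params = p, subdivision = 2L, save_every = 300,
                  state = init)
  list(
    collective = lapply(1:2, function(s)
      run(mm_condition(0.5, 5e-4), mm_setup(TRUE, TRUE), 3, s)),
    no_mech = lapply(1:2, function(s)
      run(mm_condition(1e-3, 5e-4), mm_setup(FALSE, FALSE), 2, s))
  )
})
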