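# One shared end-to-end fixture run: building it (simulation + pipeline) is
# the expensive part, the assertions spread over several files are cheap.
fixture_env <- new.env()

fixture_run <- function() {
  if (!is.null(fixture_env$res)) return(fixture_env)
  dir <- file.path(tempdir(), "exprgraph-fixture")
  sim <- simulate_inputs(fixture_spec(), dir = dir)
  cfg <- run_config("SYN1", sim$paths, file.path(dir, "out"),
                    hub_score_threshold = 0, seed = 11)
  fixture_env$dir <- dir
  fixture_env$sim <- sim
  fixture_env$cfg <- cfg
  fixture_env$res <- suppressMessages(run_pipeline(cfg))
  fixture_env
}
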