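# Session-level cache for the expensive fixtures (shock tuner, full study
# matrix) so every test file shares one computation.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

cached_healthy <- function() cached("healthy", make_healthy_patient())

cached_healthy_beat <- function()
  cached("healthy_beat", run_to_steady_state(cached_healthy()))

cached_cs <- function() cached("cs", make_cs_patient())

cached_cs_beat <- function()
  cached("cs_beat", run_to_steady_state(cached_cs()))

cached_report <- function()
  cached("report", run_study(cached_cs(), keep_beats = TRUE))

report_beat <- function(condition) {
  rep <- cached_report()
  rep$beats[[match(condition, rep$conditions$condition)]]
}
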