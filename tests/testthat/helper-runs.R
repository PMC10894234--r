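# Shared simulation cache: the expensive runs are generated once per test
# session and reused across test files.  All seeds are fixed.

run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- force(expr)
  run_cache[[key]]
}

# small open-field run used by several unit tests
mini_open <- function() cached_run("mini_open", run_simulation(
  beam_spec(), NULL, transport_config(n_histories = 4e5, seed = 101)))

mini_brass <- function() cached_run("mini_brass", run_simulation(
  beam_spec(), grid_spec("brass"),
  transport_config(n_histories = 4e5, seed = 102)))

# toy symmetric triangular depth curve peaking at 1.5 cm
triangle_curve <- function() {
  depth <- seq(0.1, 3.0, by = 0.2)
  tibble::tibble(depth = depth, value = 10 - abs(depth - 1.5))
}
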