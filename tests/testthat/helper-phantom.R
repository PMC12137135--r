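# Small, fast phantom configurations for unit tests: 48 x 48 grid, 1-min
# baseline, 3 min of light, 3 min of follow-up, with photobleaching scaled
# up so the high-fluence trough still falls inside the shortened light
# interval. Full study-condition fixtures (make_fixture defaults) are
# exercised in the acceptance tests.
small_args <- function(...) {
  utils::modifyList(
    list(h = 48L, w = 48L,
         timeline = pdt_timeline(0, 60, 240, 420),
         n_blobs = 8L,
         k_bleach = log(4) / (400 * 1.5),
         vaso_peak_min = 1.5, vaso_width_min = 0.4),
    list(...))
}

small_fixture <- function(case, seed = 1L, ...) {
  do.call(make_fixture, c(list(case = case, seed = seed), small_args(...)))
}
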