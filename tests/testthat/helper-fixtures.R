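# Shared fixtures: flat truth profiles and a rendered trial cache so multiple
# tests can reuse one expensive render.

flat_profiles <- function(hr = 66, pep = 80, lvet = 290, sv = 37.6,
                          hf = 6.35, map = 80, pupil = 3, len = 195) {
  list(hr = rep(hr, len), pep = rep(pep, len), lvet = rep(lvet, len),
       sv = rep(sv, len), hf = rep(hf, len), map = rep(map, len),
       pupil = rep(pupil, len))
}

noiseless <- function() list(ecg = 0, dzdt = 0, z0 = 0, bp = 0, pupil = 0)

.fixture_env <- new.env(parent = emptyenv())

rendered_trial <- function(key = "default", noise = NULL, seed = 11,
                           profiles = flat_profiles(), ...) {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  p <- make_default_protocol()
  beats <- simulate_beat_timeline(profiles, p, seed = seed)
  sig <- render_trial(beats, profiles, p,
                      noise = noise %||% default_render_noise(),
                      blink_rate = 0, seed = seed + 1, ...)
  .fixture_env[[key]] <- sig
  sig
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# match detected beats to truth rows by nearest R time
match_truth <- function(times, truth) {
  vapply(times, function(t) which.min(abs(truth$r_time - t)), integer(1))
}
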