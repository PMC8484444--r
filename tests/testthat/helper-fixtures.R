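# shared fixtures: constant-weather series and tiny lattices built in code

make_weather <- function(tmean, rh = 70, days = 30, start = "2001-01-01") {
  structure(
    data.frame(date = as.Date(start) + seq_len(days) - 1L,
               tmax = tmean + 5, tmin = tmean - 5,
               tmean = tmean, rh = rh),
    class = c("weather_series", "data.frame"),
    cell_id = "fixture", provenance = "fixture")
}

all_species <- function() lapply(tephrisim::list_species(), tephrisim::load_species)

# pulse of `n` individuals placed in age class 1 at t = 0
pulse_state <- function(stage, n = 1000) {
  s <- tephrisim::new_stage_state(stage)
  s$densities[1] <- n
  s
}
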