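test_that("erlang_stats gives mean delta and SD delta/sqrt(k)", {
  expect_equal(erlang_stats(128, 25), c(mean = 128, sd = 25.6))
  expect_equal(erlang_stats(128, 40), c(mean = 128, sd = 20.23858),
               tolerance = 1e-6)
  expect_equal(erlang_stats(128, 1), c(mean = 128, sd = 128))
})

test_that("step_stage conserves mass with zero mortality", {
  md <- load_species("medfly")
  st <- pulse_state(md$stages$pupa, 1000)
  dx <- dev_increment(25, md$stages$pupa)
  total_out <- 0
  s <- st
  for (d in 1:60) {
    r <- step_stage(s, dx, mu = 0)
    s <- r$state
    total_out <- total_out + r$outflow
  }
  expect_equal(sum(s$densities) + total_out, 1000, tolerance = 1e-9)
  expect_lt(sum(s$densities), 1e-6)   # everything has matured out by day 60

  # inflow route conserves too
  s2 <- new_stage_state(md$stages$pupa)
  total_in <- 0; total_out <- 0
  for (d in 1:80) {
    inflow <- if (d <= 10) 37.5 else 0
    r <- step_stage(s2, dx, mu = 0, inflow = inflow)
    s2 <- r$state
    total_in <- total_in + inflow
    total_out <- total_out + r$outflow
  }
  expect_equal(sum(s2$densities) + total_out, total_in, tolerance = 1e-9)
})

test_that("step_stage with dx = 0 only applies mortality and arrivals", {
  md <- load_species("medfly")
  s <- pulse_state(md$stages$pupa, 100)
  r <- step_stage(s, dx = 0, mu = 0.1)
  expect_equal(r$outflow, 0)
  expect_equal(r$state$densities[1], 90)
  expect_equal(sum(r$state$densities[-1]), 0)
  expect_equal(r$deaths, 10)
  expect_error(step_stage(s, dx = -1, mu = 0), "dx >= 0")
  expect_error(step_stage(s, dx = 1, mu = 2), "mu in")
})

test_that("no age class goes negative under erratic weather", {
  md <- load_species("medfly")
  set.seed(42)
  s <- pulse_state(md$stages$egg_larva, 500)
  for (d in 1:120) {
    T <- runif(1, -5, 45)
    r <- step_stage(s, dev_increment(T, md$stages$egg_larva),
                    mortality_rate(T, "egg_larva", md),
                    inflow = runif(1, 0, 50))
    s <- r$state
    expect_true(all(s$densities >= 0))
  }
})

test_that("pulse-cohort transit matches the analytic Erlang within 2%", {
  md <- load_species("medfly")
  st <- md$stages$pupa                       # delta 165 dd, k = 40
  dx <- dev_increment(25, st)                # ~15.5 dd/day
  s <- pulse_state(st, 1000)
  out <- numeric(40)
  for (d in 1:40) {
    r <- step_stage(s, dx, mu = 0)
    s <- r$state
    out[d] <- r$outflow
  }
  # exits during day d are centred at d - 0.5
  tt <- seq_along(out) - 0.5
  m <- sum(tt * out) / sum(out)
  sd_obs <- sqrt(sum(out * (tt - m)^2) / sum(out))
  theory <- erlang_stats(st$delta, st$erlang_k) / dx   # convert dd to days
  expect_equal(m, unname(theory["mean"]), tolerance = 0.02)
  expect_equal(sd_obs, unname(theory["sd"]), tolerance = 0.02)
  # spec worked example: ~10.6 days transit, CV ~ 1/sqrt(40)
  expect_equal(m, 10.6, tolerance = 0.01)
  expect_equal(sd_obs / m, 1 / sqrt(st$erlang_k), tolerance = 0.03)
})

test_that("initialize_population is deterministic and places mass correctly", {
  md <- load_species("medfly")
  p0 <- initialize_population(md, 0)
  expect_equal(unname(stage_totals(p0)), c(0, 0, 0))
  p1 <- initialize_population(md, 10)
  expect_equal(sum(p1$stages$adult$densities), 10)
  expect_equal(sum(p1$stages$egg_larva$densities), 0)
  nseed <- floor(md$stages$adult$erlang_k * 0.1)
  expect_true(all(p1$stages$adult$densities[seq_len(nseed)] > 0))
  expect_true(all(p1$stages$adult$densities[-seq_len(nseed)] == 0))
  expect_identical(p1, initialize_population(md, 10))
})

test_that("step_day: cold day means no development and no oviposition", {
  md <- load_species("medfly")
  pop <- initialize_population(md, 100)
  r <- step_day(pop, list(tmean = 4, rh = 60), md)
  expect_equal(r$out$dx_egg_larva, 0)
  expect_equal(r$out$dx_pupa, 0)
  expect_equal(r$out$dx_adult, 0)
  expect_equal(r$out$S, 0)
  expect_equal(r$out$new_pupae, 0)
  expect_lt(r$out$adult, 100)   # mortality still acts
})

test_that("step_day: extinction is absorbing and bad weather errors", {
  md <- load_species("medfly")
  pop <- initialize_population(md, 0)
  r <- step_day(pop, list(tmean = 25, rh = 70), md)
  expect_equal(unname(stage_totals(r$pop)), c(0, 0, 0))
  expect_equal(r$out$S, 0)
  expect_error(step_day(pop, list(tmean = NA, rh = 50), md), "finite")
  expect_error(step_day(pop, list(tmean = 25), md), "tmean and rh")
})

test_that("30 favorable days from 100 medfly adults yield eggs and new pupae", {
  md <- load_species("medfly")
  pop <- initialize_population(md, 100)
  res <- run_population(pop, make_weather(25, 70, days = 30), md)
  expect_gt(sum(res$trace$S), 0)
  expect_gt(sum(res$trace$new_pupae), 0)
  # egg-larval transit at 25 C is ~129/14.65 ~ 8.8 days: essentially no
  # pupae can appear in the first few days
  expect_lt(sum(res$trace$new_pupae[1:4]), 1e-3)
  expect_gt(sum(res$trace$new_pupae), 1)
})

test_that("whole-population conservation with mortality forced off", {
  # clone medfly with all mortality coefficients zeroed; no reproduction
  raw <- jsonlite::read_json(tephrisim:::species_param_path("medfly"))
  raw$mortality$groups$egg_larva$coef <- list(0)
  raw$mortality$groups$pupa_adult$coef <- list(0)
  raw$reproduction$gamma <- 1e-300          # suppress egg demand
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, tmp, auto_unbox = TRUE, null = "null")
  sp0 <- load_species(path = tmp)

  pop <- initialize_population(sp0, 50)
  wx <- make_weather(25, 70, days = 365)
  exits <- 0
  for (i in seq_len(nrow(wx))) {
    r <- step_day(pop, wx[i, ], sp0)
    pop <- r$pop
    exits <- exits + r$out$adult_maxage_deaths
  }
  total <- sum(stage_totals(pop)) + exits
  expect_equal(total, 50, tolerance = 1e-9)
})

test_that("constant cold with positive mortality drives the population to zero", {
  md <- load_species("medfly")
  pop <- initialize_population(md, 100)
  tot <- sum(stage_totals(pop))
  for (d in 1:120) {
    r <- step_day(pop, list(tmean = 2, rh = 60), md)
    pop <- r$pop
    new_tot <- sum(stage_totals(pop))
    expect_lt(new_tot, tot)
    tot <- new_tot
  }
  expect_lt(tot, 1e-4)
})

test_that("quiescent-day aging slows adults by delta_adult/delta_quiescent", {
  of <- load_species("oriental_fly")   # quiescent delta 1532 vs adult 1050
  # hot + bone-dry day: phi_RH(door window 40-95) = 0 -> quiescent
  pop <- initialize_population(of, 100)
  r <- step_day(pop, list(tmean = 25, rh = 20), of)
  expect_true(r$out$quiescent)
  expect_equal(r$out$dx_adult,
               dev_increment(25, of$stages$adult) * 1050 / 1532,
               tolerance = 1e-9)
  # with quiescence disabled, full adult aging
  pop2 <- initialize_population(of, 100, quiescence = FALSE)
  r2 <- step_day(pop2, list(tmean = 25, rh = 20), of)
  expect_false(r2$out$quiescent)
  expect_equal(r2$out$dx_adult, dev_increment(25, of$stages$adult))
})
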