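test_that("cycle statistics use the trapezoidal time average", {
  expect_equal(cycle_stats(c(7, 7, 7), c(0, 1, 2)),
               c(min = 7, mean = 7, max = 7))
  expect_equal(cycle_stats(c(0, 10), c(0, 1))[["mean"]], 5)
  set.seed(7)
  t <- sort(stats::runif(50, 0, 1))
  x <- stats::rnorm(50)
  # independent brute-force trapezoid oracle
  oracle <- sum(vapply(seq_len(49), function(i)
    (x[i] + x[i + 1]) / 2 * (t[i + 1] - t[i]), numeric(1))) / (t[50] - t[1])
  expect_equal(cycle_stats(x, t)[["mean"]], oracle)
  expect_error(cycle_stats(numeric(0), numeric(0)), "samples")
})

test_that("loop area is the shoelace area and rejects open loops", {
  # rectangle P in [10,110], V in [50,100] -> 100 * 50
  P <- c(10, 110, 110, 10, 10)
  V <- c(50, 50, 100, 100, 50)
  expect_equal(loop_area(P, V), 5000)
  expect_equal(loop_area(rep(20, 5), rep(70, 5)), 0)  # degenerate point
  expect_error(loop_area(c(0, 50, 100), c(50, 80, 120)), "open loop")
})

test_that("shoelace area agrees with an independent polygon oracle on 100 random loops", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    r <- 1 + stats::runif(1, 0, 2) + 0.3 * sin(sample(2:5, 1) * th)
    V <- 70 + 25 * r * cos(th); V <- c(V, V[1])
    P <- 50 + 35 * r * sin(th); P <- c(P, P[1])
    expect_equal(loop_area(P, V), abs(pracma::polyarea(V, P)),
                 tolerance = 1e-9)
  }
})

test_that("self-intersecting loop area sums absolute sub-loop areas", {
  # figure-eight: two unit-right-triangle lobes, signed areas cancel
  V <- c(0, 1, 1, 0)
  P <- c(0, 1, 0, 1)
  expect_equal(abs(cardioloop:::shoelace(V, P)), 0)
  expect_equal(loop_area_split(P, V), 0.5)
  # simple convex loop: identical to plain shoelace
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  expect_equal(loop_area_split(50 + 30 * sin(th), 70 + 20 * cos(th)),
               loop_area(c(50 + 30 * sin(th), 50), c(70 + 20 * cos(th), 90),
                         tol = 1),
               tolerance = 0.05)
})

test_that("potential energy matches closed forms and quadrature", {
  p_lin <- chamber_params(Ees = 2, V0 = 20, A = 0, B = 0)
  expect_equal(potential_energy(20, p_lin), 0)
  expect_equal(potential_energy(60, p_lin), 2 * 40^2 / 2)  # triangle
  p_exp <- chamber_params(Ees = 2.5, V0 = 15, A = 0.35, B = 0.027)
  ves <- 65
  quad <- stats::integrate(function(v) 0.35 * expm1(0.027 * (v - 15)), 15, ves)$value
  expect_equal(potential_energy(ves, p_exp), 2.5 * 50^2 / 2 - quad,
               tolerance = 1e-8)
  expect_warning(pe <- potential_energy(10, p_exp), "clamped")
  expect_equal(pe, 0)
})

test_that("arterial elastance and SVRi follow their defining ratios", {
  expect_equal(arterial_elastance(90, 45), 2)
  expect_equal(arterial_elastance(90, 90), 1)   # doubling SV halves Ea
  expect_error(arterial_elastance(90, 0), "ejection")
  expect_equal(svri(65, 5, 3.0, 1.5), 79.9 * 60 / 2)
  expect_equal(svri(65, 65, 3.0, 1.5), 0)
  set.seed(3)
  for (i in 1:20) {
    map <- stats::runif(1, 40, 120); cvp <- stats::runif(1, 0, 15)
    co <- stats::runif(1, 1, 8); bsa <- stats::runif(1, 1.2, 2.3)
    expect_equal(svri(map, cvp, co, bsa), 79.9 * (map - cvp) * bsa / co)
  }
  expect_error(svri(65, 5, 0, 1.5), "cardiac output")
})

test_that("coronary index and percentage change are the defined ratios", {
  expect_equal(coronary_flow_index(60, 20, 0.8), 50)
  expect_equal(coronary_flow_index(40, 40, 0.8), 0)
  expect_equal(percentage_change(110, 100), 10)
  expect_equal(percentage_change(100, 100), 0)
  expect_equal(percentage_change(86, 100), -14)
  expect_error(percentage_change(5, 0), "zero")
})

test_that("beat-level metrics agree with trapezoid oracles on a converged beat", {
  beat <- cached_healthy_beat()
  trap <- function(x, t) {
    sum((x[-1] + x[-length(x)]) / 2 * diff(t)) / (t[length(t)] - t[1])
  }
  expect_equal(pcwp(beat), trap(beat$P_pulmonary_veins, beat$t))
  h <- haemodynamic_report(beat)
  expect_equal(h$cbf, trap(beat$q_coronary_in, beat$t) * 60)
  expect_equal(h$cerebral_flow, trap(beat$q_arch_to_upper, beat$t) * 60)
  expect_gte(h$pcwp, h$lap_min)
  # pressure triples ordered, chamber volumes ordered
  for (v in c("lap", "aop", "pap", "lvp")) {
    expect_lte(h[[paste0(v, "_min")]], h[[paste0(v, "_mean")]])
    expect_lte(h[[paste0(v, "_mean")]], h[[paste0(v, "_max")]])
  }
  expect_lte(h$lvesv, h$lvedv)
  expect_lte(h$rvesv, h$rvedv)
})

test_that("energetic identities hold by construction on a converged beat", {
  beat <- cached_healthy_beat()
  e <- energetic_report(beat)
  h <- haemodynamic_report(beat)
  p <- attr(beat, "patient")
  expect_identical(e$lvpva, e$lvew + e$lvpe)
  expect_identical(e$rvpva, e$rvew + e$rvpe)
  expect_true(all(unlist(e[c("lvew", "rvew", "la_pvla", "ra_pvla")]) >= 0))
  expect_identical(h$ci, h$co / p$bsa)
  # total flow reconstructs as native output plus pump flow
  trap <- function(x, t) sum((x[-1] + x[-length(x)]) / 2 * diff(t)) /
    (t[length(t)] - t[1])
  native <- (h$lvedv - h$lvesv) * p$heart_rate / 1000
  expect_equal(h$total_flow, native + trap(beat$q_pump, beat$t) * 0.06,
               tolerance = 1e-10)
  expect_equal(e$ea_over_ees_lv, e$ea_sys / p$chambers$lv$Ees)
})
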