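test_that("default topology names all device attachment nodes and closes the loop", {
  p <- cached_healthy()
  topo <- build_topology(p)
  for (nm in c("ra", "ascending_aorta", "descending_aorta", "thoracic_aorta",
               "femoral_artery", "femoral_vein")) {
    resolved <- cardioloop:::resolve_node(nm)
    expect_true(resolved %in% topo$all_names, label = paste("node", nm))
  }
  # independent strong-connectivity oracle via igraph
  skip_if_not_installed("igraph")
  edges <- rbind(
    data.frame(from = topo$links$from_idx, to = topo$links$to_idx),
    data.frame(from = topo$valves$from_idx, to = topo$valves$to_idx))
  g <- igraph::graph_from_data_frame(edges,
                                     vertices = data.frame(seq_along(topo$all_names)))
  expect_true(igraph::is_connected(g, mode = "strong"))
})

test_that("topology validation rejects broken networks", {
  p <- cached_healthy()
  p_missing <- p
  p_missing$nodes <- p$nodes[p$nodes$name != "femoral_vein", ]
  p_missing$links <- p$links[!(p$links$from == "femoral_vein" |
                                 p$links$to == "femoral_vein"), ]
  expect_error(build_topology(p_missing), "mandatory node")

  p_open <- p
  p_open$links <- p$links[p$links$name != "ivc_to_ra", ]
  expect_error(build_topology(p_open), "closed loop")

  p_ill <- p
  p_ill$links$R[p_ill$links$name == "thoracic"] <- 0
  expect_error(build_topology(p_ill), "ill-posed")
})

test_that("RC segment relaxes to Q0*R with time constant R*C", {
  # constant inflow Q0 charging C, drained through R: P -> Q0*R, tau = R*C
  R <- 1.3; C <- 2.1; Q0 <- 5
  f <- function(t, y, parms)
    list(segment_dynamics(list(R = R, L = 0, C = C), y[1],
                          p_in = 0, q_out = -Q0)$dP)
  tt <- seq(0, 5 * R * C, by = 0.01)
  sol <- deSolve::ode(c(P = 0), tt, f, NULL, rtol = 1e-10, atol = 1e-10)
  analytic <- Q0 * R * (1 - exp(-tt / (R * C)))
  expect_lt(max(abs(sol[, "P"] - analytic)) / (Q0 * R), 1e-3)
})

test_that("RLC segment impedance matches the analytic frequency response", {
  R <- 0.05; L <- 5e-4; C <- 1.3
  w <- 2 * pi * 1.5
  f <- function(t, y, parms) {
    d <- segment_dynamics(list(R = R, L = L, C = C), y[1], y[2],
                          p_in = sin(w * t), q_out = 0)
    list(c(d$dP, d$dQ))
  }
  tt <- seq(0, 30 / 1.5, by = 1 / (200 * 1.5))
  sol <- deSolve::ode(c(P = 0, Q = 0), tt, f, NULL, rtol = 1e-10, atol = 1e-10)
  # fit amplitude/phase of the flow over the last third (transients decayed)
  keep <- tt > 20 / 1.5
  fit <- stats::lm(sol[keep, "Q"] ~ sin(w * tt[keep]) + cos(w * tt[keep]) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  phase <- atan2(-stats::coef(fit)[2], stats::coef(fit)[1])
  Z <- complex(real = R, imaginary = w * L - 1 / (w * C))
  expect_equal(amp, 1 / Mod(Z), tolerance = 0.01)
  expect_equal(as.numeric(phase), -Arg(1 / Z), tolerance = 0.01)
})

test_that("coronary branch follows Ohmic steady state and RC step response", {
  prm <- list(R1 = 1.0, R2 = 0.2, C = 0.05)
  expect_equal(coronary_flow(80, 80, prm), 0)
  expect_equal(coronary_flow(64, 4, list(R1 = 1.0, R2 = 0.2)), 50)
  # ohmic example with a single lumped resistance
  expect_equal(coronary_flow(62, 2, list(R1 = 1.2, R2 = 0)), 50)

  # step response of the intermediate node pressure
  pao <- 90
  f <- function(t, y, parms)
    list((coronary_flow(pao, 0, prm, p_cor = y[1]) - y[1] / prm$R2) / prm$C)
  tau <- prm$C * prm$R1 * prm$R2 / (prm$R1 + prm$R2)
  tt <- seq(0, 8 * tau, by = tau / 100)
  sol <- deSolve::ode(c(P = 0), tt, f, NULL, rtol = 1e-10, atol = 1e-12)
  analytic <- pao * prm$R2 / (prm$R1 + prm$R2) * (1 - exp(-tt / tau))
  expect_lt(max(abs(sol[, "P"] - analytic)) / max(analytic), 1e-3)
})

test_that("total blood volume matches a brute-force summation oracle", {
  p <- cached_healthy()
  topo <- build_topology(p)
  layout <- state_layout(topo)
  set.seed(42)
  for (i in 1:5) {
    y <- stats::runif(length(layout), 0, 120)
    names(y) <- names(layout)
    oracle <- sum(y[1:4]) +
      sum(vapply(seq_len(nrow(topo$nodes)), function(j)
        topo$nodes$Vu[j] + topo$nodes$C[j] * y[[paste0("P_", topo$nodes$name[j])]],
        numeric(1))) + 350 - y[["V_balloon"]]
    expect_equal(total_blood_volume(y, topo, priming_volume = 350), oracle)
  }
  # additivity: adding 100 mL to one compliant segment
  y2 <- y
  y2[["P_splanchnic"]] <- y[["P_splanchnic"]] +
    100 / topo$nodes$C[topo$nodes$name == "splanchnic"]
  expect_equal(total_blood_volume(y2, topo), total_blood_volume(y, topo) + 100)
})
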