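#' Simulation configuration
#'
#' Solver tolerances, beat limits and the periodic steady-state criterion.
#'
#' @param rtol,atol Relative/absolute local error tolerances passed to the
#'   stiff-capable adaptive integrator (deSolve's `lsoda`).
#' @param max_beats Maximum number of beats before giving up (>= 3).
#' @param ss_tol Relative per-beat change below which the run is declared
#'   periodic (checked on stroke volumes and mean pressures).
#' @param sample_hz Output sampling rate of the returned beat, Hz.
#' @param min_beats Minimum number of beats before convergence may be
#'   declared.
#' @param solver deSolve method name.
#' @param seed Unused by the deterministic model; kept for extensions.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(rtol = 1e-6, atol = 1e-5, max_beats = 60,
                              ss_tol = 1e-3, sample_hz = 200, min_beats = 5,
                              solver = "lsoda", seed = NULL) {
  if (ss_tol <= 0) stop("`ss_tol` must be > 0", call. = FALSE)
  if (max_beats < 3) stop("`max_beats` must be >= 3", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, max_beats = max_beats,
                 ss_tol = ss_tol, sample_hz = sample_hz,
                 min_beats = min_beats, solver = solver, seed = seed),
            class = "simulation_config")
}

#' Named layout of the state vector
#'
#' The state is the ordered concatenation of the four chamber volumes
#' (`V_lv`, `V_rv`, `V_la`, `V_ra`), one pressure per compliant node, one
#' flow per inertant link, the ECMO circuit flow `Q_ecmo` and the balloon
#' gas volume `V_balloon`.
#'
#' @param topology A [build_topology()] result.
#' @return Named integer vector mapping variable names to state positions.
#' @export
state_layout <- function(topology) {
  inert <- topology$links$name[topology$links$L > 0]
  nms <- c(paste0("V_", chamber_names),
           paste0("P_", topology$nodes$name),
           paste0("Q_", inert),
           "Q_ecmo", "V_balloon")
  stats::setNames(seq_along(nms), nms)
}

# smooth rectangular gate on the cycle-fraction axis, possibly wrapping
iabp_gate <- function(phi, infl, defl, wf) {
  if (infl < defl) {
    stats::plogis((phi - infl) / wf) * stats::plogis((defl - phi) / wf)
  } else {
    pmax(stats::plogis((phi - infl) / wf), stats::plogis((defl - phi) / wf))
  }
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Assemble the global derivative function
#'
#' Builds the pure right-hand side `f(t, y, parms)` of the closed-loop
#' system for a given patient and device configuration, in the form deSolve
#' expects. `parms` carries only the per-beat balloon timing windows
#' (`infl`, `defl` as cycle fractions); everything else is fixed in the
#' closure, so evaluating twice at the same `(t, y, parms)` gives identical
#' output. The returned function also emits auxiliary outputs (chamber
#' pressures and every element flow), captured in the integration result.
#'
#' @param patient A [patient_params()] object.
#' @param devices A [device_config()] object.
#' @param topology Optional pre-built topology (rebuilt if omitted).
#' @return Function of `(t, y, parms)` with attributes `layout` (state
#'   index map) and `topology`.
#' @export
assemble_derivative <- function(patient, devices = device_config(),
                                topology = NULL) {
  if (is.null(topology)) topology <- build_topology(patient)
  nn <- topology$n_nodes
  nodes <- topology$nodes
  links <- topology$links
  valves <- topology$valves
  layout <- state_layout(topology)
  np <- 4L + nn

  tms <- chamber_timings(patient)
  Tper <- tms$period
  ch <- patient$chambers
  sep <- patient$septum

  res_l <- links[links$L == 0, ]
  in_l <- links[links$L > 0, ]
  ni <- nrow(in_l)
  iq <- np + seq_len(ni)          # state indices of inertant flows
  i_qec <- np + ni + 1L
  i_vb <- np + ni + 2L

  # incidence matrix: rows = pressure sites, cols = flows (resistive,
  # valve, inertant, pump, balloon); net inflow = M %*% Q
  nq <- nrow(res_l) + nrow(valves) + ni + 2L
  M <- matrix(0, np, nq)
  col <- 0L
  add_flow <- function(from, to) {
    col <<- col + 1L
    if (!is.na(from)) M[from, col] <<- M[from, col] - 1
    if (!is.na(to)) M[to, col] <<- M[to, col] + 1
  }
  for (i in seq_len(nrow(res_l))) add_flow(res_l$from_idx[i], res_l$to_idx[i])
  for (i in seq_len(nrow(valves))) add_flow(valves$from_idx[i], valves$to_idx[i])
  for (i in seq_len(ni)) add_flow(in_l$from_idx[i], in_l$to_idx[i])

  ec <- devices$ecmo
  ecmo_on <- ec$mode != "off"
  if (ecmo_on) {
    all_names <- topology$all_names
    i_drain <- match(resolve_node(ec$drain_node), all_names)
    i_ret <- match(resolve_node(ec$return_node), all_names)
    if (is.na(i_drain) || is.na(i_ret))
      stop("unknown ECMO node name(s): ", ec$drain_node, " / ", ec$return_node,
           call. = FALSE)
    add_flow(i_drain, i_ret)
  } else {
    add_flow(NA, NA)
    i_drain <- i_ret <- NA_integer_
  }

  ib <- devices$iabp
  iabp_on <- isTRUE(ib$enabled)
  i_balloon <- match(resolve_node(ib$balloon_node), topology$all_names)
  if (iabp_on && is.na(i_balloon))
    stop("unknown IABP balloon node: ", ib$balloon_node, call. = FALSE)
  add_flow(NA, if (iabp_on) i_balloon else NA)

  rR <- res_l$R
  rf <- res_l$from_idx; rt <- res_l$to_idx
  vR <- valves$R; vW <- valves$width
  vf <- valves$from_idx; vt <- valves$to_idx
  iR <- in_l$R; iL <- in_l$L
  if_ <- in_l$from_idx; it_ <- in_l$to_idx
  Cn <- nodes$C
  k1 <- ec$characteristic$k1; k2 <- ec$characteristic$k2
  k3 <- ec$characteristic$k3
  wf <- 0.008 / Tper              # balloon gate ramp, ~8 ms

  aux_names <- c("P_lv", "P_rv", "P_la", "P_ra",
                 paste0("q_", res_l$name), paste0("q_", valves$name),
                 paste0("q_", in_l$name), "q_pump", "q_iabp", "a_v", "a_a")

  act <- function(t, tm) {
    s <- (t - tm$onset_frac * tm$period) %% tm$period
    Ts <- tm$systolic_duration
    tp <- tm$peak_frac * Ts
    if (s < tp) 0.5 * (1 - cos(pi * s / tp))
    else if (s <= Ts) 0.5 * (1 + cos(pi * (s - tp) / (Ts - tp)))
    else 0
  }

  f <- function(t, y, parms) {
    a_v <- act(t, tms$lv)
    a_a <- act(t, tms$la)
    Vlv <- y[1L]; Vrv <- y[2L]; Vla <- y[3L]; Vra <- y[4L]
    Plv <- a_v * ch$lv$Ees * (Vlv - ch$lv$V0) +
      (1 - a_v) * ch$lv$A * expm1(ch$lv$B * (Vlv - ch$lv$V0)) +
      sep$k_lv * (Vrv - sep$vref_rv)
    Prv <- a_v * ch$rv$Ees * (Vrv - ch$rv$V0) +
      (1 - a_v) * ch$rv$A * expm1(ch$rv$B * (Vrv - ch$rv$V0)) +
      sep$k_rv * (Vlv - sep$vref_lv)
    Pla <- a_a * ch$la$Ees * (Vla - ch$la$V0) +
      (1 - a_a) * ch$la$A * expm1(ch$la$B * (Vla - ch$la$V0))
    Pra <- a_a * ch$ra$Ees * (Vra - ch$ra$V0) +
      (1 - a_a) * ch$ra$A * expm1(ch$ra$B * (Vra - ch$ra$V0))
    P <- c(Plv, Prv, Pla, Pra, y[5:np])

    q_res <- (P[rf] - P[rt]) / rR
    dp_v <- P[vf] - P[vt]
    z <- dp_v / vW
    sp <- ifelse(z > 30, dp_v, ifelse(z < -30, 0, vW * log1p(exp(z))))
    q_val <- sp / vR
    q_in <- y[iq]
    dq_in <- (P[if_] - P[it_] - iR * q_in) / iL

    Qec <- y[i_qec]
    if (ecmo_on) {
      r_block <- if (ec$backflow_valve) 300 * stats::plogis(-Qec / 0.05) else 0
      head <- k1 * ec$rpm^2 - k2 * Qec * ec$rpm - k3 * Qec^2
      dQec <- (head - (P[i_ret] - P[i_drain]) -
                 (ec$cannula_resistance + r_block) * Qec) /
        ec$cannula_inertance
    } else {
      dQec <- -100 * Qec
    }

    Vb <- y[i_vb]
    if (iabp_on) {
      phi <- (t %% Tper) / Tper
      g_in <- iabp_gate(phi, parms$infl, parms$defl, wf)
      Pb <- P[i_balloon]
      dVb <- g_in * (ib$drive_pressure - Pb) / ib$gas_resistance *
        clamp01(ib$balloon_volume - Vb) +
        (1 - g_in) * (ib$vacuum_pressure - Pb) / ib$gas_resistance *
        clamp01(Vb)
    } else {
      dVb <- -Vb
    }
    q_iabp <- if (iabp_on) dVb else 0

    Qall <- c(q_res, q_val, q_in, Qec, q_iabp)
    net <- as.numeric(M %*% Qall)

    dy <- numeric(length(y))
    dy[1:4] <- net[1:4]
    dy[5:np] <- net[5:np] / Cn
    dy[iq] <- dq_in
    dy[i_qec] <- dQec
    dy[i_vb] <- dVb

    aux <- c(Plv, Prv, Pla, Pra, q_res, q_val, q_in, Qec, q_iabp, a_v, a_a)
    names(aux) <- aux_names
    list(dy, aux)
  }
  attr(f, "layout") <- layout
  attr(f, "topology") <- topology
  f
}

#' Initial state for a simulation
#'
#' Chambers start at their configured initial volumes and nodes at their
#' configured pressures; the difference between the implied total volume
#' and the patient's total blood volume is then distributed over the venous
#' compliances (uniform pressure offset), so `blood_volume` acts as a clean
#' volume knob.
#'
#' @param patient A [patient_params()] object.
#' @param topology A [build_topology()] result.
#' @return Named numeric state vector.
#' @export
initial_state <- function(patient, topology) {
  nn <- topology$n_nodes
  ni <- sum(topology$links$L > 0)
  layout <- state_layout(topology)
  y <- numeric(length(layout))
  names(y) <- names(layout)
  y[1:4] <- vapply(patient$chambers[chamber_names],
                   function(chp) chp$V_init, numeric(1))
  y[4 + seq_len(nn)] <- topology$nodes$P0
  base <- sum(y[1:4]) +
    sum(topology$nodes$Vu + topology$nodes$C * topology$nodes$P0)
  ven <- topology$nodes$role == "venous"
  dP <- (patient$blood_volume - base) / sum(topology$nodes$C[ven])
  y[4 + which(ven)] <- y[4 + which(ven)] + dP
  y
}

beat_monitors <- function(series) {
  c(sv_lv = max(series$V_lv) - min(series$V_lv),
    sv_rv = max(series$V_rv) - min(series$V_rv),
    edv_lv = max(series$V_lv),
    aop = mean(series$P_ascending_aorta),
    pap = mean(series$P_pulmonary_artery),
    pcwp = mean(series$P_pulmonary_veins))
}

#' Run the closed loop to periodic steady state
#'
#' Integrates beat by beat until the per-beat relative change of every
#' monitored scalar (left/right stroke volume, LV end-diastolic volume,
#' mean aortic, pulmonary arterial and pulmonary venous pressures) falls
#' below `sim$ss_tol`, then returns the final beat. Balloon counterpulsation
#' timing uses fixed cycle fractions on the first beat and is re-triggered
#' from the detected aortic valve closure of the previous beat afterwards.
#'
#' @param patient A [patient_params()] object.
#' @param devices A [device_config()] object.
#' @param sim A [simulation_config()] object.
#' @param require_convergence Raise an error when no periodic steady state
#'   is reached within `sim$max_beats` (default). With `FALSE` the final
#'   integrated beat is returned regardless — useful for fixed-length runs
#'   such as volume-drift checks.
#' @return A `beat_series`: data frame of the final beat sampled at
#'   `sim$sample_hz` (time, all state variables, chamber pressures, all
#'   element flows) with landmark times and run metadata in attributes.
#' @export
run_to_steady_state <- function(patient, devices = device_config(),
                                sim = simulation_config(),
                                require_convergence = TRUE) {
  topology <- build_topology(patient)
  f <- assemble_derivative(patient, devices, topology)
  Tper <- 60 / patient$heart_rate
  y <- initial_state(patient, topology)
  parms <- list(infl = devices$iabp$inflation_start,
                defl = devices$iabp$deflation_start)
  nout <- max(20L, round(sim$sample_hz * Tper))
  prev <- NULL
  residuals <- NULL
  converged <- FALSE
  series <- NULL
  for (beat in seq_len(sim$max_beats)) {
    t0 <- (beat - 1) * Tper
    times <- t0 + seq(0, Tper, length.out = nout + 1)
    sol <- deSolve::ode(y, times, f, parms, method = sim$solver,
                        rtol = sim$rtol, atol = sim$atol, maxsteps = 50000)
    istate <- attr(sol, "istate")[1]
    if (is.null(istate) || istate < 0 || nrow(sol) < nout + 1) {
      bad <- which.max(abs(sol[nrow(sol), 1 + seq_along(y)] -
                             sol[max(1, nrow(sol) - 1), 1 + seq_along(y)]))
      stop("solver failure in beat ", beat, " near state variable `",
           names(y)[bad], "`", call. = FALSE)
    }
    y <- sol[nrow(sol), 1 + seq_along(y)]
    series <- as.data.frame(unclass(sol))
    names(series)[1] <- "t"
    mon <- beat_monitors(series)
    if (!is.null(prev)) {
      residuals <- abs(mon - prev) / pmax(abs(mon), 1)
      if (beat >= sim$min_beats && all(residuals < sim$ss_tol)) {
        converged <- TRUE
      }
    }
    prev <- mon
    attr(series, "period") <- Tper
    attr(series, "beat") <- beat
    if (devices$iabp$enabled) {
      lm <- try(detect_landmarks(structure(series, class = c("beat_series", "data.frame"))),
                silent = TRUE)
      if (!inherits(lm, "try-error") && !is.na(lm$t_avc)) {
        w <- iabp_windows(Tper, devices$iabp,
                          list(t_avc = lm$t_avc, t_systole_onset = 0))
        parms <- list(infl = w$infl, defl = w$defl)
      }
    }
    if (converged) break
  }
  if (!converged && require_convergence)
    stop("no periodic steady state within ", sim$max_beats,
         " beats; last residuals: ",
         paste(sprintf("%s=%.2e", names(residuals), residuals), collapse = ", "),
         call. = FALSE)
  class(series) <- c("beat_series", "data.frame")
  attr(series, "patient") <- patient
  attr(series, "devices") <- devices
  attr(series, "sim") <- sim
  attr(series, "topology") <- topology
  attr(series, "monitors") <- prev
  attr(series, "converged") <- converged
  attr(series, "n_beats") <- beat
  attr(series, "iabp_windows") <- parms
  attr(series, "landmarks") <- detect_landmarks(series)
  series
}

#' @export
print.beat_series <- function(x, ...) {
  cat("Converged beat:", attr(x, "n_beats"), "beats, period",
      round(attr(x, "period"), 4), "s,", nrow(x), "samples\n")
  invisible(x)
}

#' Detect cycle landmarks on a beat
#'
#' End-diastole is the time of maximum ventricular volume, end-systole the
#' time of minimum; aortic (mitral) valve events are the times at which the
#' valve flow rises above / falls back to zero. All times are on the beat's
#' own time axis.
#'
#' @param beat A `beat_series` (or data frame with columns `t`, `V_lv`,
#'   `V_rv`, `q_aortic`, `q_mitral`).
#' @return List with `t_ed_lv`, `t_es_lv`, `edv_lv`, `esv_lv` (and the RV
#'   equivalents), valve event times `t_avo`, `t_avc`, `t_mvo`, `t_mvc`
#'   (NA when a valve never opens), and `t_systole_onset`.
#' @export
detect_landmarks <- function(beat) {
  if (diff(range(beat$V_lv)) < 1e-6 || diff(range(beat$V_rv)) < 1e-6)
    stop("non-beating signal: ventricular volumes are flat", call. = FALSE)
  valve_events <- function(q, t) {
    thr <- max(q) * 1e-3
    if (max(q) < 1e-6) return(c(open = NA_real_, close = NA_real_))
    above <- q > thr
    op <- which(!above[-length(above)] & above[-1])
    cl <- which(above[-length(above)] & !above[-1])
    c(open = if (length(op)) t[op[1] + 1] else t[1],
      close = if (length(cl)) t[cl[length(cl)] + 1] else NA_real_)
  }
  av <- valve_events(beat$q_aortic, beat$t)
  mv <- valve_events(beat$q_mitral, beat$t)
  list(
    t_ed_lv = beat$t[which.max(beat$V_lv)], edv_lv = max(beat$V_lv),
    t_es_lv = beat$t[which.min(beat$V_lv)], esv_lv = min(beat$V_lv),
    t_ed_rv = beat$t[which.max(beat$V_rv)], edv_rv = max(beat$V_rv),
    t_es_rv = beat$t[which.min(beat$V_rv)], esv_rv = min(beat$V_rv),
    t_avo = av[["open"]], t_avc = av[["close"]],
    t_mvo = mv[["open"]], t_mvc = mv[["close"]],
    t_systole_onset = beat$t[1]
  )
}
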