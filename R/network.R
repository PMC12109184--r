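#' Mandatory named branches of the closed loop
#'
#' The vessel network must contain these compliant nodes for the topology to
#' validate; the device attachment points (right atrium, ascending aorta,
#' descending aorta, thoracic aorta, femoral artery, femoral vein) are drawn
#' from them. `"descending_aorta"` is accepted as an alias of
#' `"descending_thoracic_aorta"`.
#'
#' @keywords internal
mandatory_nodes <- c(
  "ascending_aorta", "aortic_arch", "descending_thoracic_aorta",
  "thoracic_aorta", "upper_limbs_head", "superior_vena_cava",
  "inferior_vena_cava", "renal_hepatic", "splanchnic", "abdominal",
  "femoral_artery", "femoral_vein", "pulmonary_artery", "pulmonary_veins",
  "coronary"
)

chamber_names <- c("lv", "rv", "la", "ra")

node_aliases <- c(descending_aorta = "descending_thoracic_aorta")

resolve_node <- function(name) {
  ifelse(name %in% names(node_aliases), unname(node_aliases[name]), name)
}

#' Build and validate the closed-loop network topology
#'
#' Checks that the patient's node/link tables name every mandatory branch,
#' that all link endpoints exist, that no purely resistive link is ill-posed
#' (`R = 0` with `L = 0`), and that the directed graph formed by links and
#' valves is a single closed loop (one strongly connected component
#' containing all chambers and nodes). Pressure-vector indices are attached
#' so the simulator can address every endpoint by integer.
#'
#' @param patient A [patient_params()] object (or any list with `nodes`,
#'   `links`, `valves` tables in the packaged format).
#' @return An object of class `network_topology` with resolved integer
#'   indices (chambers occupy positions 1-4, nodes follow in table order).
#' @export
build_topology <- function(patient) {
  nodes <- patient$nodes
  links <- patient$links
  valves <- patient$valves
  missing <- setdiff(mandatory_nodes, nodes$name)
  if (length(missing) > 0)
    stop("topology is missing mandatory node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(nodes$name))
    stop("duplicate node names in topology", call. = FALSE)
  if (any(nodes$C <= 0))
    stop("all node compliances must be > 0", call. = FALSE)
  if (any(links$R < 0) || any(links$L < 0))
    stop("link R and L must be >= 0", call. = FALSE)
  if (any(links$R == 0 & links$L == 0))
    stop("ill-posed link: R = 0 with L = 0", call. = FALSE)

  all_names <- c(chamber_names, nodes$name)
  idx_of <- function(x) {
    x <- resolve_node(x)
    i <- match(x, all_names)
    if (anyNA(i))
      stop("unknown endpoint name(s): ",
           paste(x[is.na(i)], collapse = ", "), call. = FALSE)
    i
  }
  links$from_idx <- idx_of(links$from)
  links$to_idx <- idx_of(links$to)
  valves$from_idx <- idx_of(valves$from)
  valves$to_idx <- idx_of(valves$to)

  # closed-loop check: single strongly connected component over all elements
  n <- length(all_names)
  edges <- rbind(cbind(links$from_idx, links$to_idx),
                 cbind(valves$from_idx, valves$to_idx))
  reach <- function(start, adj) {
    seen <- logical(n); seen[start] <- TRUE; queue <- start
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    seen
  }
  fwd <- split(edges[, 2], factor(edges[, 1], levels = seq_len(n)))
  bwd <- split(edges[, 1], factor(edges[, 2], levels = seq_len(n)))
  if (!all(reach(1L, fwd) & reach(1L, bwd)))
    stop("topology error: network is not a single closed loop", call. = FALSE)

  structure(
    list(nodes = nodes, links = links, valves = valves,
         all_names = all_names, n_chambers = 4L, n_nodes = nrow(nodes)),
    class = "network_topology"
  )
}

#' @export
print.network_topology <- function(x, ...) {
  cat("Closed-loop vascular topology:", x$n_nodes, "compliant nodes,",
      nrow(x$links), "links,", nrow(x$valves), "valves\n")
  invisible(x)
}

#' Time derivatives of a single RLC vessel segment
#'
#' One segment is a series resistance R (optionally with inertance L)
#' feeding a compliance C. The governing relations are
#' `L dQ/dt = Pin - P - R Q` (or, for `L = 0`, the algebraic
#' `Q = (Pin - P)/R`) and `C dP/dt = Qin - Qout`.
#'
#' @param seg List with fields `R`, `L`, `C`.
#' @param P Pressure at the segment's compliance, mmHg.
#' @param Q Inflow through the R(L) element, mL/s (ignored when `L = 0`).
#' @param p_in Upstream (driving) pressure, mmHg.
#' @param q_out Outflow drawn from the compliance, mL/s.
#' @return List with `dP` (mmHg/s), `dQ` (mL/s^2, `NULL` for L = 0) and the
#'   instantaneous inflow `q_in`.
#' @export
segment_dynamics <- function(seg, P, Q = NULL, p_in, q_out = 0) {
  if (seg$L > 0) {
    dQ <- (p_in - P - seg$R * Q) / seg$L
    list(dP = (Q - q_out) / seg$C, dQ = dQ, q_in = Q)
  } else {
    if (seg$R <= 0) stop("ill-posed segment: R = 0 with L = 0", call. = FALSE)
    q_in <- (p_in - P) / seg$R
    list(dP = (q_in - q_out) / seg$C, dQ = NULL, q_in = q_in)
  }
}

#' Coronary branch flow
#'
#' The coronary circulation is an RC branch from the aortic root to the
#' right atrium: proximal resistance `R1` into a compliance `C`, drained by
#' `R2`. Given the intermediate node pressure the instantaneous inflow is
#' `(P_ao - P_cor)/R1`; omitting it returns the steady-state Ohmic flow
#' `(P_ao - P_ra)/(R1 + R2)`.
#'
#' @param p_ao Aortic root pressure, mmHg.
#' @param p_ra Right atrial pressure, mmHg.
#' @param params List with `R1`, `R2` (and `C`, unused for the steady state).
#' @param p_cor Optional coronary node pressure, mmHg.
#' @return Flow in mL/s.
#' @export
coronary_flow <- function(p_ao, p_ra, params, p_cor = NULL) {
  if (is.null(p_cor)) (p_ao - p_ra) / (params$R1 + params$R2)
  else (p_ao - p_cor) / params$R1
}

#' Total blood volume of the closed loop
#'
#' Sum of the four chamber volumes, every compliant segment's volume
#' (`Vu + C * P`), the ECMO circuit priming volume, minus the volume
#' displaced by the balloon gas (the balloon occupies space inside the
#' aorta, so the blood the flow source injected is not extra blood).
#'
#' @param state Named state vector as produced by the simulator (see
#'   [state_layout()]).
#' @param topology A [build_topology()] result.
#' @param priming_volume ECMO circuit volume, mL (0 when off).
#' @return Total volume in mL.
#' @export
total_blood_volume <- function(state, topology, priming_volume = 0) {
  nn <- topology$n_nodes
  vch <- sum(state[1:4])
  P <- state[4 + seq_len(nn)]
  vseg <- sum(topology$nodes$Vu + topology$nodes$C * P)
  vb <- state[[4 + nn + sum(topology$links$L > 0) + 2]]
  vch + vseg + priming_volume - vb
}
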