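#' Construct a patient parameter set
#'
#' Bundles everything that describes the circulation of one subject: the
#' four chamber parameter sets, septal coupling, activation timing rules,
#' the vascular node/link/valve tables, heart rate, body surface area and
#' total blood volume.
#'
#' @param heart_rate Heart rate in bpm (40-140).
#' @param bsa Body surface area, m^2.
#' @param blood_volume Total blood volume, mL.
#' @param chambers Named list `lv`, `rv`, `la`, `ra` of [chamber_params()].
#' @param septum A [septum_params()] object.
#' @param timing List of timing rule coefficients (see the packaged default
#'   configuration file).
#' @param nodes,links,valves Data frames in the packaged format.
#' @param meta Optional provenance list (e.g. tuner knobs).
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(heart_rate, bsa, blood_volume, chambers, septum,
                           timing, nodes, links, valves, meta = list()) {
  if (heart_rate < 40 || heart_rate > 140)
    stop("`heart_rate` must lie in [40, 140] bpm", call. = FALSE)
  if (bsa <= 0) stop("`bsa` must be > 0", call. = FALSE)
  if (blood_volume <= 0) stop("`blood_volume` must be > 0", call. = FALSE)
  stopifnot(all(c("lv", "rv", "la", "ra") %in% names(chambers)))
  structure(
    list(heart_rate = heart_rate, bsa = bsa, blood_volume = blood_volume,
         chambers = chambers, septum = septum, timing = timing,
         nodes = nodes, links = links, valves = valves, meta = meta),
    class = "patient_params"
  )
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Patient parameter set: HR", x$heart_rate, "bpm, BSA", x$bsa,
      "m^2, blood volume", x$blood_volume, "mL\n")
  cat("  LV Ees", x$chambers$lv$Ees, "mmHg/mL; RV Ees", x$chambers$rv$Ees,
      "mmHg/mL\n")
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

as_df <- function(lst) {
  do.call(rbind, lapply(lst, function(row) as.data.frame(row, stringsAsFactors = FALSE)))
}

#' Read a patient configuration file
#'
#' Loads the structured YAML patient description (the packaged
#' `healthy_patient.yaml` is the reference for the format) into a
#' [patient_params()] object.
#'
#' @param path Path to a YAML configuration file.
#' @return A [patient_params()] object.
#' @export
read_patient_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  chambers <- lapply(cfg$chambers, function(ch)
    chamber_params(ch$Ees, ch$V0, ch$A, ch$B))
  for (nm in names(chambers)) {
    chambers[[nm]]$V_init <- cfg$chambers[[nm]]$V_init
    chambers[[nm]]$label <- nm
  }
  patient_params(
    heart_rate = cfg$heart_rate, bsa = cfg$bsa,
    blood_volume = cfg$blood_volume,
    chambers = chambers,
    septum = do.call(septum_params, cfg$septum),
    timing = cfg$timing,
    nodes = as_df(cfg$nodes),
    links = as_df(cfg$links),
    valves = as_df(cfg$valves),
    meta = if (is.null(cfg$meta)) list() else cfg$meta
  )
}

#' Write a patient configuration file
#'
#' Inverse of [read_patient_config()]; the written file round-trips.
#'
#' @param patient A [patient_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_config <- function(patient, path) {
  rows <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  cfg <- list(
    heart_rate = patient$heart_rate, bsa = patient$bsa,
    blood_volume = patient$blood_volume,
    timing = patient$timing,
    chambers = lapply(patient$chambers, function(ch)
      list(Ees = ch$Ees, V0 = ch$V0, A = ch$A, B = ch$B, V_init = ch$V_init)),
    septum = unclass(patient$septum),
    valves = rows(patient$valves[, c("name", "from", "to", "R", "width")]),
    nodes = rows(patient$nodes),
    links = rows(patient$links[, c("name", "from", "to", "R", "L", "role")]),
    meta = patient$meta
  )
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' The packaged healthy reference patient
#'
#' Deterministically loads the packaged parameter file. The parameter values
#' are stand-ins from standard lumped-parameter practice, calibrated so the
#' simulated subject lands in the sanity band CO 4.5-6 L/min and mean aortic
#' pressure 85-100 mmHg at heart rate 70 bpm.
#'
#' @return A [patient_params()] object.
#' @export
make_healthy_patient <- function() {
  read_patient_config(system.file("extdata", "healthy_patient.yaml",
                                  package = "cardioloop", mustWork = TRUE))
}

# derive the four activation timings (s) from heart rate + timing rules
chamber_timings <- function(patient) {
  T <- 60 / patient$heart_rate
  tm <- patient$timing
  ts_v <- tm$ts_v_coef * sqrt(T)
  ts_a <- tm$ts_a_coef * sqrt(T)
  av <- tm$av_delay * T / tm$av_delay_ref_period
  onset_a <- ((T - av) %% T) / T
  vent <- activation_timing(T, 0, ts_v, tm$peak_frac)
  atr <- activation_timing(T, onset_a, ts_a, tm$peak_frac)
  list(lv = vent, rv = vent, la = atr, ra = atr, period = T, av_delay = av)
}
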