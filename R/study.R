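#' The study's condition matrix
#'
#' The pathological baseline followed by every combination of cannulation
#' site (central, peripheral), pump speed (3000, 3500, 4000 rpm) and
#' balloon counterpulsation (off, on at 260/-10 mmHg): 13 conditions, the
#' baseline always first.
#'
#' @param rpms Pump speeds to sweep.
#' @return Data frame with columns `condition`, `mode`, `rpm`, `iabp`.
#' @export
run_matrix <- function(rpms = c(3000, 3500, 4000)) {
  grid <- expand.grid(iabp = c(FALSE, TRUE), rpm = rpms,
                      mode = c("central", "peripheral"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$mode, grid$rpm, grid$iabp), ]
  cond <- paste0(grid$mode, "_", grid$rpm, ifelse(grid$iabp, "_iabp", ""))
  out <- rbind(
    data.frame(condition = "pathological", mode = "off", rpm = 0,
               iabp = FALSE, stringsAsFactors = FALSE),
    data.frame(condition = cond, mode = grid$mode, rpm = grid$rpm,
               iabp = grid$iabp, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

condition_devices <- function(mode, rpm, iabp) {
  ec <- if (mode == "off") ecmo_config("off") else ecmo_config(mode, rpm = rpm)
  ib <- if (iabp) iabp_config() else iabp_config(enabled = FALSE)
  device_config(ec, ib)
}

#' Run one study condition
#'
#' @param patient The (pathological) baseline patient.
#' @param mode `"off"`, `"central"` or `"peripheral"`.
#' @param rpm Pump speed (ignored when `mode = "off"`).
#' @param iabp Logical: balloon counterpulsation on.
#' @param sim A [simulation_config()].
#' @return List with `haemo`, `energy` (one-row data frames) and `beat`.
#' @export
run_condition <- function(patient, mode = "off", rpm = 0, iabp = FALSE,
                          sim = simulation_config()) {
  devices <- condition_devices(mode, rpm, iabp)
  beat <- tryCatch(
    run_to_steady_state(patient, devices, sim),
    error = function(e) stop("condition ", mode, if (rpm > 0) paste0("_", rpm),
                             if (iabp) "_iabp", " failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  list(haemo = haemodynamic_report(beat), energy = energetic_report(beat),
       beat = beat)
}

#' Run the full condition matrix
#'
#' Runs every condition of the matrix against the same baseline patient and
#' assembles the absolute metric table plus the percentage changes of every
#' metric against the pathological baseline.
#'
#' @param patient The pathological baseline patient.
#' @param matrix Condition matrix from [run_matrix()].
#' @param sim A [simulation_config()].
#' @param keep_beats Keep the per-condition beat series in the report.
#' @return An object of class `study_report` with elements `absolute`
#'   (13 x metrics), `pct` (12 x metrics, percentage changes vs baseline),
#'   `conditions` and `provenance`.
#' @export
run_study <- function(patient, matrix = run_matrix(),
                      sim = simulation_config(), keep_beats = FALSE) {
  stopifnot(identical(matrix$condition[1], "pathological"))
  rows <- vector("list", nrow(matrix))
  beats <- if (keep_beats) vector("list", nrow(matrix)) else NULL
  for (i in seq_len(nrow(matrix))) {
    res <- run_condition(patient, matrix$mode[i], matrix$rpm[i],
                         matrix$iabp[i], sim)
    rows[[i]] <- cbind(res$haemo, res$energy)
    if (keep_beats) beats[[i]] <- res$beat
  }
  absolute <- do.call(rbind, rows)
  absolute <- absolute[, metric_names()]
  rownames(absolute) <- matrix$condition
  base <- absolute[1, , drop = FALSE]
  pct <- absolute[-1, , drop = FALSE]
  for (m in metric_names()) {
    pct[[m]] <- if (base[[m]] == 0) NA_real_   # undefined (e.g. pump flow)
                else percentage_change(pct[[m]], base[[m]])
  }
  structure(
    list(absolute = cbind(matrix, absolute),
         pct = cbind(matrix[-1, ], pct),
         conditions = matrix,
         provenance = list(
           config_hash = rlang::hash(list(patient = patient, matrix = matrix,
                                          sim = unclass(sim))),
           solver = unclass(sim),
           package_version = as.character(utils::packageVersion("cardioloop"))),
         beats = beats),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", nrow(x$absolute), "conditions,",
      length(metric_names()), "metrics\n")
  cat("Percentage changes vs pathological baseline (selected):\n")
  sel <- c("condition", "lvesv", "lvedv", "rvedv", "pcwp", "aop_mean",
           "total_flow", "svri")
  print(cbind(x$pct["condition"], round(x$pct[, setdiff(sel, "condition")], 1)),
        row.names = FALSE)
  invisible(x)
}

# expectation table of the directional findings the study mirrors
directional_expectations <- function() {
  sign_rows <- rbind(
    data.frame(condition = "central_3000",
               metric = c("lvesv", "rvedv"), sign = c(1, -1)),
    data.frame(condition = "peripheral_3000",
               metric = c("lvesv", "lvedv", "rvesv", "rvedv", "laesv", "laedv"),
               sign = 1),
    data.frame(condition = "central_3000_iabp",
               metric = c("lvedv", "rvedv", "laedv"), sign = -1),
    data.frame(condition = "peripheral_4000",
               metric = c("pcwp", "pap_mean"), sign = 1),
    data.frame(condition = "central_4000",
               metric = c("pcwp", "pap_mean"), sign = -1)
  )
  sign_rows
}

#' Directional consistency of a study report
#'
#' Evaluates the documented list of qualitative expectations for the
#' support conditions against the report's percentage changes: volume and
#' pressure shifts of each cannulation site, opposite wedge/pulmonary
#' pressure response of central vs peripheral return, coronary and total
#' flow growing with pump speed, and diastolic augmentation of mean aortic
#' pressure whenever the balloon is on. Failures are reported, not raised.
#'
#' @param report A [run_study()] result (or any list with a `pct` table
#'   carrying a `condition` column).
#' @return Data frame with one row per check: `check`, `observed`
#'   (signed percentage or difference), `pass`.
#' @export
directional_checks <- function(report) {
  pct <- report$pct
  val <- function(cond, metric) {
    i <- match(cond, pct$condition)
    if (is.na(i)) NA_real_ else pct[[metric]][i]
  }
  out <- list()
  exp <- directional_expectations()
  for (i in seq_len(nrow(exp))) {
    v <- val(exp$condition[i], exp$metric[i])
    out[[length(out) + 1]] <- data.frame(
      check = sprintf("%s: %s %s vs baseline", exp$condition[i],
                      exp$metric[i], if (exp$sign[i] > 0) "increases" else "decreases"),
      observed = v, pass = !is.na(v) && sign(v) == exp$sign[i])
  }
  for (mode in c("central", "peripheral")) {
    for (metric in c("cbf", "total_flow")) {
      v <- vapply(c(3000, 3500, 4000),
                  function(r) val(paste0(mode, "_", r), metric), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        check = sprintf("%s: %s increases with rpm", mode, metric),
        observed = min(diff(v)), pass = !anyNA(v) && all(diff(v) > 0))
    }
  }
  for (mode in c("central", "peripheral")) {
    for (r in c(3000, 3500, 4000)) {
      v_on <- val(paste0(mode, "_", r, "_iabp"), "aop_mean")
      v_off <- val(paste0(mode, "_", r), "aop_mean")
      out[[length(out) + 1]] <- data.frame(
        check = sprintf("%s_%d: mean AoP higher with IABP", mode, r),
        observed = v_on - v_off, pass = !anyNA(c(v_on, v_off)) && v_on > v_off)
    }
  }
  do.call(rbind, out)
}

#' Export a study report
#'
#' Writes `absolute.csv` (13 conditions x metrics), `pct_change.csv`
#' (12 x metrics) and `summary.json` (provenance plus the directional check
#' results). The CSVs round-trip numerically.
#'
#' @param report A [run_study()] result.
#' @param path Output directory (created if needed).
#' @return Named character vector of the written files, invisibly.
#' @export
export_report <- function(report, path) {
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE))
      stop("cannot create output directory ", path, call. = FALSE)
  files <- c(absolute = file.path(path, "absolute.csv"),
             pct = file.path(path, "pct_change.csv"),
             summary = file.path(path, "summary.json"))
  utils::write.csv(report$absolute, files[["absolute"]], row.names = FALSE)
  utils::write.csv(report$pct, files[["pct"]], row.names = FALSE)
  jsonlite::write_json(
    list(provenance = report$provenance,
         directional_checks = directional_checks(report)),
    files[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Read back an exported study report
#'
#' @param path Directory written by [export_report()].
#' @return List with `absolute`, `pct` data frames and `provenance`.
#' @export
read_report <- function(path) {
  s <- jsonlite::read_json(file.path(path, "summary.json"),
                           simplifyVector = TRUE)
  num <- function(df) {
    for (m in intersect(metric_names(), names(df)))
      df[[m]] <- as.numeric(df[[m]])
    df
  }
  list(absolute = num(utils::read.csv(file.path(path, "absolute.csv"))),
       pct = num(utils::read.csv(file.path(path, "pct_change.csv"))),
       provenance = s$provenance)
}
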