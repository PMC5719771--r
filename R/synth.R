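# Synthetic TLD studies with known ground truth.

#' Parameters of the synthetic TLD study generator
#'
#' Defaults mirror the reference measurement campaign: a batch of 60
#' dosimeters of which 8 are stability controls, two dosimeters per
#' measured depth, calibration exposures of 8 dosimeters each at 25, 50 and
#' 100 cGy, controls always exposed to 100 cGy, lognormal per-dosimeter
#' sensitivities, per-session reader drift and multiplicative read noise.
#'
#' @param n_dosimeters batch size (>= 10)
#' @param n_controls stability-control dosimeters
#' @param sensitivity_sd sd of log sensitivities (lognormal around 1)
#' @param zero_dose_mean,zero_dose_sd per-dosimeter zero-dose signal (reader
#'   units)
#' @param session_drift_sd sd of log per-session reader drift
#' @param read_noise_cv coefficient of variation of multiplicative read noise
#' @param calibration_doses calibration dose levels in cGy
#' @param calibration_reps dosimeters per calibration dose level
#' @param control_dose control exposure in cGy
#' @param true_calibration named vector `c(A=, B=)`: the latent reading for a
#'   dose D is `(D - B)/A`
#' @param seed integer seed
#' @return object of class `synthetic_study_params`
#' @export
synthetic_study_params <- function(n_dosimeters = 60, n_controls = 8,
                                   sensitivity_sd = 0.05,
                                   zero_dose_mean = 150, zero_dose_sd = 30,
                                   session_drift_sd = 0.02,
                                   read_noise_cv = 0.01,
                                   calibration_doses = c(25, 50, 100),
                                   calibration_reps = 8,
                                   control_dose = 100,
                                   true_calibration = c(A = 9e-4, B = 1.4243),
                                   seed = 1) {
  if (n_dosimeters < 10) stop("n_dosimeters must be >= 10")
  if (any(c(sensitivity_sd, zero_dose_sd, session_drift_sd, read_noise_cv) < 0))
    stop("spread parameters must be >= 0")
  structure(as.list(environment()), class = "synthetic_study_params")
}

#' Generate a synthetic TLD study with hidden ground truth
#'
#' Emits a raw-readings table in the schema of [process_tld_study()]:
#' zero-dose and reference-exposure readings for the whole batch
#' (characterization session), a calibration session (the FCm reference
#' session) with control and calibration exposures, and measurement sessions
#' with two dosimeters per depth plus controls. A raw reading for dose D by
#' dosimeter i in session m is
#' `TL0_i + S_i * drift_m * (D - B)/A * (1 + noise)`.
#' The generating truth (sensitivities, drifts, true doses) is returned
#' separately and never flows into the readings table.
#'
#' @param true_depth_doses data.frame with columns `depth_cm`, `dose_cGy`
#'   (all >= 0)
#' @param params a [synthetic_study_params()]
#' @return list with `readings` (data.frame) and `truth` (list)
#' @export
generate_tld_study <- function(true_depth_doses,
                               params = synthetic_study_params()) {
  stopifnot(inherits(params, "synthetic_study_params"),
            is.data.frame(true_depth_doses),
            all(c("depth_cm", "dose_cGy") %in% names(true_depth_doses)))
  if (any(true_depth_doses$dose_cGy < 0)) stop("true doses must be >= 0")
  p <- params
  set.seed(p$seed)
  ids <- sprintf("D%02d", seq_len(p$n_dosimeters))
  S <- stats::rlnorm(p$n_dosimeters, -p$sensitivity_sd^2 / 2, p$sensitivity_sd)
  TL0 <- pmax(1, stats::rnorm(p$n_dosimeters, p$zero_dose_mean, p$zero_dose_sd))
  names(S) <- names(TL0) <- ids
  controls <- ids[seq_len(p$n_controls)]
  pool <- setdiff(ids, controls)
  A <- p$true_calibration[["A"]]; B <- p$true_calibration[["B"]]
  latent <- function(D) (D - B) / A

  rows <- list()
  emit <- function(dos, session, role, dose = NA_real_, depth = NA_real_,
                   drift = 1) {
    n <- length(dos)
    dose <- rep(dose, length.out = n)
    depth <- rep(depth, length.out = n)
    noise <- 1 + stats::rnorm(n, 0, p$read_noise_cv)
    raw <- ifelse(is.na(dose),
                  TL0[dos] * noise,
                  TL0[dos] + S[dos] * drift * latent(dose) * noise)
    rows[[length(rows) + 1]] <<- data.frame(
      dosimeter_id = dos, session_id = session, role = role, raw = raw,
      dose_level_cGy = dose, depth_cm = depth, stringsAsFactors = FALSE)
  }

  # characterization session: triple zero readouts and a triple common
  # reference exposure (standard batch-characterization practice)
  drift_char <- stats::rlnorm(1, 0, p$session_drift_sd)
  for (rep in 1:3) {
    emit(ids, "char", "zero")
    emit(ids, "char", "reference", dose = p$control_dose, drift = drift_char)
  }

  # calibration session (FCm reference session)
  drift_cal <- stats::rlnorm(1, 0, p$session_drift_sd)
  emit(controls, "cal", "control", dose = p$control_dose, drift = drift_cal)
  for (k in seq_along(p$calibration_doses)) {
    dos <- pool[((k - 1) * p$calibration_reps + 1):(k * p$calibration_reps)]
    for (d in dos)
      emit(d, "cal", "calibration", dose = p$calibration_doses[k],
           drift = drift_cal)
  }

  # measurement sessions: two dosimeters per depth, <= 26 depths per session
  depths <- true_depth_doses$depth_cm
  doses <- true_depth_doses$dose_cGy
  per_session <- floor(length(pool) / 2)
  n_sessions <- ceiling(length(depths) / per_session)
  drifts <- stats::rlnorm(n_sessions, 0, p$session_drift_sd)
  for (s in seq_len(n_sessions)) {
    sid <- sprintf("m%02d", s)
    emit(controls, sid, "control", dose = p$control_dose, drift = drifts[s])
    idx <- ((s - 1) * per_session + 1):min(s * per_session, length(depths))
    for (j in seq_along(idx)) {
      dos <- pool[c(2 * j - 1, 2 * j)]
      emit(dos, sid, "measurement", dose = rep(doses[idx[j]], 2),
           depth = rep(depths[idx[j]], 2), drift = drifts[s])
    }
  }
  readings <- do.call(rbind, rows)
  rownames(readings) <- NULL
  list(readings = readings,
       truth = list(S = S, TL0 = TL0, drift_char = drift_char,
                    drift_cal = drift_cal, drift_meas = drifts,
                    true_calibration = p$true_calibration,
                    true_depth_doses = true_depth_doses))
}
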