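# TLD reading-to-dose chain: batch characterization, session stability
# control, reading correction, linear calibration, dose recovery with
# uncertainty propagation.

#' Characterize a TLD batch
#'
#' Computes the batch mean zero-dose reading `TL0`, per-dosimeter sensitivity
#' factors `Si` (net reference reading over the batch mean net reference
#' reading, so `mean(Si) = 1`), and the zero-dose spread used for the lower
#' detection limit.
#'
#' @param zero_readings data.frame with columns `dosimeter_id`, `raw`
#'   (unexposed readings, >= 1 per dosimeter)
#' @param reference_readings data.frame with columns `dosimeter_id`, `raw`
#'   (all dosimeters exposed to a common reference dose)
#' @return object of class `batch_characterization`: `TL0`, `S` (named),
#'   `zero_sd`, `n`
#' @export
characterize_batch <- function(zero_readings, reference_readings) {
  for (df in list(zero_readings, reference_readings))
    stopifnot(is.data.frame(df), all(c("dosimeter_id", "raw") %in% names(df)))
  ids <- sort(unique(reference_readings$dosimeter_id))
  if (length(ids) < 2) stop("need at least 2 dosimeters")
  if (!all(ids %in% zero_readings$dosimeter_id))
    stop("missing zero readings for: ",
         paste(setdiff(ids, zero_readings$dosimeter_id), collapse = ", "))
  TL0 <- mean(zero_readings$raw)
  zero_sd <- stats::sd(zero_readings$raw)
  net <- vapply(ids, function(i)
    mean(reference_readings$raw[reference_readings$dosimeter_id == i]) - TL0,
    numeric(1))
  if (any(net <= 0))
    stop("zero net reference signal for dosimeter(s): ",
         paste(ids[net <= 0], collapse = ", "))
  S <- net / mean(net)
  names(S) <- ids
  structure(list(TL0 = TL0, S = S, zero_sd = zero_sd, n = length(ids)),
            class = "batch_characterization")
}

#' @export
print.batch_characterization <- function(x, ...) {
  cat(sprintf("<batch_characterization> %d dosimeters, TL0 = %.1f (sd %.1f), S in [%.3f, %.3f]\n",
              x$n, x$TL0, x$zero_sd, min(x$S), max(x$S)))
  invisible(x)
}

#' Session stability-control factor
#'
#' The first call (with `ref = NULL`) establishes the reference reading
#' `TLref` as the mean over the control dosimeters of `(TL_i - TL0)/S_i`;
#' subsequent calls compute the session correction factor
#' `FCm = mean((TL_im - TL0)/S_i) / TLref`.
#'
#' @param control_readings data.frame with columns `dosimeter_id`, `raw` for
#'   the control-dosimeter set of this session
#' @param char a [characterize_batch()] result
#' @param ref a previous `session_control` (or NULL to establish the
#'   reference session)
#' @param session_id identifier of this session
#' @return object of class `session_control`: `TLref`, `FCm` (named by
#'   session), `controls`
#' @export
session_factor <- function(control_readings, char, ref = NULL,
                           session_id = "ref") {
  stopifnot(inherits(char, "batch_characterization"))
  ids <- sort(unique(control_readings$dosimeter_id))
  if (!all(ids %in% names(char$S)))
    stop("control dosimeter(s) not in batch: ",
         paste(setdiff(ids, names(char$S)), collapse = ", "))
  if (!is.null(ref) && !setequal(ids, ref$controls))
    stop("missing control dosimeter(s): ",
         paste(setdiff(ref$controls, ids), collapse = ", "))
  m <- mean((control_readings$raw - char$TL0) / char$S[control_readings$dosimeter_id])
  if (is.null(ref)) {
    structure(list(TLref = m, FCm = stats::setNames(1, session_id),
                   controls = ids), class = "session_control")
  } else {
    f <- m / ref$TLref
    if (f < 0.5 || f > 2)
      warning(sprintf("session '%s': FCm = %.3f outside [0.5, 2]; possible reader fault",
                      session_id, f))
    ref$FCm[session_id] <- f
    ref
  }
}

#' @export
print.session_control <- function(x, ...) {
  cat(sprintf("<session_control> TLref = %.1f, %d session(s): %s\n",
              x$TLref, length(x$FCm),
              paste(sprintf("%s=%.3f", names(x$FCm), x$FCm), collapse = ", ")))
  invisible(x)
}

#' Correct raw TLD readings
#'
#' `TLcorr = ((raw - TL0)/Si) / FCm`. Negative net readings are propagated
#' (not clamped) so that low-dose estimates stay unbiased.
#'
#' @param raw raw readings (reader units, vectorized)
#' @param char a [characterize_batch()] result
#' @param session a [session_factor()] result
#' @param session_id session of the readings
#' @param dosimeter_id dosimeter ids (recycled against `raw`)
#' @return corrected readings (reader units)
#' @export
correct_reading <- function(raw, char, session, session_id, dosimeter_id) {
  stopifnot(inherits(char, "batch_characterization"),
            inherits(session, "session_control"))
  if (!session_id %in% names(session$FCm))
    stop("no FCm for session '", session_id, "'")
  if (!all(dosimeter_id %in% names(char$S)))
    stop("dosimeter(s) not in batch: ",
         paste(setdiff(dosimeter_id, names(char$S)), collapse = ", "))
  ((raw - char$TL0) / char$S[dosimeter_id]) / session$FCm[[session_id]]
}

#' Fit the TLD calibration curve
#'
#' Ordinary least squares of dose (cGy) on the mean corrected reading of
#' each dose group: `Dw = A * TLcorr + B`.
#'
#' @param groups data.frame with columns `dose_cGy` and `tlcorr` (corrected
#'   readings; >= 2 distinct dose levels)
#' @return object of class `calibration_curve`: `A` (cGy per reader unit),
#'   `B` (cGy), `residual_sd` (cGy), `cov` (2x2 covariance of (B, A))
#' @export
fit_calibration <- function(groups) {
  stopifnot(is.data.frame(groups), all(c("dose_cGy", "tlcorr") %in% names(groups)))
  lv <- sort(unique(groups$dose_cGy))
  if (length(lv) < 2) stop("need at least 2 distinct dose levels")
  mr <- vapply(lv, function(d) mean(groups$tlcorr[groups$dose_cGy == d]),
               numeric(1))
  fit <- stats::lm(lv ~ mr)
  A <- unname(coef(fit)[2]); B <- unname(coef(fit)[1])
  if (!is.finite(A) || A <= 0) stop("calibration slope must be positive")
  covm <- matrix(0, 2, 2, dimnames = list(c("B", "A"), c("B", "A")))
  rsd <- 0
  if (length(lv) > 2) {
    rsd <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
    X <- cbind(1, mr)
    covm[] <- rsd^2 * solve(crossprod(X))
  }
  calibration_curve(A, B, residual_sd = rsd, cov = covm)
}

#' Construct a calibration curve
#' @param A slope, cGy per reader unit (> 0)
#' @param B intercept, cGy
#' @param residual_sd residual standard deviation of the fit, cGy
#' @param cov 2x2 covariance matrix of (intercept, slope)
#' @return object of class `calibration_curve`
#' @export
calibration_curve <- function(A, B, residual_sd = 0,
                              cov = matrix(0, 2, 2)) {
  if (A <= 0) stop("A must be > 0")
  structure(list(A = A, B = B, residual_sd = residual_sd, cov = cov),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> Dw = %.6g * TLcorr + %.4f cGy (residual sd %.3g cGy)\n",
              x$A, x$B, x$residual_sd))
  invisible(x)
}

#' Convert replicate corrected readings at one depth to dose-to-water
#'
#' `Dw = A * mean(TLcorr) + B`. The standard uncertainty combines, in
#' quadrature, the replicate spread (type A), the session-factor spread and
#' the calibration-fit covariance.
#'
#' @param pair corrected readings of the replicate dosimeters at one depth
#'   (the reference protocol uses 2)
#' @param cal a [calibration_curve()]
#' @param fcm_rel_u relative standard uncertainty of the session factor
#' @param ldl_reading optional corrected-reading detection threshold; means
#'   below it are flagged unreliable
#' @return list: `dose_cGy`, `u_cGy`, `rel_u`, `reliable`
#' @export
reading_to_dose <- function(pair, cal, fcm_rel_u = 0, ldl_reading = NULL) {
  stopifnot(inherits(cal, "calibration_curve"), length(pair) >= 1)
  m <- mean(pair)
  dose <- cal$A * m + cal$B
  u_rep <- if (length(pair) > 1) cal$A * stats::sd(pair) / sqrt(length(pair)) else 0
  x <- c(1, m)
  u_fit2 <- as.numeric(t(x) %*% cal$cov %*% x)
  u_fc <- abs(cal$A * m) * fcm_rel_u
  u <- sqrt(u_rep^2 + u_fit2 + u_fc^2)
  list(dose_cGy = dose, u_cGy = u,
       rel_u = if (dose > 0) u / dose else Inf,
       reliable = is.null(ldl_reading) || m >= ldl_reading)
}

#' Lower detection limit of the TLD system
#'
#' Dose-equivalent of a net corrected reading of three zero-dose standard
#' deviations, through the calibration curve.
#'
#' @param char a [characterize_batch()] result
#' @param cal a [calibration_curve()]
#' @return LDL in cGy
#' @export
detection_limit <- function(char, cal) {
  stopifnot(inherits(char, "batch_characterization"),
            inherits(cal, "calibration_curve"))
  cal$A * (3 * char$zero_sd) + cal$B
}

#' Process a complete TLD study table
#'
#' Runs the full chain on a raw-readings table: batch characterization from
#' `zero` and `reference` rows, session factors from `control` rows (the
#' first session with controls, in order of appearance, is the reference
#' session), calibration fit from `calibration` rows, and per-depth doses
#' from `measurement` rows.
#'
#' @param study data.frame with columns `dosimeter_id`, `session_id`, `role`
#'   (`zero`/`reference`/`control`/`calibration`/`measurement`), `raw`,
#'   `dose_level_cGy` (calibration rows), `depth_cm` (measurement rows)
#' @return object of class `tld_results`: `char`, `session`, `cal`,
#'   `ldl_cGy` and `doses` (data.frame depth_cm, dose_cGy, u_cGy, rel_u,
#'   reliable)
#' @export
process_tld_study <- function(study) {
  req <- c("dosimeter_id", "session_id", "role", "raw")
  if (!all(req %in% names(study)))
    stop("missing column(s): ", paste(setdiff(req, names(study)), collapse = ", "))
  char <- characterize_batch(study[study$role == "zero", ],
                             study[study$role == "reference", ])
  ctl <- study[study$role == "control", ]
  if (!nrow(ctl)) stop("study has no control readings")
  sess <- NULL
  for (sid in unique(ctl$session_id)) {
    sess <- session_factor(ctl[ctl$session_id == sid, ], char, sess, sid)
  }
  # FCm spread over the controls of each session, for the uncertainty budget
  fcm_rel_u <- {
    s1 <- ctl[ctl$session_id == names(sess$FCm)[1], ]
    v <- (s1$raw - char$TL0) / char$S[s1$dosimeter_id]
    stats::sd(v) / mean(v) / sqrt(nrow(s1))
  }
  cal_rows <- study[study$role == "calibration", ]
  if (!nrow(cal_rows)) stop("study has no calibration readings")
  cal_rows$tlcorr <- correct_reading(cal_rows$raw, char, sess,
                                     cal_rows$session_id[1],
                                     cal_rows$dosimeter_id)
  cal <- fit_calibration(data.frame(dose_cGy = cal_rows$dose_level_cGy,
                                    tlcorr = cal_rows$tlcorr))
  ldl <- detection_limit(char, cal)
  meas <- study[study$role == "measurement", ]
  doses <- NULL
  if (nrow(meas)) {
    meas$tlcorr <- NA_real_
    for (sid in unique(meas$session_id)) {
      k <- meas$session_id == sid
      meas$tlcorr[k] <- correct_reading(meas$raw[k], char, sess, sid,
                                        meas$dosimeter_id[k])
    }
    doses <- do.call(rbind, lapply(sort(unique(meas$depth_cm)), function(d) {
      r <- reading_to_dose(meas$tlcorr[meas$depth_cm == d], cal,
                           fcm_rel_u = fcm_rel_u,
                           ldl_reading = 3 * char$zero_sd)
      data.frame(depth_cm = d, dose_cGy = r$dose_cGy, u_cGy = r$u_cGy,
                 rel_u = r$rel_u, reliable = r$reliable)
    }))
  }
  structure(list(char = char, session = sess, cal = cal, ldl_cGy = ldl,
                 fcm_rel_u = fcm_rel_u, doses = doses),
            class = "tld_results")
}

#' @export
print.tld_results <- function(x, ...) {
  print(x$char); print(x$session); print(x$cal)
  cat(sprintf("  LDL %.2f cGy; %d measured depths\n", x$ldl_cGy,
              if (is.null(x$doses)) 0L else nrow(x$doses)))
  invisible(x)
}
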