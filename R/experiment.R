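# End-to-end experiment driver and file I/O.

#' Experiment configuration
#'
#' @param field_sides square field sides in cm (default the reference set
#'   1, 2, 5, 10)
#' @param nominal nominal MV
#' @param ssd source-to-surface distance, cm
#' @param lung_density lung/cork density, g/cm^3
#' @param methods heterogeneity-correction methods to apply
#' @param n_histories histories per heterogeneous simulation
#' @param beam_data_histories histories per homogeneous beam-data simulation
#' @param measurement_depths depths (cm) of the synthetic TLD measurements
#' @param tld_params a [synthetic_study_params()] (seed is re-derived from
#'   `seed`)
#' @param fcor_depths depths at which detector perturbation factors are
#'   simulated and applied (NULL to skip the perturbation stage)
#' @param seed master seed; every stage seed derives from it
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(field_sides = c(1, 2, 5, 10), nominal = 15,
                              ssd = 100, lung_density = 0.26,
                              methods = c("batho", "mbatho", "etar"),
                              n_histories = 2e6, beam_data_histories = 2e6,
                              measurement_depths = seq(0.75, 27.75, by = 1),
                              tld_params = synthetic_study_params(),
                              fcor_depths = NULL, seed = 1) {
  if (any(field_sides <= 0)) stop("field sides must be > 0")
  methods <- if (length(methods)) match.arg(methods, c("batho", "mbatho", "etar"),
                                            several.ok = TRUE) else character(0)
  structure(as.list(environment()), class = "experiment_config")
}

#' Run the full comparison experiment
#'
#' For each field size: simulate the heterogeneous-phantom PDD with the
#' Monte Carlo engine; generate and process a synthetic TLD study whose true
#' doses follow the simulated curve (dose-to-medium conversion and optional
#' detector perturbation applied in reverse by the generator and forward by
#' the processing chain); compute Batho/modified-Batho/equivalent-TAR
#' corrected PDDs from Monte Carlo homogeneous beam data; and form ratio
#' curves and interface metrics against the Monte Carlo reference.
#'
#' @param config an [experiment_config()]
#' @param outdir optional output directory for CSV/JSON artifacts
#' @param phantom the heterogeneous phantom (default [make_reference_phantom()])
#' @return object of class `experiment_bundle`: `beam_data`, per-field list
#'   `fields` (each with `mc_pdd`, `tld`, `tld_pdd`, `corrected`, `ratios`,
#'   `metrics`), and `manifest`
#' @export
run_experiment <- function(config = experiment_config(), outdir = NULL,
                           phantom = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(phantom)) phantom <- make_reference_phantom(config$lung_density)
  E0 <- mean_secondary_electron_energy(synthesize_spectrum(config$nominal))

  # beam data once, over the requested radii plus small and large bracketing
  # fields so that the equivalent-TAR density-scaled radius stays in range
  bd_sides <- sort(unique(c(0.4, config$field_sides,
                            1.25 * max(config$field_sides))))
  bd <- homogeneous_beam_data(
    bd_sides, transport_options(n_histories = config$beam_data_histories,
                                seed = config$seed + 1000L),
    nominal = config$nominal, ssd = config$ssd)

  fields <- list()
  for (i in seq_along(config$field_sides)) {
    L <- config$field_sides[i]
    beam <- beam_config(nominal = config$nominal, square_side = L,
                        ssd = config$ssd)
    opt <- transport_options(n_histories = config$n_histories,
                             seed = config$seed + 10L * i)
    mc <- simulate_depth_dose(phantom, beam, opt)
    mc_pdd <- normalize_pdd(mc)

    # detector perturbation factors (optional)
    fcor <- NULL
    if (!is.null(config$fcor_depths)) {
      fopt <- transport_options(n_histories = config$n_histories,
                                seed = config$seed + 10L * i + 5L)
      fcor <- perturbation_profile(phantom, beam, config$fcor_depths, fopt)
    }

    # synthetic TLD study: truth = simulated dose-to-medium, scaled to
    # 100 cGy at dmax; the water-calibrated TLD reads dose-to-water, and the
    # detector perturbs its surroundings, so the generator maps medium dose
    # to an expected reading via the inverse conversions
    d_meas <- config$measurement_depths
    truth_med <- 100 * stats::approx(mc_pdd$depth, mc_pdd$pdd, d_meas,
                                     ties = "ordered")$y / 100
    spr <- vapply(material_at_depth(phantom, d_meas), function(mn)
      stopping_power_ratio(get_material("water"), get_material(mn), E0),
      numeric(1))
    reading_dose <- truth_med * spr # dose-to-water the TLD responds to
    if (!is.null(fcor)) {
      f <- stats::approx(fcor$depth_cm, fcor$fcor, d_meas, rule = 2,
                         ties = "ordered")$y
      reading_dose <- reading_dose * f
    }
    tp <- config$tld_params
    tp$seed <- config$seed + 100L * i
    study <- generate_tld_study(
      data.frame(depth_cm = d_meas, dose_cGy = reading_dose), tp)
    tld <- process_tld_study(study$readings)
    doses <- tld$doses
    # dose-to-medium conversion and perturbation correction
    doses$dose <- doses$dose_cGy /
      vapply(material_at_depth(phantom, doses$depth_cm), function(mn)
        stopping_power_ratio(get_material("water"), get_material(mn), E0),
        numeric(1))
    if (!is.null(fcor)) {
      f <- stats::approx(fcor$depth_cm, fcor$fcor, doses$depth_cm, rule = 2,
                         ties = "ordered")$y
      doses <- apply_perturbation(doses, data.frame(depth_cm = doses$depth_cm,
                                                    fcor = f))
    }
    tld_pdd <- normalize_pdd(data.frame(depth_cm = doses$depth_cm,
                                        dose = doses$dose,
                                        rel_se = doses$rel_u))

    # analytic corrections on the homogeneous curve for this field
    hom_pdd <- .beam_data_pdd(bd, beam, config$ssd)
    corrected <- ratios <- metrics <- list()
    for (m in config$methods) {
      corrected[[m]] <- corrected_pdd(m, hom_pdd, phantom, beam, bd)
      keep <- mc_pdd$depth <= phantom$total_depth
      mc_in <- structure(list(depth = mc_pdd$depth[keep],
                              pdd = mc_pdd$pdd[keep],
                              rel_se = mc_pdd$rel_se[keep],
                              dmax = mc_pdd$dmax), class = "pdd_curve")
      ratios[[m]] <- ratio_curve(corrected[[m]], mc_in)
      metrics[[m]] <- interface_metrics(ratios[[m]], phantom)
    }
    fields[[as.character(L)]] <- list(
      field_side = L, mc = mc, mc_pdd = mc_pdd, fcor = fcor, tld = tld,
      tld_pdd = tld_pdd, corrected = corrected, ratios = ratios,
      metrics = metrics)
  }

  manifest <- list(
    seed = config$seed, nominal = config$nominal, ssd = config$ssd,
    field_sides = config$field_sides, methods = config$methods,
    lung_density = config$lung_density,
    n_histories = config$n_histories,
    beam_data_histories = config$beam_data_histories,
    E0_MeV = E0,
    package_version = as.character(utils::packageVersion("lungpdd")),
    config_hash = .config_hash(config))
  bundle <- structure(list(beam_data = bd, fields = fields,
                           manifest = manifest),
                      class = "experiment_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# PDD of the homogeneous water phantom for one field, reconstructed from the
# beam-data TMR by the inverse of the TMR conversion
.beam_data_pdd <- function(bd, beam, ssd) {
  keep <- bd$depths <= 30
  d <- bd$depths[keep]
  tmr <- vapply(d, function(di) .beam_lookup(bd, "TMR", di, beam$equivalent_radius),
                numeric(1))
  pdd <- tmr * ((ssd + bd$dmax) / (ssd + d))^2
  normalize_pdd(data.frame(depth_cm = d, dose = pdd))
}

.config_hash <- function(config) {
  js <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  sum(utf8ToInt(as.character(js)) * seq_len(nchar(as.character(js)))) %% 2^31
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> fields: %s cm; methods: %s\n",
              paste(names(x$fields), collapse = ", "),
              paste(x$manifest$methods, collapse = ", ")))
  for (f in x$fields) {
    cat(sprintf("  %gx%g cm^2: MC dmax %.2f cm", f$field_side, f$field_side,
                f$mc_pdd$dmax))
    for (m in names(f$metrics))
      cat(sprintf("; %s max lung disc. %.0f%%", m,
                  f$metrics[[m]]$max_lung_discrepancy_pct))
    cat("\n")
  }
  invisible(x)
}

# ---- file I/O --------------------------------------------------------------

#' Write / read a PDD or dose curve as CSV
#'
#' Full-precision lossless round trip of the numeric fields.
#' @param curve a `pdd_curve` or `dose_profile`
#' @param path file path
#' @return `read_curve_csv` returns a data.frame
#' @export
write_curve_csv <- function(curve, path) {
  df <- if (inherits(curve, "pdd_curve"))
    data.frame(depth_cm = curve$depth, value = curve$pdd, rel_se = curve$rel_se)
  else if (inherits(curve, "dose_profile"))
    data.frame(depth_cm = curve$depth, value = curve$dose, rel_se = curve$rel_se)
  else as.data.frame(curve)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a TLD readings table from CSV
#'
#' Validates the [process_tld_study()] schema and reports missing columns by
#' name.
#' @param path CSV path with columns dosimeter_id, session_id, role, raw,
#'   dose_level_cGy, depth_cm
#' @return data.frame
#' @export
read_readings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("dosimeter_id", "session_id", "role", "raw", "dose_level_cGy",
           "depth_cm")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("readings file missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read an experiment configuration from YAML or JSON
#'
#' Unknown material names in a `phantom` block are rejected with the list of
#' available materials.
#' @param path file path (.yaml/.yml or .json)
#' @return an [experiment_config()]
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$phantom)) {
    bad <- setdiff(raw$phantom$materials, list_materials())
    if (length(bad))
      stop("unknown material(s): ", paste(bad, collapse = ", "),
           "; available: ", paste(list_materials(), collapse = ", "))
  }
  known <- names(formals(experiment_config))
  do.call(experiment_config, raw[intersect(names(raw), known)])
}

#' Write an experiment bundle to a directory
#'
#' Emits per-field CSV curves, JSON metrics and a manifest; every artifact
#' is regenerable from the manifest alone via [run_experiment()].
#' @param bundle an `experiment_bundle`
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(bundle$fields)) {
    f <- bundle$fields[[nm]]
    tag <- gsub("[^0-9a-zA-Z]", "_", nm)
    write_curve_csv(f$mc_pdd, file.path(outdir, sprintf("mc_pdd_%s.csv", tag)))
    write_curve_csv(f$tld_pdd, file.path(outdir, sprintf("tld_pdd_%s.csv", tag)))
    for (m in names(f$corrected))
      write_curve_csv(f$corrected[[m]],
                      file.path(outdir, sprintf("corrected_%s_%s.csv", m, tag)))
    for (m in names(f$ratios)) {
      r <- f$ratios[[m]]
      write_curve_csv(data.frame(depth_cm = r$depth, value = r$ratio,
                                 rel_se = r$rel_se),
                      file.path(outdir, sprintf("ratio_%s_%s.csv", m, tag)))
      met <- f$metrics[[m]]
      jsonlite::write_json(
        list(method = m, field_side_cm = f$field_side,
             lung_overdose_pct = met$lung_overdose_pct,
             soft_underdose_pct = met$soft_underdose_pct,
             max_lung_discrepancy_pct = met$max_lung_discrepancy_pct),
        file.path(outdir, sprintf("metrics_%s_%s.json", m, tag)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  invisible(outdir)
}
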