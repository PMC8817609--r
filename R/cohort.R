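# Fraction of LV myocardial mass subtended by each vessel territory; used
# to scale the per-vessel inlet flow, since each synthetic tree is a single
# epicardial vessel rather than the whole coronary circulation.
TERRITORY_MASS_FRACTION <- c(LAD = 0.50, LCX = 0.25, RCA = 0.25)

# Index recorded when the prescribed-flow solve collapses (non-positive
# distal pressure): physically, a subtotal occlusion whose distal pressure
# is unmeasurably low.
PRESSURE_COLLAPSE_FLOOR <- 0.05

#' Parameters of a synthetic vessel cohort
#'
#' Defines the population the cohort generator draws from. Defaults
#' emulate the structure of a 36-vessel single-lesion study population:
#' LAD/LCX/RCA mix 72/11/17%, visually estimated diameter stenosis between
#' 30 and 90%, and independent Gaussian measurement noise on the
#' "invasive" iFR and FFR readings.
#'
#' @param n_vessels number of vessels (one per synthetic patient).
#' @param vessel_mix named proportions for LAD/LCX/RCA (must sum to 1).
#' @param ds_range range of the uniform diameter-stenosis draw (%).
#' @param lv_mass_mean,lv_mass_sd LV mass distribution (g), truncated
#'   above `lv_mass_min`.
#' @param lv_mass_min truncation floor for LV mass (g).
#' @param pa_mean,pa_sd diastolic aortic pressure distribution (mmHg),
#'   truncated above `pa_min`.
#' @param pa_min truncation floor for Pa (mmHg).
#' @param sigma_ifr,sigma_ffr SD of the additive measurement noise on the
#'   invasive iFR / FFR.
#' @param hyperemic_factor fixed hyperemic flow multiplier h.
#' @param step solver resampling step (mm).
#' @param seed master seed; per-vessel child streams are derived from it,
#'   so the first k vessels are stable when `n_vessels` changes.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(n_vessels = 36,
                          vessel_mix = c(LAD = 0.72, LCX = 0.11, RCA = 0.17),
                          ds_range = c(30, 90),
                          lv_mass_mean = 120, lv_mass_sd = 20, lv_mass_min = 50,
                          pa_mean = 80, pa_sd = 8, pa_min = 40,
                          sigma_ifr = 0.02, sigma_ffr = 0.03,
                          hyperemic_factor = 3,
                          step = 0.5,
                          seed = 1L) {
  if (n_vessels < 1) stop_invalid("n_vessels must be >= 1")
  if (abs(sum(vessel_mix) - 1) > 1e-8) stop_invalid("vessel_mix must sum to 1")
  if (sigma_ifr < 0 || sigma_ffr < 0) stop_invalid("noise SDs must be >= 0")
  structure(
    list(n_vessels = as.integer(n_vessels), vessel_mix = vessel_mix,
         ds_range = ds_range, lv_mass_mean = lv_mass_mean,
         lv_mass_sd = lv_mass_sd, lv_mass_min = lv_mass_min,
         pa_mean = pa_mean, pa_sd = pa_sd, pa_min = pa_min,
         sigma_ifr = sigma_ifr, sigma_ffr = sigma_ffr,
         hyperemic_factor = hyperemic_factor, step = step,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

rnorm_trunc <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
}

#' Simulate one vessel of the cohort
#'
#' Draws patient and lesion parameters, builds a synthetic stenosed tree,
#' solves the resting and hyperemic pressure fields, reads the computed
#' indices at the sensor point, and adds Gaussian measurement noise to
#' obtain the simulated "invasive" iFR and FFR (clipped to (0, 1]). A
#' solve in which the prescribed flow cannot be sustained (non-positive
#' distal pressure, possible for subtotal occlusions under hyperemia) is
#' recorded at the 0.05 collapse floor and flagged. Deterministic for a
#' fixed seed.
#'
#' @param params a [cohort_params()].
#' @param seed integer seed for this vessel's stream.
#' @param vessel_id id recorded in the output row.
#' @return a one-row data frame with columns `vessel_id`, `vessel_type`,
#'   `ds_percent`, `ifr_ct`, `ffr_ct`, `ifr_invasive`, `ffr_invasive`,
#'   `sig_ifr_ct`, `sig_ifr_invasive`, `sig_ffr_invasive`, `collapsed`.
#' @export
simulate_vessel <- function(params, seed, vessel_id = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  draws <- with_seed(seed, {
    vtype <- sample(names(params$vessel_mix), 1, prob = params$vessel_mix)
    list(
      vtype = vtype,
      lv_mass = rnorm_trunc(params$lv_mass_mean, params$lv_mass_sd,
                            params$lv_mass_min),
      pa = rnorm_trunc(params$pa_mean, params$pa_sd, params$pa_min),
      ds = stats::runif(1, params$ds_range[1], params$ds_range[2]),
      center_frac = stats::runif(1, 0.35, 0.55),
      lesion_len = stats::runif(1, 15, 25),
      radius_jitter = stats::runif(1, 0.95, 1.05),
      eps_ifr = stats::rnorm(1, 0, params$sigma_ifr),
      eps_ffr = stats::rnorm(1, 0, params$sigma_ffr),
      tree_seed = sample.int(.Machine$integer.max - 1L, 1)
    )
  })
  base <- VESSEL_DEFAULTS[[draws$vtype]]
  tree <- generate_synthetic_tree(
    vessel_type = draws$vtype,
    inlet_radius = base$inlet_radius * draws$radius_jitter,
    stenoses = list(list(center_frac = draws$center_frac,
                         length_mm = draws$lesion_len,
                         severity = draws$ds)),
    step = params$step,
    seed = draws$tree_seed
  )
  bc <- boundary_conditions(
    pa_diastolic = draws$pa,
    lv_mass = TERRITORY_MASS_FRACTION[[draws$vtype]] * draws$lv_mass,
    hyperemic_factor = params$hyperemic_factor
  )
  solve_mode <- function(mode) {
    tryCatch(
      solve_pressure_field(tree, assemble_bc(tree, bc, mode)),
      ctifr_degenerate_physics = function(e) NULL
    )
  }
  rest <- solve_mode("resting")
  hyp <- solve_mode("hyperemic")
  collapsed <- is.null(rest) || is.null(hyp)

  lesion_pt <- lesion_point(tree)
  if (!is.null(rest)) {
    res <- index_at_measurement_point(rest, tree, lesion = lesion_pt,
                                      hyperemic_solution = hyp)
    ifr_ct <- res$ifr_ct
    ffr_ct <- if (is.null(hyp)) PRESSURE_COLLAPSE_FLOOR else res$ffr_ct
    ds_meas <- res$ds_percent
  } else {
    ifr_ct <- PRESSURE_COLLAPSE_FLOOR
    ffr_ct <- PRESSURE_COLLAPSE_FLOOR
    ds_meas <- percent_diameter_stenosis(get_segment(tree, lesion_pt$segment))
  }
  ifr_inv <- clip_unit(ifr_ct + draws$eps_ifr)
  ffr_inv <- clip_unit(ffr_ct + draws$eps_ffr)
  data.frame(
    vessel_id = vessel_id,
    vessel_type = draws$vtype,
    ds_percent = ds_meas,
    ifr_ct = ifr_ct,
    ffr_ct = ffr_ct,
    ifr_invasive = ifr_inv,
    ffr_invasive = ffr_inv,
    sig_ifr_ct = ifr_ct <= 0.89,
    sig_ifr_invasive = ifr_inv <= 0.89,
    sig_ffr_invasive = ffr_inv <= 0.80,
    collapsed = collapsed,
    stringsAsFactors = FALSE
  )
}

#' Generate a paired synthetic cohort
#'
#' Runs [simulate_vessel()] for `n_vessels` independent per-vessel seed
#' streams derived from the master seed. Reproducible: the same parameters
#' and seed give an identical table, and the first k rows are unchanged
#' when `n_vessels` grows.
#'
#' @param params a [cohort_params()].
#' @return a data frame (one row per vessel) with the columns documented
#'   in [simulate_vessel()]; `params` attached as an attribute.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  seeds <- child_seeds(params$seed, params$n_vessels)
  rows <- lapply(seq_len(params$n_vessels), function(i) {
    simulate_vessel(params, seeds[i], vessel_id = i)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}

#' Summarize a cohort
#'
#' @param cohort a data frame from [generate_cohort()].
#' @param cutoff_index,cutoff_ifr,cutoff_ffr significance cutoffs.
#' @return a list: `n`, per-index `mean` and `sd`, and prevalence (as a
#'   proportion) of positivity at each cutoff.
#' @export
cohort_summary <- function(cohort, cutoff_index = 0.89, cutoff_ifr = 0.89,
                           cutoff_ffr = 0.80) {
  idx <- c("ifr_ct", "ffr_ct", "ifr_invasive", "ffr_invasive")
  list(
    n = nrow(cohort),
    mean = vapply(cohort[idx], mean, numeric(1)),
    sd = vapply(cohort[idx], stats::sd, numeric(1)),
    prevalence = c(
      ifr_ct = mean(cohort$ifr_ct <= cutoff_index),
      ifr_invasive = mean(cohort$ifr_invasive <= cutoff_ifr),
      ffr_invasive = mean(cohort$ffr_invasive <= cutoff_ffr)
    )
  )
}

#' Write a cohort as CSV
#'
#' Comma-separated, UTF-8, header row, "." decimal; numeric columns are
#' printed at full precision so reruns with the same seed are
#' byte-identical.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  num <- vapply(cohort, is.numeric, logical(1))
  out <- cohort
  out[num] <- lapply(cohort[num], function(x) {
    ifelse(x == round(x), format(x, trim = TRUE),
           format(x, digits = 15, trim = TRUE))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a paired per-vessel table from CSV
#'
#' @param path CSV path with a header row.
#' @return a data frame.
#' @export
read_pairs_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
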