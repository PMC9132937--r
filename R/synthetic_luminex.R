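# Synthetic Luminex plate generator: matched standard and adapted plates
# with control-animal background and bait-proportional adapted signal.

#' Configuration for the synthetic Luminex generator
#'
#' @param analytes data.frame with columns `analyte`, `abundance` (total
#'   analyte level in fluorescence units) and `frac` (cell-type-derived
#'   fraction in `[0, 1]`).
#' @param regions region labels; one group of replicate wells per region.
#' @param bait_rel_abundance named relative bait abundance per region
#'   (linear scale); default 1 everywhere, in which case the recovered
#'   adapted/standard ratio estimates `frac` directly.
#' @param n_wells replicate wells per region and plate.
#' @param plate_noise_cv multiplicative noise coefficient of variation.
#' @param blank_level blank (background) fluorescence added to every well.
#' @param seed master seed.
#' @return validated list of class `synth_luminex_config`.
#' @export
synth_luminex_config <- function(analytes,
                                 regions = c("CTX", "HIP", "ST", "PM", "CB"),
                                 bait_rel_abundance = NULL,
                                 n_wells = 3L,
                                 plate_noise_cv = 0.05,
                                 blank_level = 50,
                                 seed = 1L) {
  stopifnot(is.data.frame(analytes),
            all(c("analyte", "abundance", "frac") %in% names(analytes)))
  if (any(analytes$frac < 0 | analytes$frac > 1))
    stop_config("cell-type-derived fractions must be in [0, 1]")
  if (blank_level < 0) stop_config("blank_level must be >= 0")
  if (plate_noise_cv < 0) stop_config("plate_noise_cv must be >= 0")
  if (is.null(bait_rel_abundance))
    bait_rel_abundance <- stats::setNames(rep(1, length(regions)), regions)
  if (!setequal(names(bait_rel_abundance), regions))
    stop_config("bait_rel_abundance must have one entry per region")
  structure(list(analytes = analytes, regions = regions,
                 bait_rel_abundance = bait_rel_abundance,
                 n_wells = as.integer(n_wells),
                 plate_noise_cv = plate_noise_cv,
                 blank_level = blank_level, seed = as.integer(seed)),
            class = "synth_luminex_config")
}

# multiplicative log-normal noise with mean exactly 1
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate matched synthetic Luminex plates
#'
#' Produces three plates over the same analytes and wells: the standard
#' assay (total analyte signal), the adapted assay on labeled animals
#' (cell-type-derived fraction of the analyte, scaled by the region's
#' relative bait abundance), and the adapted assay on control animals
#' (blank-level background only, since controls carry no in vivo
#' biotinylation). All signals include the blank level and multiplicative
#' noise with the configured CV.
#'
#' @param config a [synth_luminex_config()].
#' @return list with `standard`, `adapted_labeled`, `adapted_control`
#'   ([luminex_plate()]s; columns named `<region>_w<i>`), `truth` (the
#'   analyte table with per-region expected adapted signal), and
#'   `well_regions` (named region per well).
#' @export
generate_luminex_dataset <- function(config) {
  stopifnot(inherits(config, "synth_luminex_config"))
  set.seed(derive_seed(config$seed, "luminex-dataset"))
  an <- config$analytes
  wells <- as.vector(vapply(config$regions, function(r)
    sprintf("%s_w%d", r, seq_len(config$n_wells)),
    character(config$n_wells)))
  well_regions <- stats::setNames(rep(config$regions,
                                      each = config$n_wells), wells)
  nA <- nrow(an)
  nW <- length(wells)

  expected <- function(kind) {
    m <- matrix(0, nA, nW, dimnames = list(an$analyte, wells))
    for (w in seq_len(nW)) {
      r <- well_regions[[w]]
      m[, w] <- switch(kind,
        standard = an$abundance,
        adapted_labeled = an$frac * an$abundance *
          config$bait_rel_abundance[[r]],
        adapted_control = 0)
    }
    m + config$blank_level
  }
  noisy <- function(m) {
    m * matrix(ln_noise(length(m), config$plate_noise_cv), nrow(m), ncol(m))
  }

  std <- noisy(expected("standard"))
  adl <- noisy(expected("adapted_labeled"))
  adc <- noisy(expected("adapted_control"))

  truth <- an
  for (r in config$regions)
    truth[[paste0("expected_adapted_", r)]] <-
      an$frac * an$abundance * config$bait_rel_abundance[[r]]

  list(standard = luminex_plate(std, mode = "standard"),
       adapted_labeled = luminex_plate(adl, mode = "adapted"),
       adapted_control = luminex_plate(adc, mode = "adapted"),
       truth = truth, well_regions = well_regions)
}
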