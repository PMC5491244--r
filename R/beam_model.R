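#' Radiobiological weighting parameters
#'
#' The fixed factors that convert computed physical dose components into
#' biologically weighted (gray-equivalent) dose.  Dose-rate scaling factors
#' (DRSF) are per-component normalizations bringing computed dose rates
#' into agreement with in-phantom measurement: 0.64 (thermal neutron),
#' 1.39 (fast neutron), 0.96 (photon), 0.65 (boron capture).  RBE 3.2 is
#' applied to the high-LET thermal and fast neutron components, 0.5 to the
#' photon component; the boron compound factor (CBE, for BPA) is 3.8 in
#' tumor and 1.3 in normal brain.  The tumor-to-normal boron concentration
#' ratio (T/N) is assumed 3.5.
#'
#' @param drsf named numeric: `thermal`, `fast`, `photon`, `b10`.
#' @param rbe named numeric: `thermal`, `fast`, `photon`.
#' @param cbe named numeric: `tumor`, `brain`.
#' @param tn_ratio tumor/normal boron concentration ratio (>= 1).
#' @return An object of class `radiobiology_params`.
#' @export
radiobiology_params <- function(drsf = c(thermal = 0.64, fast = 1.39,
                                         photon = 0.96, b10 = 0.65),
                                rbe = c(thermal = 3.2, fast = 3.2,
                                        photon = 0.5),
                                cbe = c(tumor = 3.8, brain = 1.3),
                                tn_ratio = 3.5) {
  stopifnot(all(drsf > 0), all(rbe > 0), all(cbe > 0), tn_ratio >= 1)
  structure(list(drsf = drsf, rbe = rbe, cbe = cbe, tn_ratio = tn_ratio),
            class = "radiobiology_params")
}

BEAM_COMPONENTS <- c("thermal", "fast", "photon", "b10")

#' Parametric epithermal-beam model parameters
#'
#' Per-component depth-dose parameters of a parallel epithermal neutron
#' beam in water-equivalent tissue, at the reference reactor power.  The
#' thermal-neutron and boron-capture components share a
#' build-up-then-exponential shape `A * (exp(-d/lambda_decay) -
#' exp(-d/lambda_buildup))` (the thermal flux builds up over the first
#' ~2 cm by moderation, then attenuates); the fast component is a
#' monotone-decaying exponential; the photon (capture gamma) component
#' builds up and decays slowly.  The boron-capture amplitude is the dose
#' rate at the reference boron concentration; it scales linearly with the
#' local concentration.  Use [default_beam_model()] for the shipped
#' calibrated defaults.
#'
#' @param components named list (`thermal`, `fast`, `photon`, `b10`) of
#'   lists with `amplitude_Gy_min`, `lambda_decay_cm` and (except `fast`)
#'   `lambda_buildup_cm`.
#' @param collimator_diameter_cm beam collimator diameter (default 14 cm).
#' @param penumbra_sigma_cm width parameter of the error-function penumbra.
#' @param field_contraction_cm_per_cm in-tissue contraction of the
#'   effective field edge with depth: the 50% radius shrinks by this many
#'   cm per cm of depth (thermal flux deep in tissue is sustained by the
#'   field core, so the useful field narrows with depth).  0 disables.
#' @param reference_boron_ppm normal-tissue boron concentration at which
#'   the `b10` amplitude is expressed (ppm).
#' @param reference_power_MW,reference_flux_n_cm2_s reactor reference
#'   operating point (bookkeeping only; dose rates are at this power).
#' @return An object of class `beam_model_params`.
#' @export
beam_model_params <- function(components,
                              collimator_diameter_cm = 14,
                              penumbra_sigma_cm = 0.6,
                              field_contraction_cm_per_cm = 0,
                              reference_boron_ppm = 25,
                              reference_power_MW = 1.2,
                              reference_flux_n_cm2_s = 1.28e9) {
  stopifnot(all(BEAM_COMPONENTS %in% names(components)))
  for (nm in BEAM_COMPONENTS) {
    cp <- components[[nm]]
    if (cp$amplitude_Gy_min < 0 || cp$lambda_decay_cm <= 0)
      stop("component amplitudes must be >= 0 and decay lengths > 0")
  }
  structure(list(components = components,
                 collimator_diameter_cm = collimator_diameter_cm,
                 penumbra_sigma_cm = penumbra_sigma_cm,
                 field_contraction_cm_per_cm = field_contraction_cm_per_cm,
                 reference_boron_ppm = reference_boron_ppm,
                 reference_power_MW = reference_power_MW,
                 reference_flux_n_cm2_s = reference_flux_n_cm2_s),
            class = "beam_model_params")
}

#' Shipped default beam model
#'
#' Reads `thor_default.yaml` from the package: a parametric model of an
#' epithermal reactor beam (1.2 MW, epithermal flux 1.28e9 n cm^-2 s^-1,
#' 14-cm collimator) whose thermal/boron penetration length is calibrated
#' so that the advantage depth equals 8.5 cm at T/N = 3.5
#' (see [compute_advantage_depth()]).
#'
#' @return A [beam_model_params()].
#' @export
default_beam_model <- function() {
  read_beam_model(system.file("extdata", "thor_default.yaml",
                              package = "bnctplan", mustWork = TRUE))
}

#' Read/write beam-model parameters as YAML
#' @param path YAML file path.
#' @return [read_beam_model()]: a [beam_model_params()];
#'   [write_beam_model()]: `path` invisibly.
#' @export
read_beam_model <- function(path) {
  y <- yaml::read_yaml(path)
  beam_model_params(components = y$components,
                    collimator_diameter_cm = y$collimator_diameter_cm,
                    penumbra_sigma_cm = y$penumbra_sigma_cm,
                    field_contraction_cm_per_cm =
                      if (is.null(y$field_contraction_cm_per_cm)) 0
                      else y$field_contraction_cm_per_cm,
                    reference_boron_ppm = y$reference_boron_ppm,
                    reference_power_MW = y$reference_power_MW,
                    reference_flux_n_cm2_s = y$reference_flux_n_cm2_s)
}

#' @rdname read_beam_model
#' @param params a [beam_model_params()].
#' @export
write_beam_model <- function(params, path) {
  stopifnot(inherits(params, "beam_model_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Physical dose rate of one beam component at depth
#'
#' Closed-form on-axis depth-dose rate (Gy/min at reference power) in
#' water-equivalent tissue.  The `b10` component is the boron-capture dose
#' rate at the reference boron concentration.
#'
#' @param depth radiological depth in cm (vectorized, >= 0).
#' @param component one of `"thermal"`, `"fast"`, `"photon"`, `"b10"`.
#' @param params a [beam_model_params()].
#' @return dose rate(s) in Gy/min.
#' @export
component_depth_dose_rate <- function(depth, component, params) {
  component <- match.arg(component, BEAM_COMPONENTS)
  if (any(depth < 0)) stop("depth must be >= 0")
  cp <- params$components[[component]]
  if (component == "fast" && is.null(cp$lambda_buildup_cm)) {
    # plain monotone-decaying exponential when no build-up is configured
    cp$amplitude_Gy_min * exp(-depth / cp$lambda_decay_cm)
  } else {
    # degenerate lambda_decay == lambda_buildup collapses to zero dose
    cp$amplitude_Gy_min * (exp(-depth / cp$lambda_decay_cm) -
                             exp(-depth / cp$lambda_buildup_cm))
  }
}

#' Radial beam profile
#'
#' Unitless off-axis factor: ~1 inside the collimated field, an
#' error-function roll-off of width `penumbra_sigma_cm` centred on the
#' field edge (half value exactly at the collimator radius), tending to 0
#' outside.
#'
#' @param r perpendicular distance from the beam axis (cm, vectorized).
#' @param params a [beam_model_params()].
#' @return fraction(s) in (0, 1).
#' @export
#' @param depth radiological depth (cm) at which the profile is evaluated;
#'   the effective field edge contracts with depth by
#'   `field_contraction_cm_per_cm`, but never below a 3.5-cm core radius
#'   (the central region stays fully fluent at depth).  At `depth = 0` the
#'   half-value sits exactly at the collimator radius.
radial_profile <- function(r, params, depth = 0) {
  if (any(r < 0)) stop("r must be >= 0")
  edge <- pmax(params$collimator_diameter_cm / 2 -
                 params$field_contraction_cm_per_cm * depth, 3.5)
  # 0.5 * erfc((r - edge) / (sqrt(2) * sigma)), via pnorm
  pnorm(r, mean = edge, sd = params$penumbra_sigma_cm, lower.tail = FALSE)
}

#' Biologically weighted on-axis depth-dose rate
#'
#' Applies the DRSF per component and the RBE/CBE weighting to the on-axis
#' physical curves, for tumor-like tissue (boron at T/N times the
#' reference concentration, tumor CBE) or normal tissue (reference
#' concentration, brain CBE).  Units: Gy-Eq/min.
#'
#' @param depth radiological depth in cm (vectorized).
#' @param params a [beam_model_params()].
#' @param rb a [radiobiology_params()].
#' @param tissue `"tumor"` or `"normal"`.
#' @return weighted dose rate(s), Gy-Eq/min.
#' @export
weighted_depth_dose <- function(depth, params, rb = radiobiology_params(),
                                tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  boron_factor <- if (tissue == "tumor") rb$cbe[["tumor"]] * rb$tn_ratio
                  else rb$cbe[["brain"]]
  rb$rbe[["thermal"]] * rb$drsf[["thermal"]] *
    component_depth_dose_rate(depth, "thermal", params) +
  rb$rbe[["fast"]] * rb$drsf[["fast"]] *
    component_depth_dose_rate(depth, "fast", params) +
  rb$rbe[["photon"]] * rb$drsf[["photon"]] *
    component_depth_dose_rate(depth, "photon", params) +
  boron_factor * rb$drsf[["b10"]] *
    component_depth_dose_rate(depth, "b10", params)
}

#' Advantage depth of the beam model
#'
#' The advantage depth (AD) is the depth in tissue at which the weighted
#' dose to tumor equals the maximum weighted dose to normal tissue along
#' the beam; beyond it a single field gives no therapeutic benefit.
#' Computed on the central axis of a homogeneous water-equivalent phantom:
#' the normal-tissue maximum is located numerically, then the largest
#' crossing of the tumor curve with that level is found by bracketing and
#' bisection to 0.01 cm.
#'
#' @param params a [beam_model_params()].
#' @param rb a [radiobiology_params()].
#' @param max_depth search limit in cm.
#' @param resolution scan resolution in cm for bracketing.
#' @return advantage depth in cm.
#' @export
compute_advantage_depth <- function(params, rb = radiobiology_params(),
                                    max_depth = 40, resolution = 0.05) {
  normal <- function(d) weighted_depth_dose(d, params, rb, "normal")
  tumor <- function(d) weighted_depth_dose(d, params, rb, "tumor")
  grid <- seq(0, max_depth, by = resolution)
  nv <- normal(grid)
  i <- which.max(nv)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- if (hi > lo)
    optimize(normal, c(lo, hi), maximum = TRUE, tol = 1e-6)
  else list(maximum = grid[i], objective = nv[i])
  nmax <- opt$objective
  f <- tumor(grid) - nmax
  if (all(f < 0)) {
    # coincident curves (e.g. T/N = 1 with equal CBE): the tumor curve
    # touches the normal maximum at the peak itself; the tolerance covers
    # the sub-grid refinement of the normal maximum
    if (max(f) > -1e-4 * nmax) return(opt$maximum)
    stop("advantage depth undefined: tumor dose never reaches the ",
         "normal-tissue maximum")
  }
  # largest depth where the (eventually decreasing) tumor curve crosses nmax
  above <- max(which(f >= 0))
  if (above == length(grid))
    stop("tumor dose still above the normal-tissue maximum at max_depth; ",
         "increase max_depth")
  uniroot(function(d) tumor(d) - nmax,
          lower = grid[above], upper = grid[above + 1],
          tol = 1e-4)$root
}

#' Calibrate the beam model to a target advantage depth
#'
#' One-dimensional root finding on the shared thermal/boron penetration
#' length (`lambda_decay_cm` of the `thermal` and `b10` components) so that
#' [compute_advantage_depth()] of the result equals `target_ad` within
#' 0.05 cm.  This is the only transport-level observable the model is
#' anchored to; all other shape parameters are documented defaults.
#'
#' @param params starting [beam_model_params()].
#' @param rb a [radiobiology_params()].
#' @param target_ad target advantage depth (cm).
#' @param bracket search interval for the penetration length (cm).
#' @return calibrated [beam_model_params()].
#' @export
calibrate_beam_model <- function(params, rb = radiobiology_params(),
                                 target_ad = 8.5, bracket = c(1.5, 12)) {
  set_lambda <- function(l) {
    params$components$thermal$lambda_decay_cm <- l
    params$components$b10$lambda_decay_cm <- l
    params
  }
  g <- function(l) compute_advantage_depth(set_lambda(l), rb) - target_ad
  # fixed point: already on target
  cur <- tryCatch(compute_advantage_depth(params, rb), error = function(e) NA)
  if (!is.na(cur) && abs(cur - target_ad) < 0.01) return(params)
  # the two-exponential shape needs decay > build-up to stay nonnegative
  lo <- max(bracket[1],
            1.05 * params$components$thermal$lambda_buildup_cm,
            1.05 * params$components$b10$lambda_buildup_cm)
  root <- tryCatch(
    uniroot(g, lower = lo, upper = bracket[2], tol = 1e-5)$root,
    error = function(e) stop("no advantage-depth root in the bracket [",
                             bracket[1], ", ", bracket[2], "] cm: ",
                             conditionMessage(e)))
  set_lambda(root)
}
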