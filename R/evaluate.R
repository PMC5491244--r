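#' Cumulative dose-volume histogram
#'
#' Exact voxel-counting cumulative DVH: at each bin edge, the fraction of
#' the structure volume receiving at least that dose.  Starts at 1 at dose
#' 0 and ends at 0 beyond the maximum dose.
#'
#' @param dose 3D dose array (Gy-Eq) or an `rbe_dose_map`.
#' @param mask logical structure mask (nonempty).
#' @param geom a [grid_geometry()].
#' @param bin_width bin width in Gy-Eq (default 0.05).
#' @return An object of class `dvh`: `dose` (bin edges), `volume_fraction`,
#'   `volume_cm3`.
#' @export
cumulative_dvh <- function(dose, mask, geom, bin_width = 0.05) {
  if (inherits(dose, "rbe_dose_map")) dose <- dose$dose
  if (!any(mask)) stop("empty structure mask")
  d <- dose[mask]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(dose = edges, volume_fraction = frac,
                 volume_cm3 = mask_volume_cm3(mask, geom)),
            class = "dvh")
}

#' Dose received by at least a given volume fraction
#'
#' Inverts the cumulative DVH by linear interpolation: the dose exceeded by
#' exactly fraction `v` of the structure volume.  `D95 = dose_at_volume(dvh,
#' 0.95)`, `D5 = dose_at_volume(dvh, 0.05)`.
#'
#' @param dvh a [cumulative_dvh()].
#' @param v volume fraction in (0, 1].
#' @return dose in Gy-Eq.
#' @export
dose_at_volume <- function(dvh, v) {
  stopifnot(v > 0, v <= 1)
  f <- dvh$volume_fraction
  d <- dvh$dose
  i <- max(which(f >= v))          # f starts at 1, so this always exists
  if (i == length(f)) return(d[i])
  if (f[i] == f[i + 1]) return(d[i])
  d[i] + (f[i] - v) / (f[i] - f[i + 1]) * (d[i + 1] - d[i])
}

#' Homogeneity index of a target DVH
#'
#' `HI = D5 / D95`, the ratio of the minimum dose in the hottest 5% to the
#' minimum dose in the best-covered 95% of the target; 1 means perfectly
#' uniform.
#'
#' @param dvh a [cumulative_dvh()] of the target.
#' @return unitless HI (>= 1).
#' @export
homogeneity_index <- function(dvh) {
  d95 <- dose_at_volume(dvh, 0.95)
  if (d95 <= 0) stop("D95 is zero; homogeneity index undefined")
  dose_at_volume(dvh, 0.05) / d95
}

#' Integral dose to a structure
#'
#' `ID (Gy-Eq L) = mean dose (Gy-Eq) x volume (L)`.
#'
#' @param dose 3D dose array (Gy-Eq) or an `rbe_dose_map`.
#' @param mask logical structure mask (nonempty).
#' @param geom a [grid_geometry()].
#' @return integral dose in Gy-Eq L.
#' @export
integral_dose <- function(dose, mask, geom) {
  if (inherits(dose, "rbe_dose_map")) dose <- dose$dose
  if (!any(mask)) stop("empty structure mask")
  mean(dose[mask]) * mask_volume_cm3(mask, geom) / 1000
}

#' Therapeutic gain
#'
#' Ratio of the minimal target dose to the maximal normal-tissue dose
#' (CTVmin / NTmax); above 1 every target voxel receives more than any
#' normal-tissue voxel.
#'
#' @param ctv_min minimal CTV dose (Gy-Eq).
#' @param nt_max maximal normal-tissue dose (Gy-Eq, > 0).
#' @return unitless ratio.
#' @export
therapeutic_gain <- function(ctv_min, nt_max) {
  if (nt_max <= 0) stop("maximal normal-tissue dose must be positive")
  ctv_min / nt_max
}

#' Default organ-at-risk maximum-dose tolerances (Gy-Eq)
#' @format Named numeric vector (strict upper limits).
#' @export
OAR_TOLERANCES <- c(NB = 13, L_ON = 10, R_ON = 10, CW = 12)

#' Dose statistics of one structure
#'
#' Dmin/Dmax/Dmean from the voxel doses directly, D95/D5/HI from the DVH,
#' and the integral dose.
#'
#' @param dose 3D dose array (Gy-Eq).
#' @param mask logical structure mask.
#' @param geom a [grid_geometry()].
#' @param bin_width DVH bin width.
#' @return one-row data.frame: Dmin, Dmax, Dmean, D95, D5, HI, ID_GyEqL,
#'   volume_cm3.
#' @export
structure_metrics <- function(dose, mask, geom, bin_width = 0.05) {
  d <- dose[mask]
  dvh <- cumulative_dvh(dose, mask, geom, bin_width)
  data.frame(Dmin = min(d), Dmax = max(d), Dmean = mean(d),
             D95 = dose_at_volume(dvh, 0.95),
             D5 = dose_at_volume(dvh, 0.05),
             HI = dose_at_volume(dvh, 0.05) / dose_at_volume(dvh, 0.95),
             ID_GyEqL = integral_dose(dose, mask, geom),
             volume_cm3 = mask_volume_cm3(mask, geom))
}

#' Organ-at-risk metrics with tolerance flags
#'
#' Dmean, Dmax and integral dose per organ at risk, plus a strict
#' maximum-dose tolerance check (`Dmax < limit`; a Dmax exactly at the
#' limit fails).  A structure named in `tolerances` but absent from the
#' structure set is reported with `present = FALSE`, never silently
#' skipped.
#'
#' @param dose 3D dose array (Gy-Eq) or an `rbe_dose_map`.
#' @param structures a `structure_set`.
#' @param tolerances named numeric of maximum-dose limits (Gy-Eq).
#' @return data.frame: structure, present, volume_cm3, Dmean, Dmax,
#'   ID_GyEqL, tolerance_GyEq, pass.
#' @export
oar_metrics <- function(dose, structures, tolerances = OAR_TOLERANCES) {
  if (inherits(dose, "rbe_dose_map")) dose <- dose$dose
  geom <- structures$geom
  rows <- lapply(names(tolerances), function(nm) {
    m <- structures$masks[[nm]]
    if (is.null(m) || !any(m))
      return(data.frame(structure = nm, present = FALSE,
                        volume_cm3 = NA_real_, Dmean = NA_real_,
                        Dmax = NA_real_, ID_GyEqL = NA_real_,
                        tolerance_GyEq = tolerances[[nm]], pass = NA))
    d <- dose[m]
    data.frame(structure = nm, present = TRUE,
               volume_cm3 = mask_volume_cm3(m, geom),
               Dmean = mean(d), Dmax = max(d),
               ID_GyEqL = integral_dose(dose, m, geom),
               tolerance_GyEq = tolerances[[nm]],
               pass = max(d) < tolerances[[nm]])
  })
  do.call(rbind, rows)
}

#' Deepest target depth from the body surface along a beam angle
#'
#' Maximum over CTV voxels of the geometric distance from the body entry
#' surface along the beam direction, as measured on CT images (geometric,
#' not radiological, depth).
#'
#' @param body_mask logical body mask.
#' @param ctv_mask logical CTV mask (nonempty).
#' @param angle beam angle in degrees.
#' @param geom a [grid_geometry()].
#' @return depth in cm.
#' @export
max_tumor_depth <- function(body_mask, ctv_mask, angle, geom) {
  stopifnot(any(body_mask), any(ctv_mask))
  pts <- mask_coords(ctv_mask, geom)
  max(geometric_depth(body_mask, geom, angle, pts))
}

#' Full metric bundle for one plan
#'
#' CTV statistics, therapeutic gain against body-minus-CTV, organ-at-risk
#' metrics, and beam-on times, as a single tidy row.
#'
#' @param plan a `bnct_plan` from [plan_treatment()].
#' @param structures a `structure_set`.
#' @param tolerances organ-at-risk maximum-dose limits.
#' @param bin_width DVH bin width.
#' @return one-row data.frame of plan-level metrics (OAR columns prefixed
#'   by structure name).
#' @export
plan_metrics <- function(plan, structures, tolerances = OAR_TOLERANCES,
                         bin_width = 0.05) {
  dose <- plan$dose
  geom <- structures$geom
  ctv <- structure_metrics(dose, structures$masks$CTV, geom, bin_width)
  nt_mask <- structures$masks$body & !structures$masks$CTV
  nt_max <- max(dose[nt_mask])
  oar <- oar_metrics(dose, structures, tolerances)
  out <- data.frame(n_fields = length(plan$fields),
                    total_minutes = plan$total_minutes,
                    nt_spread = plan$nt_spread,
                    CTV_min = ctv$Dmin, CTV_max = ctv$Dmax,
                    CTV_mean = ctv$Dmean, CTV_D95 = ctv$D95,
                    CTV_D5 = ctv$D5, HI = ctv$HI,
                    CTV_volume_cm3 = ctv$volume_cm3,
                    NT_max = nt_max,
                    gain = therapeutic_gain(ctv$Dmin, nt_max))
  for (i in seq_len(nrow(oar))) {
    nm <- oar$structure[i]
    out[[paste0(nm, "_Dmean")]] <- oar$Dmean[i]
    out[[paste0(nm, "_Dmax")]] <- oar$Dmax[i]
    out[[paste0(nm, "_ID")]] <- oar$ID_GyEqL[i]
    out[[paste0(nm, "_pass")]] <- oar$pass[i]
  }
  out
}
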