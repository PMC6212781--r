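#' Chromatin fiber geometry for closed-form looping calculations
#'
#' Bundles the geometric parameters of the interphase fiber used by the
#' analytic calculators: its diameter, linear compaction, the
#' centre-to-centre distance below which two loci count as "in
#' contact", and the Kuhn (statistical segment) length of the
#' ideal-chain description.
#'
#' The defaults describe a 20-nm fiber carrying 50 bp per nm with a
#' 50-nm contact threshold.  The Kuhn length defaults to the fiber
#' diameter, so one statistical segment carries 1 kb.
#'
#' @param fiber_diameter_nm Fiber diameter in nm.
#' @param compaction_bp_per_nm Base pairs per nm of fiber contour.
#' @param capture_radius_nm Contact-detection threshold in nm.
#' @param kuhn_length_nm Kuhn segment length in nm; defaults to the
#'   fiber diameter.
#' @return An object of class `fiber_geometry`.
#' @examples
#' geom <- fiber_geometry()
#' melt_contact_probability(1e5, geom)
#' @export
fiber_geometry <- function(fiber_diameter_nm = 20,
                           compaction_bp_per_nm = 50,
                           capture_radius_nm = 50,
                           kuhn_length_nm = fiber_diameter_nm) {
  vals <- c(fiber_diameter_nm, compaction_bp_per_nm, capture_radius_nm,
            kuhn_length_nm)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      any(vals[-3] == 0))  # a zero capture radius is a legal limit
    stopf("all fiber_geometry parameters must be positive and finite")
  structure(list(fiber_diameter_nm = fiber_diameter_nm,
                 compaction_bp_per_nm = compaction_bp_per_nm,
                 capture_radius_nm = capture_radius_nm,
                 kuhn_length_nm = kuhn_length_nm),
            class = "fiber_geometry")
}

#' Fraction of factors dimerized in free solution
#'
#' Exact solution of the mass-action equilibrium 2M = D with
#' dissociation constant `Kd = [M]^2 / [D]`.  Two reporting conventions
#' are supported: `"molecules"` counts the fraction of molecules
#' residing in dimers (`2[D] / total`), `"complexes"` counts dimers as
#' a fraction of all complexes (`[D] / ([M] + [D])`).
#'
#' At a typical nuclear concentration of 1 nM and `Kd = 1e-7` M only on
#' the order of 1% of factors dimerize, which is why freely diffusing
#' factors are poor loop stabilizers.
#'
#' @param total_concentration_molar Total factor concentration (M),
#'   counted in molecule equivalents.
#' @param Kd_molar Dissociation constant (M).
#' @param convention `"molecules"` (default) or `"complexes"`.
#' @return Dimer fraction in `[0, 1]`.
#' @examples
#' dimer_fraction(1e-9, 1e-7)
#' dimer_fraction(1e-9, 1e-7, convention = "complexes")
#' @export
dimer_fraction <- function(total_concentration_molar, Kd_molar = 1e-7,
                           convention = c("molecules", "complexes")) {
  convention <- match.arg(convention)
  Tc <- total_concentration_molar
  if (!is.numeric(Tc) || length(Tc) != 1L || !is.finite(Tc) || Tc < 0)
    stopf("total_concentration_molar must be a single non-negative number")
  if (!is.numeric(Kd_molar) || Kd_molar <= 0)
    stopf("Kd_molar must be positive")
  if (Tc == 0) return(0)
  # monomer from 2 M^2 / Kd + M - T = 0
  M <- Kd_molar * (sqrt(1 + 8 * Tc / Kd_molar) - 1) / 4
  D <- M^2 / Kd_molar
  switch(convention,
         molecules = 2 * D / Tc,
         complexes = D / (M + D))
}

#' Occupancy of a tethered factor pair
#'
#' Two factors bound to cognate sites on the same fiber see each other
#' at the local concentration set by the tether, not the bulk
#' concentration.  The two-state occupancy is `c / (c + Kd)`.  At the
#' local concentration implied by sites ~10 kb apart (~2e-7 M for
#' `Kd = 1e-7` M) about two thirds of such pairs are dimers, enough to
#' stabilize a loop.
#'
#' @param local_concentration_molar Effective local concentration (M).
#' @param Kd_molar Dissociation constant (M).
#' @return Dimerized fraction in `[0, 1]`.
#' @examples
#' tethered_dimer_fraction(2e-7, 1e-7)  # ~0.67
#' @export
tethered_dimer_fraction <- function(local_concentration_molar,
                                    Kd_molar = 1e-7) {
  if (!is.numeric(local_concentration_molar) ||
      any(local_concentration_molar <= 0))
    stopf("local_concentration_molar must be positive")
  if (!is.numeric(Kd_molar) || Kd_molar <= 0)
    stopf("Kd_molar must be positive")
  local_concentration_molar / (local_concentration_molar + Kd_molar)
}

#' Local concentration seen across a chromatin tether
#'
#' Models one molecule confined to a sphere whose radius is the RMS
#' end-to-end distance of the intervening fiber treated as an ideal
#' chain of Kuhn segments, and converts to molar units.  Below one Kuhn
#' segment the chain is rod-like and the contour length is used as the
#' radius instead.
#'
#' @param separation_bp Genomic separation of the two sites (bp).
#' @param geometry A [fiber_geometry()].
#' @return Concentration in mol/L.
#' @examples
#' local_concentration(1e4)  # sites 10 kb apart
#' @export
local_concentration <- function(separation_bp, geometry = fiber_geometry()) {
  stopifnot(inherits(geometry, "fiber_geometry"))
  if (!is.numeric(separation_bp) || any(separation_bp <= 0))
    stopf("separation_bp must be positive")
  contour_nm <- separation_bp / geometry$compaction_bp_per_nm
  n_seg <- contour_nm / geometry$kuhn_length_nm
  radius_nm <- ifelse(n_seg < 1, contour_nm,
                      sqrt(n_seg) * geometry$kuhn_length_nm)
  vol_litre <- (4 / 3) * pi * radius_nm^3 * 1e-24
  1 / (.AVOGADRO * vol_litre)
}

#' Ideal-chain ("polymer melt") contact probability
#'
#' Probability that two loci a given genomic distance apart lie within
#' the capture radius, treating the intervening fiber as an ideal
#' (phantom) chain — the melt-screened limit appropriate to a dense
#' nucleus.  The end-to-end vector over `N = contour / kuhn` segments
#' is Gaussian with variance `N b^2`, so the closure probability is the
#' exact spherical integral `P(chi^2_3 < r_c^2 / (N b^2 / 3))`.
#'
#' With the default 20-nm fiber at 50 bp/nm and a 50-nm capture radius
#' the probability is ~1.5e-2 at 0.1 Mb, ~5e-4 at 1 Mb and ~2e-5 at
#' 10 Mb, decaying asymptotically as separation^(-3/2).
#'
#' @param separation_bp Genomic separation (bp); vectorized.
#' @param geometry A [fiber_geometry()].
#' @param method `"exact"` for the spherical integral (default) or
#'   `"approx"` for the small-radius approximation
#'   `(3 / (2 pi N b^2))^{3/2} * (4/3) pi r_c^3`.
#' @return Contact probability (vectorized over `separation_bp`).
#' @examples
#' melt_contact_probability(c(1e5, 1e6, 1e7))
#' @export
melt_contact_probability <- function(separation_bp,
                                     geometry = fiber_geometry(),
                                     method = c("exact", "approx")) {
  method <- match.arg(method)
  stopifnot(inherits(geometry, "fiber_geometry"))
  if (!is.numeric(separation_bp) || any(!is.finite(separation_bp)))
    stopf("separation_bp must be finite and numeric")
  rc <- geometry$capture_radius_nm
  if (rc < 0) stopf("capture radius must be non-negative")
  b <- geometry$kuhn_length_nm
  bp_per_seg <- b * geometry$compaction_bp_per_nm
  if (any(separation_bp < bp_per_seg))
    stopf("separation_bp must be at least one Kuhn segment (%g bp)",
          bp_per_seg)
  n_seg <- separation_bp / bp_per_seg
  var_coord <- n_seg * b^2 / 3          # per-coordinate Gaussian variance
  if (method == "exact") {
    stats::pchisq(rc^2 / var_coord, df = 3)
  } else {
    (2 * pi * var_coord)^(-3 / 2) * (4 / 3) * pi * rc^3
  }
}
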