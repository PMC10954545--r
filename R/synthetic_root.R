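#' Specification for a synthetic lateral-root outline
#'
#' A root is modelled as a midline along x with a local width profile:
#' a linear taper from zero width at the tip to the base diameter over
#' `taper_length_um`, plus an optional Gaussian bulge (swelling, as induced
#' by microtubule-depolymerizing treatment). The two outline sides are
#' placed at plus/minus half the local width around the midline, sampled
#' every `spacing_um`, with Gaussian tracing noise.
#'
#' @param length_um Root length in um (default 500; must exceed the tip
#'   exclusion zone used downstream).
#' @param base_diameter_um Diameter away from the tip (default 80).
#' @param taper_length_um Length of the tapering tip in um (default 120).
#' @param bulge_amplitude_um Extra diameter at the bulge peak (default 0).
#' @param bulge_center_um,bulge_width_um Bulge centre position and Gaussian
#'   s.d. (defaults 300, 60). Swelling is broad relative to the root width,
#'   so the outline slope stays small and the nearest-neighbour distance
#'   agrees with the vertical width function.
#' @param spacing_um Outline point spacing (default 2).
#' @param noise_sd_um Tracing noise s.d. per coordinate (default 0.3).
#' @param curve_amplitude_um Amplitude of a half-sine midline curvature
#'   (default 0, straight).
#' @param seed Integer seed.
#' @return Object of class `root_spec`.
#' @export
root_spec <- function(length_um = 500, base_diameter_um = 80,
                      taper_length_um = 120, bulge_amplitude_um = 0,
                      bulge_center_um = 300, bulge_width_um = 60,
                      spacing_um = 2, noise_sd_um = 0.3,
                      curve_amplitude_um = 0, seed = 1L) {
  stopifnot_scalar_num(length_um, "length_um", 0, strict_min = TRUE)
  stopifnot_scalar_num(base_diameter_um, "base_diameter_um", 0,
                       strict_min = TRUE)
  stopifnot_scalar_num(spacing_um, "spacing_um", 0, strict_min = TRUE)
  structure(list(length_um = length_um,
                 base_diameter_um = base_diameter_um,
                 taper_length_um = taper_length_um,
                 bulge_amplitude_um = bulge_amplitude_um,
                 bulge_center_um = bulge_center_um,
                 bulge_width_um = bulge_width_um, spacing_um = spacing_um,
                 noise_sd_um = noise_sd_um,
                 curve_amplitude_um = curve_amplitude_um,
                 seed = as.integer(seed)),
            class = "root_spec")
}

root_width_fun <- function(spec) {
  function(x) {
    w <- spec$base_diameter_um * pmin(1, x / spec$taper_length_um)
    if (spec$bulge_amplitude_um > 0) {
      w <- w + spec$bulge_amplitude_um *
        exp(-(x - spec$bulge_center_um)^2 / (2 * spec$bulge_width_um^2))
    }
    w
  }
}

#' Simulate a two-sided root outline with known maximum diameter
#'
#' @param spec A [root_spec()].
#' @param tip_exclude_um Tip zone excluded from the analytic truth (default
#'   100, matching the measurement convention).
#' @param top_k Number of largest widths averaged for the analytic truth
#'   (default 10).
#' @return List: `outline` (a [root_outline()]), `true_diameter` (mean of
#'   the `top_k` largest noiseless widths over the retained sample points),
#'   `true_max_width` (noiseless maximum width outside the tip zone),
#'   `width_fun` (the noiseless width function of axial position).
#' @examples
#' sim <- make_root_outline(root_spec(bulge_amplitude_um = 30, seed = 2))
#' sim$true_diameter
#' @export
make_root_outline <- function(spec, tip_exclude_um = 100, top_k = 10L) {
  stopifnot(inherits(spec, "root_spec"))
  wfun <- root_width_fun(spec)
  x <- seq(0, spec$length_um, by = spec$spacing_um)
  w <- wfun(x)
  mid <- spec$curve_amplitude_um * sin(pi * x / spec$length_um)
  with_seed(spec$seed, {
    n <- length(x)
    s1 <- cbind(x, mid + w / 2 + stats::rnorm(n, 0, spec$noise_sd_um))
    s2 <- cbind(x, mid - w / 2 + stats::rnorm(n, 0, spec$noise_sd_um))
    outline <- root_outline(s1, s2, tip = c(0, mid[1L]))
    retained <- w[x >= tip_exclude_um]
    top <- sort(retained, decreasing = TRUE)[
      seq_len(min(top_k, length(retained)))]
    list(outline = outline, true_diameter = mean(top),
         true_max_width = max(retained), width_fun = wfun)
  })
}
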