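#' Solve the sinusoid amplitude that yields a target r_ec
#'
#' Inverts the analytic amplitude-to-r_ec mapping of [curve_truth()] at
#' fixed wavelength and baseline, by root finding. r_ec decreases
#' monotonically with amplitude, so the root is unique.
#'
#' @param target_rec Target step-chord r_ec in (0, 1).
#' @param wavelength,baseline_length Curve geometry in pixels.
#' @param interval Amplitude search interval in pixels.
#' @return Amplitude in pixels.
#' @export
solve_amplitude <- function(target_rec, wavelength, baseline_length,
                            interval = c(0.25, 40)) {
  if (target_rec <= 0 || target_rec >= 1)
    stop("target_rec must be in (0, 1)")
  f <- function(A) curve_truth(curve_spec("sinusoid", amplitude = A,
                                          wavelength = wavelength,
                                          baseline_length = baseline_length)
                               )$true_rec_step - target_rec
  stats::uniroot(f, interval, tol = 1e-4)$root
}

#' Two-cohort demonstration dataset
#'
#' Generates a compact paper-style study: a wavy "control" cohort and a
#' smoother "diabetic" cohort whose true mean r_ec values are set to the
#' requested targets (defaults 0.823 vs 0.889, typical of healthy versus
#' diabetic murine aorta) by solving for the corresponding sinusoid
#' amplitudes. Rendering is scaled down (160 px slices, 2 px strokes) so
#' repeated calibration runs stay cheap.
#'
#' @param seed Master seed; the two cohort seeds derive from it.
#' @param control_rec,diabetic_rec Target true mean r_ec per group. Set
#'   them equal for a null-effect dataset.
#' @param n_control,n_diabetic Stacks per group.
#' @param slices_per_stack,curves_per_slice Counts per stack / slice.
#' @param image_size Slice side length in pixels.
#' @param stroke_thickness,wavelength,amplitude_sd,noise_sd Rendering and
#'   curve-population parameters (pixels).
#' @return As [generate_cohorts()], plus elements `amplitudes` (solved
#'   per-group means) and `metadata` (stack_id, group_label,
#'   region_label).
#' @export
demo_cohorts <- function(seed = 1L, control_rec = 0.823,
                         diabetic_rec = 0.889, n_control = 10L,
                         n_diabetic = 11L, slices_per_stack = 1L,
                         curves_per_slice = 3L, image_size = 160L,
                         stroke_thickness = 2, wavelength = 60,
                         amplitude_sd = 1.5, noise_sd = 10) {
  shape <- c(image_size, image_size)
  margin <- ceiling(stroke_thickness) + 2
  baseline <- shape[2] - 2 * margin - 2
  amp_c <- solve_amplitude(control_rec, wavelength, baseline)
  amp_d <- if (diabetic_rec == control_rec) amp_c else
    solve_amplitude(diabetic_rec, wavelength, baseline)
  mk <- function(group, amp, sd_offset, n) cohort_spec(
    group, n_stacks = n, slices_per_stack = slices_per_stack,
    curves_per_slice = curves_per_slice,
    amplitude_distribution = c(amp, amplitude_sd),
    wavelength_distribution = c(wavelength, 0),
    seed = (seed + sd_offset) %% .Machine$integer.max)
  render <- render_spec(image_shape = shape,
                        stroke_thickness = stroke_thickness,
                        noise_sd = noise_sd)
  out <- generate_cohorts(mk("control", amp_c, 0L, n_control),
                          mk("diabetic", amp_d, 500009L, n_diabetic),
                          render, compute_truth = FALSE)
  out$amplitudes <- c(control = amp_c, diabetic = amp_d)
  out$metadata <- stack_metadata(out$stacks)
  out
}

#' Stack metadata table
#'
#' @param stacks List of [image_stack()] objects.
#' @return Data frame with `stack_id`, `group_label`, `region_label`.
#' @export
stack_metadata <- function(stacks) {
  data.frame(stack_id = vapply(stacks, `[[`, "", "stack_id"),
             group_label = vapply(stacks, `[[`, "", "group_label"),
             region_label = vapply(stacks, `[[`, "", "region_label"),
             row.names = NULL)
}
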