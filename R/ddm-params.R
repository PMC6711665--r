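#' Diffusion-model parameter set
#'
#' Bundles the parameters of a plain Wiener diffusion process between two
#' absorbing bounds. The internal convention places the bounds at 0 and `a`
#' with the accumulator starting at `w * a`; drift is accuracy-coded, i.e.
#' positive drift pushes toward the upper (correct) bound. No inter-trial
#' variability parameters are included.
#'
#' @param a Bound separation (> 0), in model units.
#' @param v Mean drift rate (signed, model units per second). Positive values
#'   drive the accumulator toward the correct bound.
#' @param t_er Non-decision time in seconds (>= 0): sensory encoding plus
#'   response execution, added on top of the decision time.
#' @param w Relative start point in (0, 1); 0.5 (unbiased) unless overridden.
#' @param sigma Within-trial noise scale (> 0). All reported parameter
#'   magnitudes assume the `sigma = 1` convention.
#'
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(a = 2, v = 1, t_er = 0.3)
#' choice_probability(p)
#' @export
ddm_params <- function(a, v, t_er = 0, w = 0.5, sigma = 1) {
  vals <- c(a = a, v = v, t_er = t_er, w = w, sigma = sigma)
  if (!all(is.finite(vals))) {
    abort("all diffusion parameters must be finite numbers")
  }
  if (a <= 0) abort("bound separation `a` must be > 0")
  if (w <= 0 || w >= 1) abort("relative start point `w` must lie in (0, 1)")
  if (t_er < 0) abort("non-decision time `t_er` must be >= 0")
  if (sigma <= 0) abort("noise scale `sigma` must be > 0")
  structure(
    list(a = a, v = v, t_er = t_er, w = w, sigma = sigma),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "<ddm_params> a = %.4g, v = %.4g, t_er = %.4g s, w = %.3g, sigma = %.3g\n",
    x$a, x$v, x$t_er, x$w, x$sigma
  ))
  invisible(x)
}

stopifnot_params <- function(params) {
  if (!inherits(params, "ddm_params")) {
    abort("`params` must be created with `ddm_params()`")
  }
  params
}
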