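#' Parameters of the two-compartment sebaceous-gland model
#'
#' Bundles the free and fixed quantities of the progenitor/differentiated
#' (P/D) compartment model of postnatal sebaceous-gland (SG) development.
#' Basal progenitors divide at a per-cell rate
#' \deqn{u_P(t) = c \, (1 + D/P)^k \, e^{-t^2/s}}
#' where `t` is model time in days since developmental onset, `c` is the
#' growth-rate amplitude (1/day), `k` the dimensionless feedback exponent on
#' the suprabasal-to-basal ratio, and `s` the Gaussian decay scale (day^2).
#' By default `s = c`, the shared-constant parameterization in which the
#' model has exactly two growth constants; supply `decay_scale` to decouple
#' the decay time scale from the amplitude (e.g. to let back-skin glands,
#' ceasing around P7, and tail-skin glands, developing until about P9,
#' differ in duration but not amplitude).
#'
#' @param c Growth-rate amplitude, per day. Must be > 0.
#' @param k Feedback exponent on the D/P ratio, dimensionless, >= 0.
#' @param f_p Self-renewal probability of a basal progenitor division,
#'   in `[0, 1]`. `1 - f_p` is the probability that an offspring detaches
#'   and differentiates.
#' @param p0 Initial progenitor count at onset (cells). Default 11, the
#'   progenitor pool observed at the start of SG development (~P2).
#' @param d0 Initial differentiated count (cells), >= 0. Default 0.
#' @param t_onset Postnatal day at which development starts. Default 2.
#' @param t_end Postnatal day at which development ends. Default 9
#'   (tail skin; use 7 for back skin).
#' @param decay_scale Optional Gaussian decay scale `s` in day^2. When
#'   `NULL` (default) the decay scale is shared with `c`.
#'
#' @return An object of class `"sg_params"`: a named list with the fields
#'   above plus the resolved decay scale.
#' @examples
#' p <- sg_params(c = 1.5, k = 2, f_p = 0.8)
#' p
#' @seealso [simulate_sg()], [growth_rate()], [sg_fit()]
#' @export
sg_params <- function(c, k, f_p, p0 = 11, d0 = 0, t_onset = 2, t_end = 9,
                      decay_scale = NULL) {
  stopifnot(is.numeric(c), length(c) == 1L, is.numeric(k), length(k) == 1L,
            is.numeric(f_p), length(f_p) == 1L)
  if (!is.finite(c) || c <= 0) stop("'c' must be a finite positive number")
  if (!is.finite(k) || k < 0) stop("'k' must be finite and >= 0")
  if (!is.finite(f_p) || f_p < 0 || f_p > 1)
    stop("'f_p' must lie in [0, 1]")
  if (!is.finite(p0) || p0 <= 0)
    stop("'p0' must be > 0 (the D/P feedback is undefined for an empty basal layer)")
  if (!is.finite(d0) || d0 < 0) stop("'d0' must be >= 0")
  if (!is.finite(t_onset) || !is.finite(t_end) || t_end <= t_onset)
    stop("'t_end' must exceed 't_onset'")
  if (!is.null(decay_scale)) {
    if (!is.finite(decay_scale) || decay_scale <= 0)
      stop("'decay_scale' must be > 0 when supplied")
  }
  structure(
    list(c = as.numeric(c), k = as.numeric(k), f_p = as.numeric(f_p),
         p0 = as.numeric(p0), d0 = as.numeric(d0),
         t_onset = as.numeric(t_onset), t_end = as.numeric(t_end),
         decay_scale = if (is.null(decay_scale)) NULL else as.numeric(decay_scale)),
    class = "sg_params")
}

# resolved Gaussian decay scale s (day^2): decay_scale if set, else c
.decay_scale <- function(params) {
  if (is.null(params$decay_scale)) params$c else params$decay_scale
}

#' @export
print.sg_params <- function(x, ...) {
  cat("Two-compartment SG model parameters\n")
  cat(sprintf("  growth amplitude c : %.6g /day\n", x$c))
  cat(sprintf("  feedback exponent k: %.6g\n", x$k))
  cat(sprintf("  self-renewal f_p   : %.6g\n", x$f_p))
  cat(sprintf("  initial pool       : P0 = %g, D0 = %g cells\n", x$p0, x$d0))
  cat(sprintf("  development window : P%g -> P%g\n", x$t_onset, x$t_end))
  cat(sprintf("  Gaussian decay s   : %.6g day^2 (%s)\n", .decay_scale(x),
              if (is.null(x$decay_scale)) "shared with c" else "independent"))
  invisible(x)
}

#' Read model parameters from a flat plain-text config file
#'
#' The file is flat YAML: one `key: value` line per field, keys exactly
#' matching the [sg_params()] argument names (`c, k, f_p, p0, d0, t_onset,
#' t_end, decay_scale`). Missing optional keys fall back to the
#' [sg_params()] defaults; `c`, `k` and `f_p` are required.
#'
#' @param path Path to the config file.
#' @return An `sg_params` object.
#' @export
read_sg_params <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file did not parse to key: value pairs")
  needed <- c("c", "k", "f_p")
  missing <- setdiff(needed, names(vals))
  if (length(missing))
    stop("config file is missing required keys: ", paste(missing, collapse = ", "))
  known <- c("c", "k", "f_p", "p0", "d0", "t_onset", "t_end", "decay_scale")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(sg_params, vals[intersect(known, names(vals))])
}
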