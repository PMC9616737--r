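#' Classify a parameter perturbation by its effect on gland composition
#'
#' Simulates the base and perturbed parameter sets to the (shared)
#' development horizon and compares endpoint compartment sizes. An increase
#' beyond the relative tolerance in basal cells only is `P_EXPANSION`, in
#' suprabasal cells only `D_EXPANSION`, in both `COMBINED`, in neither
#' `NONE` — the scenario labels of the gland-expansion analysis (e.g. a
#' knockout that lowers the self-renewal probability should read as
#' suprabasal-driven expansion).
#'
#' @param base,perturbed [sg_params()] objects with identical development
#'   windows.
#' @param rel_tol Relative tolerance separating genuine expansion from
#'   integrator noise. Default 0.05.
#' @return An object of class `"perturbation_class"`: list with `label`
#'   (one of `"P_EXPANSION"`, `"D_EXPANSION"`, `"COMBINED"`, `"NONE"`),
#'   `rel_tol`, and the endpoint pairs.
#' @examples
#' wt <- sg_params(c = 1.5, k = 2, f_p = 0.8)
#' classify_perturbation(wt, wt)  # NONE
#' @export
classify_perturbation <- function(base, perturbed, rel_tol = 0.05) {
  stopifnot(inherits(base, "sg_params"), inherits(perturbed, "sg_params"),
            rel_tol >= 0)
  if (base$t_onset != perturbed$t_onset || base$t_end != perturbed$t_end)
    stop("base and perturbed parameter sets must share the development window")
  eb <- endpoint(simulate_sg(base))
  ep <- endpoint(simulate_sg(perturbed))
  p_up <- ep[["p_end"]] > eb[["p_end"]] * (1 + rel_tol)
  d_up <- ep[["d_end"]] > eb[["d_end"]] * (1 + rel_tol)
  label <- if (p_up && d_up) "COMBINED"
           else if (p_up) "P_EXPANSION"
           else if (d_up) "D_EXPANSION"
           else "NONE"
  structure(list(label = label, rel_tol = rel_tol,
                 p_base = eb[["p_end"]], d_base = eb[["d_end"]],
                 p_perturbed = ep[["p_end"]], d_perturbed = ep[["d_end"]]),
            class = "perturbation_class")
}

#' @export
print.perturbation_class <- function(x, ...) {
  cat(sprintf("%s (rel_tol %.3g): P %.2f -> %.2f, D %.2f -> %.2f\n",
              x$label, x$rel_tol, x$p_base, x$p_perturbed,
              x$d_base, x$d_perturbed))
  invisible(x)
}

#' Sweep self-renewal and feedback strength and classify each scenario
#'
#' Runs the model over a grid of `(f_p, k)` values — the two factors
#' predicted to regulate gland cell numbers: the detachment/differentiation
#' probability of basal progenitors (`1 - f_p`) and the strength of the
#' suprabasal feedback on basal proliferation (`k`) — keeping everything
#' else at the base values, and labels each grid cell against the base
#' endpoint via [classify_perturbation()].
#'
#' @param base An [sg_params()] object giving the reference scenario.
#' @param f_p_grid,k_grid Numeric vectors of values to sweep (within the
#'   model bounds).
#' @param rel_tol Classification tolerance, as in [classify_perturbation()].
#' @return A data frame (one row per grid cell) with columns `f_p`, `k`,
#'   `p_end`, `d_end`, `total`, `label` and `status` (`"ok"` or the error
#'   message for cells whose simulation failed).
#' @export
sweep_perturbations <- function(base, f_p_grid, k_grid, rel_tol = 0.05) {
  stopifnot(inherits(base, "sg_params"),
            length(f_p_grid) >= 1L, length(k_grid) >= 1L)
  grid <- expand.grid(f_p = as.numeric(f_p_grid), k = as.numeric(k_grid),
                      KEEP.OUT.ATTRS = FALSE)
  out <- cbind(grid, p_end = NA_real_, d_end = NA_real_, total = NA_real_,
               label = NA_character_, status = "ok",
               stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      pert <- sg_params(c = base$c, k = grid$k[i], f_p = grid$f_p[i],
                        p0 = base$p0, d0 = base$d0, t_onset = base$t_onset,
                        t_end = base$t_end, decay_scale = base$decay_scale)
      cls <- classify_perturbation(base, pert, rel_tol)
      list(p = cls$p_perturbed, d = cls$d_perturbed, label = cls$label)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[i] <- conditionMessage(res)
    } else {
      out$p_end[i] <- res$p
      out$d_end[i] <- res$d
      out$total[i] <- res$p + res$d
      out$label[i] <- res$label
    }
  }
  out
}
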