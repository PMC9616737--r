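# lognormal with arithmetic mean m and coefficient of variation cv
.rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic wholemount morphometry
#'
#' Draws per-gland maximal length, width, basal nuclear density and
#' suprabasal cell size from lognormal distributions around the configured
#' means with the configured coefficients of variation — the multiplicative
#' noise model natural for strictly positive measurements. Gland pairs with
#' width exceeding length are redrawn so the length >= width convention
#' holds. Fully deterministic per seed.
#'
#' @param n_glands Number of glands.
#' @param length_mean,length_cv Maximal length mean (um) and CV.
#'   Defaults 70 um, 0.15.
#' @param width_mean,width_cv Maximal width mean (um) and CV.
#'   Defaults 45 um, 0.15.
#' @param density_mean,density_cv Basal nuclear linear density mean
#'   (nuclei/um) and CV. Defaults 0.14 /um, 0.1.
#' @param cellsize_mean,cellsize_cv Suprabasal cell size mean (um) and CV.
#'   Defaults 14 um, 0.1.
#' @param cohort Optional cohort label for all glands.
#' @param seed Integer seed.
#' @return An [sg_measurements()] data frame with `n_glands` rows.
#' @export
synth_sg_measurements <- function(n_glands,
                                  length_mean = 70, length_cv = 0.15,
                                  width_mean = 45, width_cv = 0.15,
                                  density_mean = 0.14, density_cv = 0.1,
                                  cellsize_mean = 14, cellsize_cv = 0.1,
                                  cohort = NULL, seed = 1) {
  stopifnot(n_glands >= 1)
  set.seed(seed)
  len <- .rlnorm_cv(n_glands, length_mean, length_cv)
  wid <- .rlnorm_cv(n_glands, width_mean, width_cv)
  for (iter in 1:100) {
    bad <- wid > len
    if (!any(bad)) break
    len[bad] <- .rlnorm_cv(sum(bad), length_mean, length_cv)
    wid[bad] <- .rlnorm_cv(sum(bad), width_mean, width_cv)
  }
  if (any(wid > len))
    stop("could not draw length >= width; configured widths exceed lengths")
  sg_measurements(sg_id = sprintf("sg%04d", seq_len(n_glands)),
                  max_length = len, max_width = wid,
                  basal_nuclear_density = .rlnorm_cv(n_glands, density_mean,
                                                     density_cv),
                  suprabasal_cell_size = .rlnorm_cv(n_glands, cellsize_mean,
                                                    cellsize_cv),
                  cohort = cohort)
}

#' Generate synthetic cell-count observations
#'
#' Integrates the model at `true_params`, samples the requested quantities
#' at the given postnatal days, and multiplies each value by lognormal
#' noise with mean 1 and the given coefficient of variation. With
#' `count_noise_cv = 0` the observations equal the trajectory exactly, so
#' fitting them closes the parameter-recovery loop.
#'
#' @param true_params The generating [sg_params()].
#' @param obs_days Postnatal days to observe (within the development
#'   window).
#' @param count_noise_cv Noise CV (dimensionless). Default 0.05.
#' @param quantities Which quantities to observe per day; subset of
#'   `c("P", "D", "total")`. Default `"total"`.
#' @param n_replicates Independent noisy replicates per (day, quantity)
#'   that are averaged into the reported value. Default 1.
#' @param seed Integer seed.
#' @return A [count_observations()] object.
#' @export
synth_count_observations <- function(true_params, obs_days,
                                     count_noise_cv = 0.05,
                                     quantities = "total",
                                     n_replicates = 1, seed = 1) {
  stopifnot(inherits(true_params, "sg_params"),
            all(quantities %in% c("P", "D", "total")), n_replicates >= 1)
  set.seed(seed)
  grid <- expand.grid(day = sort(unique(as.numeric(obs_days))),
                      quantity = quantities, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  obs0 <- count_observations(grid$day, grid$quantity,
                             value = rep(1, nrow(grid)))
  mu <- .simulated_at_obs(true_params, obs0)
  noisy <- vapply(mu, function(m)
    mean(.rlnorm_cv(n_replicates, m, count_noise_cv)), 0)
  count_observations(grid$day, grid$quantity, noisy)
}

#' Generate a synthetic marker table with planted enriched genes
#'
#' Background fold changes are lognormal centred at 1 for every
#' (gene, compartment) pair; each planted gene instead receives its
#' configured multiplier as fold change in its target compartment. A fixed
#' number of genes — `round(annotated_fraction * n_genes)`, always
#' including the planted genes — are annotated with one of the configured
#' GO terms, so the GO filter's output size is known exactly.
#'
#' @param n_genes Number of background genes (named `gene0001`...).
#' @param compartments Character vector of compartment labels.
#'   Default `c("SG", "IFE", "outer bulge")`.
#' @param planted Optional data frame with columns `gene`, `compartment`,
#'   `multiplier` describing genes planted as enriched; planted gene names
#'   must not collide with background names.
#' @param annotated_fraction Fraction of genes carrying a configured GO
#'   term. Default 0.1.
#' @param go_terms GO IDs used for annotation. Default
#'   `c("GO:0098632", "GO:0007160")`.
#' @param background_cv Lognormal CV of background fold changes.
#'   Default 0.5.
#' @param seed Integer seed.
#' @return A list with elements `rows` (a [marker_table()]) and
#'   `annotations` (gene -> GO ID list, as [read_go_annotations()] returns).
#' @export
synth_marker_table <- function(n_genes, compartments = c("SG", "IFE",
                                                         "outer bulge"),
                               planted = NULL, annotated_fraction = 0.1,
                               go_terms = c("GO:0098632", "GO:0007160"),
                               background_cv = 0.5, seed = 1) {
  stopifnot(n_genes >= 1, length(compartments) >= 1)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (!is.null(planted)) {
    stopifnot(all(c("gene", "compartment", "multiplier") %in% names(planted)))
    if (any(planted$gene %in% genes))
      stop("planted gene name collides with a background gene")
    if (!all(planted$compartment %in% compartments))
      stop("planted compartment not in 'compartments'")
  }
  all_genes <- c(genes, planted$gene)
  grid <- expand.grid(gene = all_genes, compartment = compartments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fc <- .rlnorm_cv(nrow(grid), 1, background_cv)
  if (!is.null(planted)) {
    idx <- match(paste(planted$gene, planted$compartment),
                 paste(grid$gene, grid$compartment))
    fc[idx] <- planted$multiplier
  }
  rows <- marker_table(grid$gene, grid$compartment, fc)

  n_ann <- max(round(annotated_fraction * n_genes), 0L)
  annotated <- sample(genes, min(n_ann, n_genes))
  annotated <- union(planted$gene, annotated)
  ann <- lapply(stats::setNames(annotated, annotated), function(g)
    sample(go_terms, 1L))
  list(rows = rows, annotations = ann)
}

#' Wild-type and knockout parameter fixtures
#'
#' Two documented parameter sets, identical except that the knockout has a
#' lower self-renewal probability `f_p` — the model-level reading of a
#' knockout that accelerates basal progenitor detachment and
#' differentiation. Simulating both shows the knockout signature: a larger
#' endpoint suprabasal compartment and D/P ratio without basal
#' accumulation. These are illustrative fixture values chosen for this
#' package, not fitted estimates.
#'
#' @return A list with elements `wt` and `ko`, both [sg_params()].
#' @examples
#' fx <- wt_ko_fixtures()
#' classify_perturbation(fx$wt, fx$ko)
#' @export
wt_ko_fixtures <- function() {
  list(wt = sg_params(c = 1.5, k = 2, f_p = 0.8),
       ko = sg_params(c = 1.5, k = 2, f_p = 0.65))
}
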