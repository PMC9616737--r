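#' Ellipsoid volume
#'
#' \eqn{V = \frac{4}{3}\pi a b c} for semi-axes `a`, `b`, `c`.
#'
#' @param a,b,c Semi-axes in micrometres, all > 0.
#' @return Volume in cubic micrometres. Vectorized.
#' @examples
#' ellipsoid_volume(10, 10, 10)  # sphere, 4188.79
#' @export
ellipsoid_volume <- function(a, b, c) {
  .check_axes(a, b, c)
  4 / 3 * pi * a * b * c
}

#' Ellipsoid surface area (Thomsen approximation)
#'
#' Closed-form approximation with the power mean of the pairwise semi-axis
#' products at exponent `p = 1.6`:
#' \deqn{A \approx 4\pi \left( \frac{(ab)^p + (ac)^p + (bc)^p}{3} \right)^{1/p}.}
#' Exact for spheres; within about 1.2% of the true surface integral for
#' moderate aspect ratios (worst near p ~ 1.6-sensitive elongations).
#'
#' @param a,b,c Semi-axes in micrometres, all > 0.
#' @param p Power-mean exponent. Default 1.6.
#' @return Surface area in square micrometres. Vectorized.
#' @examples
#' ellipsoid_surface(10, 10, 10)  # 4*pi*100
#' @export
ellipsoid_surface <- function(a, b, c, p = 1.6) {
  .check_axes(a, b, c)
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

.check_axes <- function(a, b, c) {
  if (any(!is.finite(a) | a <= 0) || any(!is.finite(b) | b <= 0) ||
      any(!is.finite(c) | c <= 0))
    stop("ellipsoid semi-axes must be finite and > 0")
}

#' Wholemount sebaceous-gland morphometry table
#'
#' One row per gland: identifier, maximal length and width (full axes, in
#' micrometres, measured en face on the wholemount), linear basal nuclear
#' density (nuclei per micrometre along the basal layer) and mean linear
#' suprabasal cell size (micrometres). Rows with width exceeding length are
#' swapped, with a warning, to enforce the length >= width convention.
#'
#' @param sg_id Gland identifiers.
#' @param max_length,max_width Full axes, micrometres, > 0.
#' @param basal_nuclear_density Nuclei per micrometre, > 0.
#' @param suprabasal_cell_size Mean linear cell size, micrometres, > 0.
#' @param cohort Optional grouping label (e.g. genotype), recycled.
#' @return A data frame of class `"sg_measurements"`.
#' @export
sg_measurements <- function(sg_id, max_length, max_width,
                            basal_nuclear_density, suprabasal_cell_size,
                            cohort = NULL) {
  n <- length(sg_id)
  num <- list(max_length = max_length, max_width = max_width,
              basal_nuclear_density = basal_nuclear_density,
              suprabasal_cell_size = suprabasal_cell_size)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (length(v) != n || any(!is.finite(v)) || any(v <= 0))
      stop("'", nm, "' must be positive and match the number of glands")
  }
  swap <- max_width > max_length
  if (any(swap)) {
    warning(sum(swap), " gland(s) had width > length; axes swapped")
    tmp <- max_length[swap]
    max_length[swap] <- max_width[swap]
    max_width[swap] <- tmp
  }
  out <- data.frame(sg_id = as.character(sg_id), max_length = max_length,
                    max_width = max_width,
                    basal_nuclear_density = basal_nuclear_density,
                    suprabasal_cell_size = suprabasal_cell_size)
  if (!is.null(cohort)) out$cohort <- rep_len(as.character(cohort), n)
  structure(out, class = c("sg_measurements", "data.frame"))
}

#' Read a morphometry table from TSV
#'
#' Header must contain `sg_id`, `max_length`, `max_width`,
#' `basal_nuclear_density`, `suprabasal_cell_size`; an optional `cohort`
#' column is carried through.
#'
#' @param path Path to a tab-separated file.
#' @return An [sg_measurements()] data frame.
#' @export
read_sg_measurements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sg_id", "max_length", "max_width", "basal_nuclear_density",
            "suprabasal_cell_size")
  if (!all(need %in% names(tab)))
    stop("morphometry TSV must have columns: ", paste(need, collapse = ", "))
  sg_measurements(tab$sg_id, tab$max_length, tab$max_width,
                  tab$basal_nuclear_density, tab$suprabasal_cell_size,
                  cohort = if ("cohort" %in% names(tab)) tab$cohort else NULL)
}

#' Write a morphometry table to TSV
#'
#' @param m An [sg_measurements()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sg_measurements <- function(m, path) {
  stopifnot(inherits(m, "sg_measurements"))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate basal and suprabasal cell numbers from gland morphometry
#'
#' Models each gland as a prolate spheroid with semi-axes
#' `a = max_length/2` and `b = c = max_width/2`: the ellipsoid surface is
#' tiled by basal cells and its volume filled by suprabasal cells. The
#' footprint of one basal cell is taken as the square of the mean
#' internuclear spacing, `(1/basal_nuclear_density)^2` (the linear density
#' is measured along the basal layer, so its inverse is the spacing in
#' micrometres); the volume of one suprabasal cell is
#' `suprabasal_cell_size^3`. Then
#' `p_est = surface / basal-cell area` and `d_est = volume / cell volume`.
#'
#' @param m An [sg_measurements()] data frame.
#' @return A data frame of class `"sg_cell_counts"`: per gland, `sg_id`,
#'   `sg_area` (um^2, Thomsen), `sg_volume` (um^3), `p_est`, `d_est` and
#'   the `cohort` column when present. Counts are left unrounded.
#' @examples
#' m <- sg_measurements("g1", 20, 20, 0.1, 15)
#' estimate_counts(m)  # p_est ~ 12.57, d_est ~ 1.24
#' @export
estimate_counts <- function(m) {
  stopifnot(inherits(m, "sg_measurements"))
  a <- m$max_length / 2
  b <- m$max_width / 2
  area <- ellipsoid_surface(a, b, b)
  vol <- ellipsoid_volume(a, b, b)
  basal_area <- (1 / m$basal_nuclear_density)^2
  cell_vol <- m$suprabasal_cell_size^3
  out <- data.frame(sg_id = m$sg_id, sg_area = area, sg_volume = vol,
                    p_est = area / basal_area, d_est = vol / cell_vol)
  if (!is.null(m$cohort)) out$cohort <- m$cohort
  structure(out, class = c("sg_cell_counts", "data.frame"))
}

#' Cohort summaries of estimated cell counts
#'
#' Arithmetic mean and sample standard deviation of the basal and
#' suprabasal estimates, per cohort (or over all glands when no cohort
#' column exists). A single-gland group reports SD = 0 with
#' `sd_defined = FALSE`.
#'
#' @param counts An `"sg_cell_counts"` data frame from [estimate_counts()],
#'   or an [sg_measurements()] table (estimated on the fly).
#' @return Data frame with one row per cohort: `cohort`, `n`, `p_mean`,
#'   `p_sd`, `d_mean`, `d_sd`, `sd_defined`.
#' @export
summarize_counts <- function(counts) {
  if (inherits(counts, "sg_measurements")) counts <- estimate_counts(counts)
  stopifnot(inherits(counts, "sg_cell_counts"))
  if (nrow(counts) == 0L) stop("no glands to summarize")
  grp <- if (is.null(counts$cohort)) rep("all", nrow(counts)) else counts$cohort
  res <- lapply(split(counts, grp), function(g) {
    n <- nrow(g)
    data.frame(cohort = g$cohort[1L] %||% "all", n = n,
               p_mean = mean(g$p_est),
               p_sd = if (n > 1L) stats::sd(g$p_est) else 0,
               d_mean = mean(g$d_est),
               d_sd = if (n > 1L) stats::sd(g$d_est) else 0,
               sd_defined = n > 1L)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
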