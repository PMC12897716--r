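# Trajectory observables: radius of gyration, block-averaged errors,
# radial distribution functions, swelling ratio and the transition
# temperature.

#' Radius of gyration
#'
#' Root-mean-square distance of the selected beads from their centroid,
#' with equal bead masses. Coordinates must be unwrapped: if `bonds` and
#' `box_side` are supplied, any bond longer than half the box is taken as
#' evidence of wrapped input and raises a coordinate error.
#'
#' @param positions N x 3 coordinate matrix (unwrapped).
#' @param indices Optional subset of rows (default: all).
#' @param bonds Optional two-column bond matrix for the wrap check.
#' @param box_side Box side, required for the wrap check.
#' @return Radius of gyration in the units of `positions`.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(4, 0, 0)))  # 2
#' @export
radius_of_gyration <- function(positions, indices = NULL, bonds = NULL,
                               box_side = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (!is.null(indices)) positions <- positions[indices, , drop = FALSE]
  if (nrow(positions) < 2) {
    stop("radius of gyration needs at least two beads", call. = FALSE)
  }
  if (!is.null(bonds) && !is.null(box_side) && nrow(bonds) > 0) {
    bl <- sqrt(rowSums((positions[bonds[, 1], , drop = FALSE] -
                          positions[bonds[, 2], , drop = FALSE])^2))
    if (any(bl > box_side / 2)) {
      stop("coordinate error: bond longer than half the box; ",
           "positions appear to be wrapped", call. = FALSE)
    }
  }
  centred <- sweep(positions, 2, colMeans(positions))
  sqrt(mean(rowSums(centred^2)))
}

#' Per-frame radius of gyration of the polymer
#'
#' @param traj A `trajectory`.
#' @param length_unit Multiplier applied to the reduced value (e.g.
#'   `traj$units$rc * 1e10` for angstrom).
#' @return Numeric vector, one value per frame.
#' @export
rg_series <- function(traj, length_unit = 1) {
  stopifnot(inherits(traj, "trajectory"))
  vapply(traj$frames, function(fr) {
    radius_of_gyration(fr$xyz, traj$polymer_indices, traj$bonds,
                       fr$box_side)
  }, numeric(1)) * length_unit
}

#' Mean and standard error by block averaging
#'
#' Error estimation for correlated series: the data are grouped into an
#' increasing number of blocks, the standard deviation of the block means
#' is computed for each blocking, and the standard error of the mean is
#' read off the plateau of that curve. The plateau window used is 12-25
#' blocks, where the blocks of a well-sampled simulation are effectively
#' independent; the reported SEM is the average over that window.
#'
#' @param series Numeric time series (length >= `2 * max_blocks`).
#' @param min_blocks,max_blocks Plateau window in number of blocks.
#' @return List with `mean`, `sem`, and `sem_by_blocks` (the blocking
#'   curve, for inspection).
#' @export
block_sem <- function(series, min_blocks = 12, max_blocks = 25) {
  n <- length(series)
  if (n < 2 * max_blocks) {
    stop("insufficient data: need at least ", 2 * max_blocks,
         " points for the ", min_blocks, "-", max_blocks, " block window",
         call. = FALSE)
  }
  nb <- min_blocks:max_blocks
  sems <- vapply(nb, function(k) {
    bs <- n %/% k
    m <- matrix(series[seq_len(k * bs)], nrow = bs)
    stats::sd(colMeans(m)) / sqrt(k)
  }, numeric(1))
  list(mean = mean(series), sem = mean(sems),
       sem_by_blocks = data.frame(n_blocks = nb, sem = sems))
}

.traj_group <- function(traj, group) {
  if (is.character(group) && length(group) == 1) {
    which(traj$types == group)
  } else {
    as.integer(group)
  }
}

.shell_volumes <- function(edges) 4 / 3 * pi * diff(edges^3)

#' Radial distribution function between two bead groups
#'
#' Minimum-image pair-distance histogram normalized by the ideal-gas
#' expectation at the groups' densities, averaged over frames with equal
#' weight. When the two groups are identical the distinct-pair convention
#' applies (self-pairs excluded).
#'
#' @param traj A `trajectory`.
#' @param group_a,group_b Bead selections: integer indices or a type name
#'   ("water", "monomer").
#' @param bin_width Histogram bin width (reduced units; default 0.1 rc).
#' @param r_max Histogram range; at most half the box side.
#' @param length_unit Multiplier for the returned `r` axis.
#' @param every Use every `every`-th frame.
#' @return A data.frame with `r` (bin centres) and `g`.
#' @export
rdf_pair <- function(traj, group_a, group_b, bin_width = 0.1,
                     r_max = NULL, length_unit = 1, every = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  box <- traj$box_side
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9) {
    stop("r_max exceeds half the box side", call. = FALSE)
  }
  ia <- .traj_group(traj, group_a)
  ib <- .traj_group(traj, group_b)
  same <- identical(sort(ia), sort(ib))
  nbins <- ceiling(r_max / bin_width)
  edges <- seq(0, by = bin_width, length.out = nbins + 1)
  frames <- traj$frames[seq(1, length(traj$frames), by = every)]
  h <- numeric(nbins)
  for (fr in frames) {
    A <- fr$xyz[ia, , drop = FALSE]
    B <- if (same) A else fr$xyz[ib, , drop = FALSE]
    h <- h + .cpp_pair_hist(A, B, box, nbins * bin_width, nbins, same)
  }
  npairs <- if (same) length(ia) * (length(ia) - 1) / 2 else
    length(ia) * length(ib)
  expected <- npairs * .shell_volumes(edges) / box^3
  g <- h / (length(frames) * expected)
  data.frame(r = (edges[-1] - bin_width / 2) * length_unit, g = g)
}

#' Radial distribution function from a per-frame reference point
#'
#' g(r) between a single reference site per frame - by default the
#' centre of mass of the polymer, computed on unwrapped coordinates and
#' re-wrapped into the box - and a bead group. Low values at small r
#' diagnose solvent exclusion from a collapsed core.
#'
#' @inheritParams rdf_pair
#' @param group Bead selection for the surrounding group.
#' @param point_fun Function(frame, traj) returning the reference point
#'   (length-3, unwrapped); defaults to the polymer centre of mass.
#' @return A data.frame with `r` and `g`.
#' @export
rdf_from_point <- function(traj, group, bin_width = 0.1, r_max = NULL,
                           length_unit = 1, every = 1L,
                           point_fun = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  box <- traj$box_side
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9) {
    stop("r_max exceeds half the box side", call. = FALSE)
  }
  if (is.null(point_fun)) {
    point_fun <- function(fr, tr) {
      colMeans(fr$xyz[tr$polymer_indices, , drop = FALSE])
    }
  }
  ig <- .traj_group(traj, group)
  nbins <- ceiling(r_max / bin_width)
  edges <- seq(0, by = bin_width, length.out = nbins + 1)
  frames <- traj$frames[seq(1, length(traj$frames), by = every)]
  h <- numeric(nbins)
  for (fr in frames) {
    p <- point_fun(fr, traj)
    p <- p - box * floor(p / box)
    h <- h + .cpp_pair_hist(matrix(p, 1, 3), fr$xyz[ig, , drop = FALSE],
                            box, nbins * bin_width, nbins, FALSE)
  }
  expected <- length(ig) * .shell_volumes(edges) / box^3
  g <- h / (length(frames) * expected)
  data.frame(r = (edges[-1] - bin_width / 2) * length_unit, g = g)
}

#' Swelling ratio across temperatures
#'
#' Size at each temperature relative to the size at the reference
#' temperature, Rg(T)/Rg(Tref); the reference is the lowest temperature
#' unless given.
#'
#' @param rg_by_T Named numeric vector (names = temperatures in K) or
#'   two-column data.frame (temperature, Rg).
#' @param T_ref Reference temperature; must be present.
#' @return data.frame with `temperature` and `swelling`.
#' @export
swelling_ratio <- function(rg_by_T, T_ref = NULL) {
  tab <- .as_rg_table(rg_by_T)
  if (is.null(T_ref)) T_ref <- min(tab$temperature)
  i <- match(T_ref, tab$temperature)
  if (is.na(i)) {
    stop("reference temperature ", T_ref, " not present", call. = FALSE)
  }
  data.frame(temperature = tab$temperature,
             swelling = tab$rg / tab$rg[i])
}

.as_rg_table <- function(rg_by_T) {
  if (is.data.frame(rg_by_T)) {
    tab <- data.frame(temperature = rg_by_T[[1]], rg = rg_by_T[[2]])
  } else {
    stopifnot(!is.null(names(rg_by_T)))
    tab <- data.frame(temperature = as.numeric(names(rg_by_T)),
                      rg = as.numeric(rg_by_T))
  }
  tab[order(tab$temperature), ]
}

#' Position of the first peak of a g(r) curve
#'
#' Finds the first local maximum rising above g = 1 and refines its
#' position by parabolic interpolation through the maximum bin and its two
#' neighbours.
#'
#' @param curve data.frame with columns `r` and `g` (>= 3 bins).
#' @return Peak position in the units of `r`, or `NA_real_` if no bin
#'   exceeds 1 at a local maximum (the no-peak sentinel).
#' @export
first_peak_position <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 3)
  g <- curve$g
  r <- curve$r
  n <- length(g)
  for (i in 2:(n - 1)) {
    if (g[i] > 1 && g[i] >= g[i - 1] && g[i] > g[i + 1]) {
      denom <- g[i - 1] - 2 * g[i] + g[i + 1]
      offset <- if (abs(denom) < 1e-300) 0 else
        0.5 * (g[i - 1] - g[i + 1]) / denom
      return(r[i] + offset * (r[i + 1] - r[i]))
    }
  }
  NA_real_
}

#' Maximum-diameter estimate from a monomer-monomer g(r) tail
#'
#' The largest distance at which the pair correlation still exceeds a
#' threshold; with an isolated cluster the monomer-monomer g(r) decays to
#' zero beyond the cluster span, so this tail cutoff approximates the
#' maximum diameter.
#'
#' @param curve data.frame with `r` and `g`.
#' @param threshold Detection level (default 1e-3).
#' @return Largest `r` with `g > threshold` (`NA_real_` if none).
#' @export
max_diameter <- function(curve, threshold = 1e-3) {
  above <- which(curve$g > threshold)
  if (!length(above)) return(NA_real_)
  curve$r[max(above)]
}

#' Transition-temperature bracket
#'
#' Locates the steepest drop of Rg with temperature: the consecutive
#' temperature pair with the largest decrease brackets the volume phase
#' transition.
#'
#' @param rg_by_T Named numeric vector or two-column data.frame as in
#'   [swelling_ratio()]; needs at least 4 temperatures.
#' @return Length-2 numeric vector `(T_low, T_high)`. Returns
#'   `c(NA, NA)` when Rg never decreases (no transition); a bracket whose
#'   drop is not unique (flat/linear input) carries the attribute
#'   `degenerate = TRUE`.
#' @export
transition_temperature <- function(rg_by_T) {
  tab <- .as_rg_table(rg_by_T)
  if (nrow(tab) < 4) {
    stop("need at least 4 temperatures to bracket a transition",
         call. = FALSE)
  }
  drops <- -diff(tab$rg)
  if (max(drops) <= 0) return(c(NA_real_, NA_real_))
  i <- which.max(drops)
  out <- c(tab$temperature[i], tab$temperature[i + 1])
  tol <- 1e-8 * max(abs(drops))
  if (sum(drops >= max(drops) - tol) > 1) attr(out, "degenerate") <- TRUE
  out
}

#' Full analysis of a production trajectory
#'
#' Bundles the standard observables: the Rg time series with block-binned
#' SEM and the three g(r) families (polymer COM to water, monomer-water,
#' monomer-monomer).
#'
#' @param traj A `trajectory`.
#' @param bin_width RDF bin width (reduced).
#' @param length_unit Multiplier for lengths (defaults to angstrom via the
#'   trajectory's unit system, or 1 if absent).
#' @param rdf_every Frame stride for the RDFs.
#' @return An `analysis_result` list: `rg_series`, `rg_mean`, `rg_sem`,
#'   `rdf_com_water`, `rdf_monomer_water`, `rdf_monomer_monomer`.
#' @export
analyze_trajectory <- function(traj, bin_width = 0.1, length_unit = NULL,
                               rdf_every = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(length_unit)) {
    length_unit <- if (!is.null(traj$units)) traj$units$rc * 1e10 else 1
  }
  rg <- rg_series(traj, length_unit)
  bs <- if (length(rg) >= 50) block_sem(rg) else
    list(mean = mean(rg), sem = NA_real_)
  has_water <- any(traj$types == "water")
  res <- list(
    temperature = traj$temperature,
    engine = traj$engine,
    rg_series = rg,
    rg_mean = bs$mean,
    rg_sem = bs$sem,
    rdf_monomer_monomer = rdf_pair(traj, "monomer", "monomer",
                                   bin_width = bin_width,
                                   length_unit = length_unit,
                                   every = rdf_every),
    rdf_monomer_water = if (has_water)
      rdf_pair(traj, "monomer", "water", bin_width = bin_width,
               length_unit = length_unit, every = rdf_every) else NULL,
    rdf_com_water = if (has_water)
      rdf_from_point(traj, "water", bin_width = bin_width,
                     length_unit = length_unit, every = rdf_every) else NULL
  )
  class(res) <- "analysis_result"
  res
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("Analysis (%s, %.5g K): Rg = %.3f +/- %.3f over %d frames\n",
              x$engine, x$temperature, x$rg_mean,
              ifelse(is.na(x$rg_sem), 0, x$rg_sem), length(x$rg_series)))
  invisible(x)
}
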