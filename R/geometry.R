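# Pair-class Cu-Cu distance and coordination-plane orientation statistics.

# The pair classes partition all Cu-Cu pairs of a tetramer: intra-dimer
# pairs live within the preformed dimers (AB, CD), inter-dimer pairs
# across them (AC, AD, BC, BD). For the half-occupancy stoichiometry
# (Cu on A and C only) the intra class is empty and the inter class
# reduces to AC.
PAIR_CLASSES <- c("intra_dimer", "inter_dimer")

pair_in_class <- function(ch1, ch2, cls) {
  dimer <- c(A = 1L, B = 1L, C = 2L, D = 2L)
  same <- dimer[ch1] == dimer[ch2]
  if (cls == "intra_dimer") same else !same
}

#' Cu-Cu distances of one pair class
#'
#' Pools, over all configurations, the Euclidean Cu-Cu distances of the
#' requested pair class (`"intra_dimer"`: AB and CD; `"inter_dimer"`:
#' AC, AD, BC and BD). An empty class for the given stoichiometry (e.g.
#' intra-dimer pairs when only chains A and C carry Cu) returns an empty
#' vector with a message.
#'
#' @param ens an `oligomer_ensemble`.
#' @param class `"intra_dimer"` or `"inter_dimer"`.
#' @param pairs optional restriction to specific chain pairs, e.g. `"AB"`
#'   to exclude CD from the intra class.
#' @return numeric vector of distances, nm.
#' @export
pair_distances <- function(ens, class = c("intra_dimer", "inter_dimer"),
                           pairs = NULL) {
  class <- match.arg(class)
  stopifnot(inherits(ens, "oligomer_ensemble"))
  if (!length(ens$configurations)) stop("ensemble is empty")
  out <- numeric(0)
  for (cfg in ens$configurations) {
    sites <- cfg$cu_sites
    ns <- length(sites)
    if (ns < 2L) next
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      ci <- sites[[i]]$chain; cj <- sites[[j]]$chain
      if (!pair_in_class(ci, cj, class)) next
      if (!is.null(pairs) &&
          !(paste0(ci, cj) %in% pairs || paste0(cj, ci) %in% pairs)) next
      out <- c(out, sqrt(sum((sites[[i]]$cu - sites[[j]]$cu)^2)))
    }
  }
  if (!length(out))
    message(sprintf("no %s Cu pairs for stoichiometry %s",
                    gsub("_", "-", class), ens$stoichiometry))
  out
}

#' Mean and standard deviation of a distance sample
#'
#' Arithmetic mean and population standard deviation (divisor `n`), the
#' summary used for pair-class distance tables.
#'
#' @param distances at least two values, nm.
#' @return named vector `c(mean, sd, n)`.
#' @export
summarize_distances <- function(distances) {
  distances <- as.numeric(distances)
  n <- length(distances)
  if (n < 2L) stop("need at least two distances to summarize")
  m <- mean(distances)
  c(mean = m, sd = sqrt(mean((distances - m)^2)), n = n)
}

#' Normal of a Cu coordination plane
#'
#' Unit vector perpendicular to the plane spanned by the Cu-N(His6) and
#' Cu-N(His13) bonds, \eqn{(n_{His6} - cu) \times (n_{His13} - cu)}
#' normalized. The ligand order (His6 first) fixes the sign convention.
#' This normal is the geometric proxy for the Cu g-tensor z-axis.
#'
#' @param site a Cu site: list with fields `cu`, `n_his6`, `n_his13`
#'   (positions, any consistent unit).
#' @return unit 3-vector.
#' @export
coordination_normal <- function(site) {
  b1 <- site$n_his6 - site$cu
  b2 <- site$n_his13 - site$cu
  v <- c(b1[2] * b2[3] - b1[3] * b2[2],
         b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-9 * sqrt(sum(b1^2)) * sqrt(sum(b2^2)) || nrm == 0)
    stop("Cu-ligand bonds are collinear; coordination plane undefined")
  v / nrm
}

#' Relative orientation of coordination planes
#'
#' For every Cu pair of the requested class, the scalar product of the two
#' coordination-plane unit normals. The angular spread is summarized as
#' the root-mean-square angle \eqn{\sqrt{E[\arccos(s)^2]}} (the circular
#' standard deviation about perfect alignment), in degrees.
#'
#' @param ens an `oligomer_ensemble`.
#' @param class pair class, as in [pair_distances].
#' @param bin_width histogram bin width on the scalar-product axis.
#' @return list with `scalar_products`, `angle_sd_deg`, and a normalized
#'   `histogram` over `[-1, 1]`.
#' @export
orientation_distribution <- function(ens, class = c("intra_dimer", "inter_dimer"),
                                     bin_width = 0.05) {
  class <- match.arg(class)
  stopifnot(inherits(ens, "oligomer_ensemble"))
  sp <- numeric(0)
  for (cfg in ens$configurations) {
    sites <- cfg$cu_sites
    ns <- length(sites)
    if (ns < 2L) next
    normals <- lapply(sites, coordination_normal)
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      if (!pair_in_class(sites[[i]]$chain, sites[[j]]$chain, class)) next
      sp <- c(sp, sum(normals[[i]] * normals[[j]]))
    }
  }
  if (!length(sp)) {
    message(sprintf("no %s Cu pairs for stoichiometry %s",
                    gsub("_", "-", class), ens$stoichiometry))
    return(list(scalar_products = sp, angle_sd_deg = NA_real_, histogram = NULL))
  }
  sp <- pmin(1, pmax(-1, sp))
  ang <- acos(sp)
  breaks <- seq(-1, 1 + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(sp, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  hist <- list(centres = breaks[-length(breaks)] + bin_width / 2,
               density = cnt / (sum(cnt) * bin_width))
  list(scalar_products = sp,
       angle_sd_deg = sqrt(mean(ang^2)) * 180 / pi,
       histogram = hist)
}

#' Radius of gyration of a configuration
#'
#' Mass-unweighted root-mean-square distance of the bead centres from
#' their centroid, in nm. Coarse-grained beads carry no masses, so no
#' mass weighting is applied.
#'
#' @param config one configuration of an `oligomer_ensemble`.
#' @param chains chains to include (default all four).
#' @return radius of gyration, nm.
#' @export
radius_of_gyration <- function(config, chains = c("A", "B", "C", "D")) {
  xyz <- do.call(rbind, config$chains[chains])
  if (is.null(xyz) || nrow(xyz) < 2L) stop("need at least two beads")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums((xyz - rep(ctr, each = nrow(xyz)))^2)))
}
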