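# Solvent-accessible surface area (Shrake-Rupley) and the SASA-ratio
# definition of an assembled tetramer.

#' SASA parameters
#'
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_sphere_points number of test points per atom sphere; the point
#'   set is a deterministic golden-section spiral, so areas are
#'   reproducible bit-for-bit.
#' @return an object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 60)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_params")
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
golden_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of a set of spheres
#'
#' Shrake-Rupley algorithm: for each atom, test points are placed on the
#' probe-expanded sphere of radius \eqn{r_i + probe}; the accessible
#' fraction is the share of points not buried inside any other expanded
#' sphere, and contributes \eqn{4\pi (r_i + probe)^2} times that fraction.
#' The subset is evaluated in isolation: atoms outside it are ignored
#' entirely.
#'
#' @param xyz n x 3 coordinate matrix, Angstrom.
#' @param radii per-atom radii, Angstrom.
#' @param params a [sasa_params].
#' @return total area in Angstrom^2, with attribute `"per_atom"`.
#' @export
sasa <- function(xyz, radii, params = sasa_params()) {
  xyz <- as.matrix(xyz)
  if (!nrow(xyz)) stop("empty atom set")
  if (length(radii) != nrow(xyz))
    stop("missing radius: need one radius per atom (got ", length(radii),
         " for ", nrow(xyz), " atoms)")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("missing radius: all atom radii must be positive and finite; ",
         "offending atom(s): ", paste(which(!is.finite(radii) | radii <= 0),
                                      collapse = ", "))
  n <- nrow(xyz)
  rx <- radii + params$probe_radius
  pts <- golden_sphere_points(params$n_sphere_points)
  areas <- numeric(n)
  # neighbour lists via squared-distance cutoff
  for (i in seq_len(n)) {
    d2 <- rowSums((xyz - rep(xyz[i, ], each = n))^2)
    nb <- which(d2 < (rx + rx[i])^2 & seq_len(n) != i)
    p <- pts * rx[i] + rep(xyz[i, ], each = params$n_sphere_points)
    if (length(nb)) {
      free <- rep(TRUE, nrow(p))
      for (j in nb) {
        if (!any(free)) break
        dj <- rowSums((p[free, , drop = FALSE] -
                         rep(xyz[j, ], each = sum(free)))^2)
        thr <- rx[j]^2
        # points exactly on another expanded surface (degenerate overlap,
        # e.g. coincident identical spheres) are credited to the
        # lower-indexed atom, so the shared surface is counted once
        buried <- dj < thr * (1 - 1e-10) | (dj < thr * (1 + 1e-10) & j < i)
        free[free] <- !buried
      }
      frac <- mean(free)
    } else frac <- 1
    areas[i] <- 4 * pi * rx[i]^2 * frac
  }
  structure(sum(areas), per_atom = areas)
}

# SASA of selected chains of one configuration (complementary chains
# removed, no re-relaxation), in Angstrom^2.
sasa_chains <- function(config, chains, params = sasa_params(),
                        radius_table = c(bead = 3.0, CU = 1.4, N = 1.55)) {
  at <- config_atoms(config, chains, radius_table)
  as.numeric(sasa(at$xyz, at$radii, params))
}

#' SASA-ratio tetramer filter
#'
#' A configuration counts as an assembled tetramer when the total
#' solvent-accessible surface area of the four chains is lower than 0.95
#' of the sum of the areas of its two constituent dimers evaluated in
#' isolation:
#' \deqn{SASA(ABCD) / (SASA(AB) + SASA(CD)) < 0.95.}
#' Separated dimers bury no mutual surface and give a ratio of 1; contact
#' between the dimers buries area and pushes the ratio below the
#' threshold. The inequality is strict: a ratio of exactly 0.95 is
#' rejected.
#'
#' @param config one configuration (chains A-D present).
#' @param params a [sasa_params].
#' @param threshold ratio threshold (default 0.95).
#' @return logical: assembled or not, with attributes `"ratio"`,
#'   `"sasa_abcd"`, `"sasa_ab"`, `"sasa_cd"`.
#' @export
tetramer_filter <- function(config, params = sasa_params(), threshold = 0.95) {
  s_abcd <- sasa_chains(config, c("A", "B", "C", "D"), params)
  s_ab <- sasa_chains(config, c("A", "B"), params)
  s_cd <- sasa_chains(config, c("C", "D"), params)
  if (s_ab + s_cd <= 0) stop("zero dimer surface area; ratio undefined")
  ratio <- s_abcd / (s_ab + s_cd)
  structure(ratio < threshold, ratio = ratio,
            sasa_abcd = s_abcd, sasa_ab = s_ab, sasa_cd = s_cd)
}

#' Tetramer filter over an ensemble
#'
#' Applies [tetramer_filter] to every configuration.
#'
#' @param ens an `oligomer_ensemble`.
#' @param params a [sasa_params].
#' @param threshold ratio threshold.
#' @return data frame with columns `model`, `ratio`, `assembled`; the
#'   accepted fraction is attached as attribute `"fraction"`.
#' @export
filter_tetramers <- function(ens, params = sasa_params(), threshold = 0.95) {
  stopifnot(inherits(ens, "oligomer_ensemble"))
  res <- lapply(ens$configurations, tetramer_filter,
                params = params, threshold = threshold)
  out <- data.frame(model = seq_along(res),
                    ratio = vapply(res, attr, 0, "ratio"),
                    assembled = vapply(res, as.logical, TRUE))
  structure(out, fraction = mean(out$assembled))
}
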