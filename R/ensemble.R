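# Synthetic coarse-grained Cu-Abeta tetramer ensembles.
#
# Tetramers are built as dimers of dimers (chains A+B and C+D). Each
# configuration places four Cu sites with prescribed pair-distance laws
# (intra-dimer AB/CD and inter-dimer AC/AD/BC/BD), attaches His6/His13
# ligand pseudo-atoms defining a coordination plane per Cu, and surrounds
# each chain with a compact bead-per-residue cloud so that surface-area
# and gyration statistics are meaningful.

#' Specification of a synthetic tetramer ensemble
#'
#' Parameters of the generator. Distance laws are (mixtures of) normal
#' distributions truncated at 0.3 nm, the hard-sphere Cu-Cu contact.
#' `intra_mean`/`intra_sd` may be vectors to request an equal-weight (or
#' `intra_weight`-weighted) mixture, e.g. the bimodal law of
#' non-cross-linked dimers.
#'
#' Stoichiometries: `"Cu1"` one Cu per chain, no cross-link; `"Cub"` one Cu
#' per chain with intra-dimer cross-links (geometrically: a tighter,
#' unimodal intra-dimer law); `"Cuh"` one Cu per dimer, carried by chains A
#' and C only, so only the AC pair exists.
#'
#' @param n_configs number of configurations (models).
#' @param stoichiometry `"Cu1"`, `"Cub"` or `"Cuh"`.
#' @param intra_mean,intra_sd intra-dimer Cu-Cu law, nm (vectors allowed).
#' @param intra_weight mixture weights for vector laws.
#' @param inter_mean,inter_sd inter-dimer Cu-Cu law, nm.
#' @param plane_angle_sd spread (degrees) of the angle between coordination
#'   plane normals of the two Cu sites within a dimer.
#' @param compactness in (0, 1]; 1 keeps the inter-dimer placement implied
#'   by the distance laws, smaller values push the two dimers apart by
#'   scaling their centre separation with `1/compactness` (emulating
#'   non-assembled configurations).
#' @param beads_per_chain residues per coarse-grained chain.
#' @param chain_radius confinement radius of each chain's bead cloud, nm.
#' @param chain_pull fraction by which chain anchors are pulled from their
#'   Cu site toward the tetramer centre (packs the core).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_configs = 100,
                          stoichiometry = c("Cub", "Cu1", "Cuh"),
                          intra_mean = 2.0, intra_sd = 0.2,
                          intra_weight = NULL,
                          inter_mean = 3.6, inter_sd = 0.9,
                          plane_angle_sd = 20,
                          compactness = 1,
                          beads_per_chain = 42,
                          chain_radius = 1.2,
                          chain_pull = 0.7,
                          seed = NULL) {
  stoichiometry <- match.arg(stoichiometry)
  stopifnot(n_configs >= 1, length(intra_mean) == length(intra_sd),
            all(intra_sd >= 0), all(inter_sd >= 0), length(inter_mean) == 1L,
            compactness > 0, compactness <= 1,
            beads_per_chain >= 1, chain_radius > 0,
            chain_pull >= 0, chain_pull <= 1,
            plane_angle_sd >= 0)
  if (any(intra_mean <= 0.3) || any(intra_mean >= 10))
    stop("infeasible geometry: `intra_mean` must lie in (0.3, 10) nm ",
         "(0.3 nm is the hard-sphere Cu-Cu contact)")
  if (inter_mean <= 0.3 || inter_mean >= 10)
    stop("infeasible geometry: `inter_mean` must lie in (0.3, 10) nm")
  if (is.null(intra_weight)) intra_weight <- rep(1, length(intra_mean))
  intra_weight <- intra_weight / sum(intra_weight)
  structure(list(n_configs = as.integer(n_configs),
                 stoichiometry = stoichiometry,
                 intra_mean = intra_mean, intra_sd = intra_sd,
                 intra_weight = intra_weight,
                 inter_mean = inter_mean, inter_sd = inter_sd,
                 plane_angle_sd = plane_angle_sd,
                 compactness = compactness,
                 beads_per_chain = as.integer(beads_per_chain),
                 chain_radius = chain_radius, chain_pull = chain_pull,
                 seed = seed),
            class = "ensemble_spec")
}

CU_CONTACT_NM <- 0.3     # truncation bound of all distance laws
CU_N_BOND_NM <- 0.20     # Cu-N(His) coordination bond length

# Draw n values from a truncated-normal mixture law.
draw_mixture <- function(n, mean, sd, weight) {
  if (length(mean) == 1L) return(rnorm_trunc(n, mean, sd, CU_CONTACT_NM))
  comp <- sample.int(length(mean), n, replace = TRUE, prob = weight)
  out <- numeric(n)
  for (i in seq_along(mean)) {
    idx <- comp == i
    if (any(idx)) out[idx] <- rnorm_trunc(sum(idx), mean[i], sd[i], CU_CONTACT_NM)
  }
  out
}

# --- Feasibility of a 4-point distance set -------------------------------
# Four points with pair distances (AB, AC, AD, BC, BD, CD) embed in R^3
# iff the Gram matrix anchored at A is positive semidefinite. All
# arguments are vectors (one entry per candidate configuration); returns a
# logical vector. Checked through the principal minors.
quad_feasible <- function(ab, ac, ad, bc, bd, cd) {
  g11 <- ab^2; g22 <- ac^2; g33 <- ad^2
  g12 <- (ab^2 + ac^2 - bc^2) / 2
  g13 <- (ab^2 + ad^2 - bd^2) / 2
  g23 <- (ac^2 + ad^2 - cd^2) / 2
  m12 <- g11 * g22 - g12^2
  m13 <- g11 * g33 - g13^2
  m23 <- g22 * g33 - g23^2
  det3 <- g11 * (g22 * g33 - g23^2) - g12 * (g12 * g33 - g13 * g23) +
    g13 * (g12 * g23 - g13 * g22)
  scale <- pmax(g11, g22, g33)
  m12 >= -1e-9 * scale^2 & m13 >= -1e-9 * scale^2 & m23 >= -1e-9 * scale^2 &
    det3 >= -1e-9 * scale^3
}

# Embed one feasible distance set: returns 4 x 3 coordinates (A B C D rows),
# A at the origin. Chirality of D is randomized by the caller's RNG.
embed_quad <- function(ab, ac, ad, bc, bd, cd) {
  bx <- ab
  cx <- (ab^2 + ac^2 - bc^2) / (2 * ab)
  cy <- sqrt(max(0, ac^2 - cx^2))
  dx <- (ab^2 + ad^2 - bd^2) / (2 * ab)
  dy <- if (cy > 0) (ac^2 + ad^2 - cd^2 - 2 * cx * dx) / (2 * cy) else 0
  dz <- sqrt(max(0, ad^2 - dx^2 - dy^2)) * sample(c(-1, 1), 1L)
  rbind(A = c(0, 0, 0), B = c(bx, 0, 0), C = c(cx, cy, 0), D = c(dx, dy, dz))
}

# --- Calibration of the inter-pair proposal ------------------------------
# Rejection on geometric feasibility truncates the joint law of the four
# inter-dimer distances, which would bias the accepted marginals. The
# proposal (mean, sd) is therefore calibrated by a damped moment-matching
# fixed point so that the *accepted* inter distances reproduce the
# requested law. The calibration is a deterministic numerical solve (own
# fixed internal RNG substream) and is cached per distance law.
.calib_cache <- new.env(parent = emptyenv())

calibrate_inter_proposal <- function(spec, n_cal = 20000L, iterations = 6L) {
  key <- paste(c(spec$intra_mean, spec$intra_sd, spec$intra_weight,
                 spec$inter_mean, spec$inter_sd), collapse = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  tm <- spec$inter_mean; ts <- spec$inter_sd
  mu <- tm; sg <- ts
  with_seed(761543, {
    for (it in seq_len(iterations)) {
      ab <- draw_mixture(n_cal, spec$intra_mean, spec$intra_sd, spec$intra_weight)
      cd <- draw_mixture(n_cal, spec$intra_mean, spec$intra_sd, spec$intra_weight)
      acc <- accept_quadruples(ab, cd, mu, sg)
      inter <- c(acc$ac, acc$ad, acc$bc, acc$bd)
      if (ts > 0) {
        mu <- mu + 0.9 * (tm - mean(inter))
        sg <- max(1e-6, sg * (ts / sd(inter))^0.9)
      } else {
        mu <- mu + 0.9 * (tm - mean(inter))
      }
    }
  })
  out <- list(mu = mu, sg = sg)
  .calib_cache[[key]] <- out
  out
}

# Vectorized rejection sampler: for each configuration draw inter-pair
# quadruples from the proposal until the six distances are embeddable.
accept_quadruples <- function(ab, cd, mu, sg, max_rounds = 10000L) {
  n <- length(ab)
  ac <- ad <- bc <- bd <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    m <- length(todo)
    if (!m) break
    pac <- rnorm_trunc(m, mu, sg, CU_CONTACT_NM)
    pad <- rnorm_trunc(m, mu, sg, CU_CONTACT_NM)
    pbc <- rnorm_trunc(m, mu, sg, CU_CONTACT_NM)
    pbd <- rnorm_trunc(m, mu, sg, CU_CONTACT_NM)
    ok <- quad_feasible(ab[todo], pac, pad, pbc, pbd, cd[todo])
    idx <- todo[ok]
    ac[idx] <- pac[ok]; ad[idx] <- pad[ok]; bc[idx] <- pbc[ok]; bd[idx] <- pbd[ok]
    todo <- todo[!ok]
  }
  if (length(todo))
    stop("infeasible geometry: inter-dimer distance law incompatible with ",
         "the intra-dimer law (rejection sampling did not terminate)")
  list(ac = ac, ad = ad, bc = bc, bd = bd)
}

# --- Chain clouds --------------------------------------------------------
# Confined random walk: bead-per-residue chain with 0.38 nm steps kept
# within `radius` of the anchor.
chain_cloud <- function(anchor, n_beads, radius, step = 0.38) {
  x <- matrix(NA_real_, n_beads, 3)
  x[1, ] <- anchor + runif_sphere(1) * runif(1) * radius * 0.5
  if (n_beads == 1L) return(x)
  for (i in 2:n_beads) {
    nxt <- x[i - 1, ] + step * runif_sphere(1)
    d <- sqrt(sum((nxt - anchor)^2))
    if (d > radius) nxt <- anchor + (nxt - anchor) * (radius / d)
    x[i, ] <- nxt
  }
  x
}

# One Cu site: position plus the two His-nitrogen ligands spanning the
# coordination plane. `normal` is the requested plane normal; the ligands
# are laid out so that (n_his6 - cu) x (n_his13 - cu) points along it.
make_cu_site <- function(chain, cu, normal) {
  normal <- normal / sqrt(sum(normal^2))
  e1 <- perp_vector(normal)
  az <- 2 * pi * runif(1)
  e1 <- as.vector(rotate_about(matrix(e1, 1), normal, az))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(chain = chain,
       cu = cu,
       n_his6 = cu + CU_N_BOND_NM * e1,
       n_his13 = cu + CU_N_BOND_NM * e2)
}

#' Generate a synthetic tetramer ensemble
#'
#' Draws `spec$n_configs` tetramer configurations. Intra-dimer Cu-Cu
#' distances follow the requested (possibly mixture) truncated-normal law
#' exactly; inter-dimer distances follow the inter law through a
#' feasibility-calibrated rejection sampler (see [ensemble_spec]).
#' Within-dimer coordination-plane normals are drawn with angular spread
#' `plane_angle_sd`; normals of different dimers are uncorrelated.
#'
#' @param spec an [ensemble_spec].
#' @return an object of class `oligomer_ensemble`: list of configurations,
#'   each with `chains` (named list of bead coordinate matrices, nm),
#'   `radii` (per-bead radii, Angstrom) and `cu_sites`.
#' @examples
#' ens <- generate_ensemble(ensemble_spec(n_configs = 5, seed = 1))
#' length(ens$configurations)
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  cuh <- spec$stoichiometry == "Cuh"
  prop <- if (!cuh) calibrate_inter_proposal(spec) else NULL
  with_seed(spec$seed, {
    n <- spec$n_configs
    ab <- draw_mixture(n, spec$intra_mean, spec$intra_sd, spec$intra_weight)
    cd <- draw_mixture(n, spec$intra_mean, spec$intra_sd, spec$intra_weight)
    configs <- vector("list", n)
    if (cuh) {
      acd <- rnorm_trunc(n, spec$inter_mean, spec$inter_sd, CU_CONTACT_NM)
      for (i in seq_len(n))
        configs[[i]] <- build_config_cuh(acd[i], spec)
    } else {
      acc <- accept_quadruples(ab, cd, prop$mu, prop$sg)
      for (i in seq_len(n))
        configs[[i]] <- build_config_4cu(
          ab[i], acc$ac[i], acc$ad[i], acc$bc[i], acc$bd[i], cd[i], spec)
    }
    structure(list(configurations = configs,
                   stoichiometry = spec$stoichiometry,
                   spec = spec),
              class = "oligomer_ensemble")
  })
}

# Shared tail of configuration building: chains, compactness, site normals.
finish_config <- function(cu_pos, cu_chain, dimer_of_site, spec) {
  chains <- c("A", "B", "C", "D")
  # coordination-plane normals: one reference per dimer; within a dimer the
  # second site is tilted from the first by a signed N(0, plane_angle_sd)
  # angle about a random in-plane axis, so the within-dimer angle is |delta|.
  refs <- list(runif_sphere(1)[1, ], runif_sphere(1)[1, ])
  sigma <- spec$plane_angle_sd * pi / 180
  normals <- vector("list", length(cu_chain))
  seen_dimer <- integer(0)
  for (s in seq_along(cu_chain)) {
    d <- dimer_of_site[s]
    if (d %in% seen_dimer) {
      delta <- rnorm(1, 0, sigma)
      axis <- perp_vector(refs[[d]])
      axis <- as.vector(rotate_about(matrix(axis, 1), refs[[d]], 2 * pi * runif(1)))
      normals[[s]] <- as.vector(rotate_about(matrix(refs[[d]], 1), axis, delta))
    } else {
      normals[[s]] <- refs[[d]]
      seen_dimer <- c(seen_dimer, d)
    }
  }
  # chain anchors: Cu-bearing chains sit at their Cu pulled toward the
  # tetramer centre; Cu-free chains next to their dimer partner.
  centre <- colMeans(cu_pos)
  anchor <- matrix(NA_real_, 4, 3, dimnames = list(chains, NULL))
  for (ch in chains) {
    s <- match(ch, cu_chain)
    if (!is.na(s)) {
      anchor[ch, ] <- cu_pos[s, ] + spec$chain_pull * (centre - cu_pos[s, ])
    }
  }
  for (ch in chains[is.na(match(chains, cu_chain))]) {
    partner <- switch(ch, A = "B", B = "A", C = "D", D = "C")
    anchor[ch, ] <- anchor[partner, ] + runif_sphere(1)[1, ] * 0.5
  }
  # compactness < 1 pushes dimer CD away from AB along the centre axis.
  if (spec$compactness < 1) {
    c_ab <- colMeans(anchor[c("A", "B"), , drop = FALSE])
    c_cd <- colMeans(anchor[c("C", "D"), , drop = FALSE])
    axis <- c_cd - c_ab
    nrm <- sqrt(sum(axis^2))
    if (nrm < 1e-9) { axis <- c(1, 0, 0); nrm <- 1 } else axis <- axis / nrm
    shift <- axis * nrm * (1 / spec$compactness - 1)
    for (ch in c("C", "D")) anchor[ch, ] <- anchor[ch, ] + shift
    for (s in seq_along(cu_chain))
      if (cu_chain[s] %in% c("C", "D")) cu_pos[s, ] <- cu_pos[s, ] + shift
  }
  beads <- lapply(chains, function(ch)
    chain_cloud(anchor[ch, ], spec$beads_per_chain, spec$chain_radius))
  names(beads) <- chains
  sites <- lapply(seq_along(cu_chain), function(s)
    make_cu_site(cu_chain[s], cu_pos[s, ], normals[[s]]))
  list(chains = beads,
       radii = rep(3.0, spec$beads_per_chain),  # Angstrom, per bead
       cu_sites = sites)
}

build_config_4cu <- function(ab, ac, ad, bc, bd, cd, spec) {
  pos <- embed_quad(ab, ac, ad, bc, bd, cd)
  # random rigid motion so ensembles are not aligned to a frame
  axis <- runif_sphere(1)[1, ]
  pos <- rotate_about(pos, axis, 2 * pi * runif(1))
  finish_config(pos, cu_chain = c("A", "B", "C", "D"),
                dimer_of_site = c(1L, 1L, 2L, 2L), spec = spec)
}

build_config_cuh <- function(acd, spec) {
  pos <- rbind(c(0, 0, 0), c(acd, 0, 0))
  axis <- runif_sphere(1)[1, ]
  pos <- rotate_about(pos, axis, 2 * pi * runif(1))
  finish_config(pos, cu_chain = c("A", "C"),
                dimer_of_site = c(1L, 2L), spec = spec)
}

#' @export
print.oligomer_ensemble <- function(x, ...) {
  cat(sprintf("Oligomer ensemble: %d configurations, stoichiometry %s\n",
              length(x$configurations), x$stoichiometry))
  ns <- length(x$configurations[[1]]$cu_sites)
  cat(sprintf("  %d Cu sites and %d chains per configuration\n",
              ns, length(x$configurations[[1]]$chains)))
  invisible(x)
}

#' @export
summary.oligomer_ensemble <- function(object, ...) {
  intra <- pair_distances(object, "intra_dimer")
  inter <- pair_distances(object, "inter_dimer")
  out <- list(
    n_configs = length(object$configurations),
    stoichiometry = object$stoichiometry,
    intra = if (length(intra) >= 2) summarize_distances(intra) else NULL,
    inter = if (length(inter) >= 2) summarize_distances(inter) else NULL
  )
  class(out) <- "summary.oligomer_ensemble"
  out
}

#' @export
print.summary.oligomer_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d %s tetramers\n", x$n_configs, x$stoichiometry))
  if (!is.null(x$intra))
    cat(sprintf("  intra-dimer Cu-Cu: %.2f +/- %.2f nm\n",
                x$intra["mean"], x$intra["sd"]))
  if (!is.null(x$inter))
    cat(sprintf("  inter-dimer Cu-Cu: %.2f +/- %.2f nm\n",
                x$inter["mean"], x$inter["sd"]))
  invisible(x)
}
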