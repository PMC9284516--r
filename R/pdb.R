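# Multi-model PDB input/output for coarse-grained tetramer ensembles.
#
# Naming convention (documented contract between the generator and the
# readers): one MODEL block per configuration; chains A-D; one ATOM record
# per residue bead (name CA, residue ALA, numbered from 1); per Cu site a
# HETATM group sharing the chain and a residue number >= 901:
#   CU  / residue CU   - the copper ion (element CU)
#   ND1 / residue CUL  - His6-role  N-delta ligand pseudo-atom (element N)
#   NE2 / residue CUL  - His13-role N-epsilon ligand pseudo-atom (element N)
# Coordinates are in Angstrom in the file and nm in memory (factor 10).

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens an `oligomer_ensemble` from [generate_ensemble].
#' @param file output path.
#' @param remarks extra character lines written as `REMARK` records; the
#'   generator seed is recorded automatically when known.
#' @return `file`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, file, remarks = NULL) {
  stopifnot(inherits(ens, "oligomer_ensemble"))
  con <- file(file, "w")
  on.exit(close(con))
  hdr <- c(sprintf("REMARK   6 STOICHIOMETRY %s", ens$stoichiometry),
           if (!is.null(ens$spec$seed))
             sprintf("REMARK   6 SEED %d", as.integer(ens$spec$seed)),
           if (!is.null(remarks)) paste("REMARK   6", remarks))
  writeLines(hdr, con)
  fmt <- "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (m in seq_along(ens$configurations)) {
    cfg <- ens$configurations[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (ch in names(cfg$chains)) {
      xyz <- cfg$chains[[ch]] * 10   # nm -> Angstrom
      for (i in seq_len(nrow(xyz))) {
        serial <- serial + 1L
        writeLines(sprintf(fmt, "ATOM", serial, "CA", "ALA", ch, i,
                           xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, "C"), con)
      }
    }
    site_no <- integer(0)
    for (s in cfg$cu_sites) {
      ch <- s$chain
      site_no[ch] <- (if (is.na(site_no[ch] %||% NA)) 0L else site_no[ch]) + 1L
      res <- 900L + site_no[ch]
      at <- rbind(s$cu, s$n_his6, s$n_his13) * 10
      nm <- c("CU", "ND1", "NE2"); rn <- c("CU", "CUL", "CUL")
      el <- c("CU", "N", "N")
      for (i in 1:3) {
        serial <- serial + 1L
        writeLines(sprintf(fmt, "HETATM", serial, nm[i], rn[i], ch, res,
                           at[i, 1], at[i, 2], at[i, 3], 1, 0, el[i]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    name = trimws(substr(lines, 13, 16)),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resid = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE
  )
}

#' Read a multi-model PDB ensemble
#'
#' Parses a multi-model PDB following the naming convention described in
#' [write_ensemble_pdb]: chains A-D of residue beads plus per-site HETATM
#' groups (CU with ND1/NE2 ligand records sharing its residue number).
#' Models missing a chain, a Cu, or a ligand atom -- or whose ligands sit
#' further than 3.5 Angstrom from their Cu -- are skipped with a warning
#' naming the model and the defect.
#'
#' @param file path to a PDB file.
#' @param bead_radius radius assigned to chain beads, Angstrom.
#' @return an `oligomer_ensemble`.
#' @export
read_ensemble <- function(file, bead_radius = 3.0) {
  raw <- readLines(file)
  starts <- grep("^MODEL", raw)
  ends <- grep("^ENDMDL", raw)
  blocks <- if (length(starts)) {
    if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records")
    Map(function(s, e) raw[(s + 1):(e - 1)], starts, ends)
  } else list(raw)
  stoich <- sub(".*STOICHIOMETRY +", "",
                grep("REMARK.*STOICHIOMETRY", raw, value = TRUE)[1])
  configs <- list()
  for (m in seq_along(blocks)) {
    at <- parse_pdb_atoms(blocks[[m]])
    bad <- NULL
    chains <- list()
    for (ch in c("A", "B", "C", "D")) {
      sel <- at$record == "ATOM" & at$chain == ch
      if (!any(sel)) { bad <- sprintf("missing chain %s", ch); break }
      xyz <- as.matrix(at[sel, c("x", "y", "z")]) / 10
      dimnames(xyz) <- NULL
      chains[[ch]] <- xyz
    }
    sites <- list()
    if (is.null(bad)) {
      het <- at[at$record == "HETATM", , drop = FALSE]
      if (!nrow(het)) bad <- "no Cu HETATM records"
      else {
        grp <- split(het, paste(het$chain, het$resid))
        for (g in grp) {
          pos <- function(nm) {
            i <- which(g$name == nm)
            if (length(i) != 1L) return(NULL)
            as.numeric(g[i, c("x", "y", "z")]) / 10
          }
          cu <- pos("CU"); n6 <- pos("ND1"); n13 <- pos("NE2")
          if (is.null(cu) || is.null(n6) || is.null(n13)) {
            bad <- sprintf("incomplete Cu site on chain %s residue %d",
                           g$chain[1], g$resid[1])
            break
          }
          if (sqrt(sum((n6 - cu)^2)) > 0.35 || sqrt(sum((n13 - cu)^2)) > 0.35) {
            bad <- sprintf("ligand atom beyond 3.5 A of Cu on chain %s", g$chain[1])
            break
          }
          sites[[length(sites) + 1L]] <-
            list(chain = g$chain[1], cu = cu, n_his6 = n6, n_his13 = n13)
        }
        if (is.null(bad)) {
          ord <- order(vapply(sites, `[[`, "", "chain"))
          sites <- sites[ord]
        }
      }
    }
    if (!is.null(bad)) {
      warning(sprintf("model %d skipped: %s", m, bad), call. = FALSE)
      next
    }
    configs[[length(configs) + 1L]] <-
      list(chains = chains,
           radii = rep(bead_radius, nrow(chains[["A"]])),
           cu_sites = sites)
  }
  if (!length(configs)) stop("no usable models in ", file)
  if (!(stoich %in% c("Cu1", "Cub", "Cuh")))
    stoich <- if (length(configs[[1]]$cu_sites) == 2L) "Cuh" else "Cu1"
  structure(list(configurations = configs, stoichiometry = stoich, spec = NULL),
            class = "oligomer_ensemble")
}

# Flatten one configuration's selected chains into coordinates (Angstrom)
# and radii (Angstrom) for surface-area work. Chain beads plus the Cu and
# ligand pseudo-atoms of Cu sites on those chains.
config_atoms <- function(config, chains = c("A", "B", "C", "D"),
                         radius_table = c(bead = 3.0, CU = 1.4, N = 1.55)) {
  xyz <- NULL; rad <- NULL
  for (ch in chains) {
    b <- config$chains[[ch]]
    if (is.null(b)) stop("configuration lacks chain ", ch)
    xyz <- rbind(xyz, b * 10)
    rad <- c(rad, rep(radius_table[["bead"]], nrow(b)))
  }
  for (s in config$cu_sites) {
    if (!(s$chain %in% chains)) next
    xyz <- rbind(xyz, s$cu * 10, s$n_his6 * 10, s$n_his13 * 10)
    rad <- c(rad, radius_table[["CU"]], radius_table[["N"]], radius_table[["N"]])
  }
  list(xyz = xyz, radii = rad)
}
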