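# Deterministic Fibonacci-spiral directions on the unit sphere; seedless,
# so the solvent-accessible surface sampler is fully reproducible.
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  phi <- k * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

#' Sample the solvent-accessible surface of a structure
#'
#' Shrake-Rupley style sphere sampling: every atom is covered with a
#' deterministic spiral of \code{points_per_atom} points on its probe-
#' inflated sphere (radius + probe) and points falling inside any other
#' atom's inflated sphere are discarded. Surviving points form the
#' solvent-accessible surface; each carries the residue identity of its
#' parent atom and an electrostatic value initialised to 0 (see
#' \code{\link{assign_electrostatics}}).
#'
#' @param structure A \code{zern_structure}.
#' @param probe Probe (water) radius in Angstrom, default 1.4.
#' @param points_per_atom Spiral points per atom, default 256.
#' @return A \code{zern_cloud} with \code{source = "computed"}.
#' @export
sample_sas <- function(structure, probe = 1.4, points_per_atom = 256L) {
  a <- structure$atoms
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rr <- a$radius + probe
  dirs <- fibonacci_sphere(points_per_atom)
  d2 <- as.matrix(dist(xyz))^2
  keys <- residue_keys(structure)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * rr[i], 2L, xyz[i, ], "+")
    neigh <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    keep <- rep(TRUE, points_per_atom)
    for (j in neigh) {
      dx <- pts[, 1L] - xyz[j, 1L]
      dy <- pts[, 2L] - xyz[j, 2L]
      dz <- pts[, 3L] - xyz[j, 3L]
      keep <- keep & (dx * dx + dy * dy + dz * dz >= rr[j]^2)
      if (!any(keep)) break
    }
    if (any(keep))
      out[[i]] <- data.frame(x = pts[keep, 1L], y = pts[keep, 2L],
                             z = pts[keep, 3L], es = 0,
                             residue_key = keys[i], atom_row = i,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(df) || nrow(df) == 0L)
    stop("structure has no solvent-accessible surface at this probe radius")
  rownames(df) <- NULL
  cl <- new_cloud(df, probe = probe, source = "computed")
  attr(cl, "points_per_atom") <- points_per_atom
  cl
}

#' Per-residue solvent-accessible surface area
#'
#' Integrates the retained fraction of each atom's sampled sphere:
#' SASA(atom) = retained/total * 4 pi (radius + probe)^2, summed over the
#' atoms of each residue. Reported in nm^2 (1 nm^2 = 100 A^2), the unit
#' used throughout the decoy machinery.
#'
#' @inheritParams sample_sas
#' @return Named numeric vector, residue key -> SASA in nm^2 (buried
#'   residues report 0).
#' @export
residue_sasa <- function(structure, probe = 1.4, points_per_atom = 256L) {
  a <- structure$atoms
  keys <- residue_keys(structure)
  cl <- tryCatch(sample_sas(structure, probe, points_per_atom),
                 error = function(e) NULL)
  all_keys <- unique(keys)
  sasa <- setNames(rep(0, length(all_keys)), all_keys)
  if (is.null(cl)) return(sasa)
  area_per_pt <- 4 * pi * (a$radius + probe)^2 / points_per_atom
  contrib <- rowsum(area_per_pt[cl$atom_row], cl$residue_key)
  sasa[rownames(contrib)] <- contrib[, 1L] / 100  # A^2 -> nm^2
  sasa
}

# Theoretical maximum accessible surface areas per residue type
# (Tien et al. 2013 theoretical values), in A^2
max_sasa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

#' Relative solvent accessibility per residue
#'
#' Residue SASA divided by a per-amino-acid reference maximum (theoretical
#' maxima bundled; override or extend via \code{reference}). Values above
#' 1 are possible for unusually exposed conformations.
#'
#' @inheritParams sample_sas
#' @param reference Named vector of reference maxima in A^2; defaults to
#'   the bundled table.
#' @param unknown_res_ref Fallback reference (A^2) for residue names
#'   absent from the table; when \code{NULL} (default) such residues are
#'   an error.
#' @return Named numeric vector, residue key -> relative SASA.
#' @export
relative_sasa <- function(structure, probe = 1.4, points_per_atom = 256L,
                          reference = max_sasa_reference(),
                          unknown_res_ref = NULL) {
  sasa <- residue_sasa(structure, probe, points_per_atom)
  a <- structure$atoms
  keys <- residue_keys(structure)
  resname <- a$resname[!duplicated(keys)]
  names(resname) <- keys[!duplicated(keys)]
  refs <- reference[resname[names(sasa)]]
  unknown <- is.na(refs)
  if (any(unknown)) {
    if (is.null(unknown_res_ref))
      stop("no reference SASA for residue name(s): ",
           paste(unique(resname[names(sasa)][unknown]), collapse = ", "),
           "; supply `unknown_res_ref`")
    refs[unknown] <- unknown_res_ref
  }
  sasa / (unname(refs) / 100)  # reference A^2 -> nm^2
}

# heavy side-chain centroid of each residue (falls back to all heavy
# atoms for glycine-like residues, then to all atoms)
residue_centroids <- function(structure) {
  a <- structure$atoms
  keys <- residue_keys(structure)
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- !(a$name %in% backbone) & a$element != "H"
  pick <- side
  # residues with no side-chain heavy atoms: use all their atoms
  has_side <- tapply(pick, keys, any)
  fallback <- keys %in% names(has_side)[!has_side]
  pick[fallback] <- TRUE
  xyz <- as.matrix(a[pick, c("x", "y", "z")])
  k <- keys[pick]
  cx <- rowsum(xyz, k)
  cnt <- as.vector(rowsum(rep(1, length(k)), k))
  sweep(cx, 1L, cnt, "/")
}

#' Assign electrostatic values to a surface point cloud
#'
#' In \code{residue_coulomb} mode, the potential of each residue is a
#' screened Coulomb sum over all atoms of the structure, evaluated at the
#' residue's side-chain centroid:
#' phi(R) = sum_j q_j exp(-d_j / lambda) / (epsilon d_j), with
#' Debye-like screening length \code{lambda} (Angstrom) and uniform
#' dielectric \code{epsilon}; distances are floored at \code{d_floor}
#' so the residue's own charges dominate its sign without a singularity. Every surface point of a residue receives
#' that residue's single value, so the per-residue constancy of the
#' electrostatic surface convention holds exactly. In
#' \code{per_point_file} mode a user-supplied vector (e.g. from an
#' external Poisson-Boltzmann or generalized-Born run) is attached
#' instead, one value per point.
#'
#' @param cloud A \code{zern_cloud}.
#' @param structure The originating \code{zern_structure}
#'   (\code{residue_coulomb} mode).
#' @param mode \code{"residue_coulomb"} (default) or \code{"per_point_file"}.
#' @param epsilon Relative dielectric constant (default 80).
#' @param screen Screening length lambda in Angstrom (default 8).
#' @param d_floor Minimum interaction distance in Angstrom (default 1).
#' @param values Per-point potential values (\code{per_point_file} mode).
#' @return The cloud with its \code{es} column filled.
#' @export
assign_electrostatics <- function(cloud, structure = NULL,
                                  mode = c("residue_coulomb", "per_point_file"),
                                  epsilon = 80, screen = 8, d_floor = 1,
                                  values = NULL) {
  mode <- match.arg(mode)
  if (mode == "per_point_file") {
    if (is.null(values) || length(values) != nrow(cloud))
      stop("per_point_file mode needs `values` with one entry per point (",
           nrow(cloud), " expected, ", length(values), " given)")
    cloud$es <- as.numeric(values)
    return(cloud)
  }
  if (attr(cloud, "source") != "computed")
    stop("residue_coulomb mode requires a cloud computed from `structure`")
  stopifnot(!is.null(structure))
  pot <- residue_potentials(structure, epsilon = epsilon, screen = screen,
                            d_floor = d_floor)
  cloud$es <- unname(pot[cloud$residue_key])
  cloud
}

# Screened Coulomb potential of every residue at its side-chain centroid.
# Distances are floored at d_floor so a residue's own charges (which can sit
# arbitrarily close to, or exactly at, the centroid) contribute a bounded,
# dominant term instead of a singularity.
residue_potentials <- function(structure, epsilon = 80, screen = 8,
                               d_floor = 1) {
  a <- structure$atoms
  ctr <- residue_centroids(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  q <- a$charge
  pot <- setNames(numeric(nrow(ctr)), rownames(ctr))
  for (i in seq_len(nrow(ctr))) {
    d <- pmax(sqrt(colSums((t(xyz) - ctr[i, ])^2)), d_floor)
    pot[i] <- sum(q * exp(-d / screen) / (epsilon * d))
  }
  pot
}
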