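# Synthetic surface-patch and toy-complex generators. These emulate the
# statistical features the descriptor pipeline relies on -- smooth curved
# patches, per-residue-constant electrostatic values, complementary
# surface/mold pairs, a flat-vs-concave two-class contrast, and a small
# two-chain antibody/antigen complex with Chothia-consistent numbering --
# without attempting to mimic real protein geometry in any finer detail.

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# uniform directions within a spherical cap of half-angle cap_angle (rad)
# around +z
cap_directions <- function(n, cap_angle) {
  z <- runif(n, cos(cap_angle), 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Gaussian bump field on the sphere: radial offset as a function of
# direction, sum of bumps at unit-vector centers
bump_field <- function(dirs, centers, amplitudes, widths) {
  out <- numeric(nrow(dirs))
  for (b in seq_len(nrow(centers))) {
    ang <- acos(pmin(1, pmax(-1, dirs %*% centers[b, ])))
    out <- out + amplitudes[b] * exp(-ang^2 / (2 * widths[b]^2))
  }
  out
}

# group points into pseudo-residues of `block` consecutive points and
# assign per-residue electrostatic values
assign_block_charges <- function(xyz, block, charge_pattern, charge_scale,
                                 charge_bias = 0) {
  n <- nrow(xyz)
  res_id <- (seq_len(n) - 1L) %/% block + 1L
  key <- make_residue_key("S", res_id, "")
  es <- numeric(n)
  if (charge_pattern != "neutral") {
    for (r in unique(res_id)) {
      i <- which(res_id == r)
      v <- switch(charge_pattern,
        dipolar = charge_scale * sign(mean(xyz[i, 1L]) + 1e-12),
        random = charge_scale * rnorm(1L) + charge_bias)
      es[i] <- v
    }
  }
  list(es = es, residue_key = key)
}

#' Generate a synthetic surface patch
#'
#' Deterministic under \code{seed}. Points are sampled on a spherical cap
#' (optionally squashed into an ellipsoid or perturbed by a field of
#' Gaussian bumps) and grouped into pseudo-residues of
#' \code{residue_block} consecutive points sharing one electrostatic
#' value, emulating the per-residue constancy of computed molecular
#' surfaces.
#'
#' @param kind \code{"sphere_cap"}, \code{"ellipsoid_cap"} or
#'   \code{"bumpy"}.
#' @param n_points Number of surface points.
#' @param seed Integer seed.
#' @param radius Base sphere radius in Angstrom.
#' @param cap_angle Cap half-angle in degrees (180 = full sphere).
#' @param axes Length-3 scaling for \code{"ellipsoid_cap"}.
#' @param n_bumps,bump_amplitude,bump_width Bump field parameters for
#'   \code{"bumpy"} (amplitude in Angstrom, width in radians).
#' @param charge_pattern \code{"neutral"}, \code{"dipolar"} or
#'   \code{"random"}.
#' @param charge_scale,charge_bias Electrostatic value scale/offset.
#' @param residue_block Points per pseudo-residue (default 5).
#' @return A \code{zern_patch} of kind \code{"synthetic"}.
#' @export
make_patch <- function(kind = c("sphere_cap", "ellipsoid_cap", "bumpy"),
                       n_points = 500L, seed = 1L, radius = 6,
                       cap_angle = 60, axes = c(1, 0.75, 0.6),
                       n_bumps = 6L, bump_amplitude = 1, bump_width = 0.35,
                       charge_pattern = c("neutral", "dipolar", "random"),
                       charge_scale = 1, charge_bias = 0,
                       residue_block = 5L) {
  kind <- match.arg(kind)
  charge_pattern <- match.arg(charge_pattern)
  with_seed(seed, {
    dirs <- cap_directions(n_points, cap_angle * pi / 180)
    r <- rep(radius, n_points)
    if (kind == "bumpy") {
      centers <- cap_directions(n_bumps, cap_angle * pi / 180)
      amps <- runif(n_bumps, 0.3, 1) * bump_amplitude *
        sample(c(-1, 1), n_bumps, replace = TRUE)
      wids <- runif(n_bumps, 0.7, 1.3) * bump_width
      r <- r + bump_field(dirs, centers, amps, wids)
    }
    xyz <- dirs * r
    if (kind == "ellipsoid_cap") xyz <- sweep(xyz, 2L, axes, "*")
    chg <- assign_block_charges(xyz, residue_block, charge_pattern,
                                charge_scale, charge_bias)
    pts <- data.frame(x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      es = chg$es, residue_key = chg$residue_key,
                      stringsAsFactors = FALSE)
    new_patch(pts, kind = "synthetic")
  })
}

#' Generate a complementary surface/mold patch pair
#'
#' Patch A is a bumpy cap; patch B is an independent point sample of the
#' same bump field offset radially by \code{gap} (the "mold") with its
#' per-residue electrostatic values negated (charge complementarity), and
#' then subjected to a random rigid motion so that only rotation-
#' invariant descriptors can reveal the match.
#'
#' @param n_points Points per patch.
#' @param seed Integer seed (controls the field, both samples and the
#'   rigid motion).
#' @param gap Radial offset of the mold in Angstrom.
#' @param radius,cap_angle,n_bumps,bump_amplitude,bump_width As in
#'   \code{\link{make_patch}}.
#' @param charge_scale Electrostatic magnitude.
#' @param residue_block Points per pseudo-residue.
#' @return List with patches \code{A} and \code{B}.
#' @export
make_complementary_pair <- function(n_points = 500L, seed = 1L, gap = 0.5,
                                    radius = 6, cap_angle = 60, n_bumps = 6L,
                                    bump_amplitude = 1.2, bump_width = 0.35,
                                    charge_scale = 1, residue_block = 5L) {
  with_seed(seed, {
    ca <- cap_angle * pi / 180
    centers <- cap_directions(n_bumps, ca)
    amps <- runif(n_bumps, 0.3, 1) * bump_amplitude *
      sample(c(-1, 1), n_bumps, replace = TRUE)
    wids <- runif(n_bumps, 0.7, 1.3) * bump_width
    sample_side <- function(offset, sign_es) {
      dirs <- cap_directions(n_points, ca)
      r <- radius + bump_field(dirs, centers, amps, wids) + offset
      xyz <- dirs * r
      res_id <- (seq_len(n_points) - 1L) %/% residue_block + 1L
      es <- numeric(n_points)
      for (rr in unique(res_id)) {
        i <- which(res_id == rr)
        es[i] <- sign_es * charge_scale * sign(mean(xyz[i, 1L]) + 1e-12)
      }
      data.frame(x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], es = es,
                 residue_key = make_residue_key("S", res_id, ""),
                 stringsAsFactors = FALSE)
    }
    ptsA <- sample_side(0, +1)
    ptsB <- sample_side(gap, -1)
    R <- random_rotation()
    shift <- runif(3L, -20, 20)
    xyzB <- as.matrix(ptsB[, c("x", "y", "z")]) %*% t(R)
    ptsB$x <- xyzB[, 1L] + shift[1L]
    ptsB$y <- xyzB[, 2L] + shift[2L]
    ptsB$z <- xyzB[, 3L] + shift[3L]
    list(A = new_patch(ptsA, kind = "synthetic"),
         B = new_patch(ptsB, kind = "synthetic"))
  })
}

#' Generate a labelled two-class patch dataset
#'
#' Encodes the geometric prior separating the two antigen classes:
#' "protein" binders get flat, low-curvature combining sites (a shallow
#' cap on a large sphere) with a dipolar charge pattern, "nonprotein"
#' binders get deep concave pockets (a wide cap on a small sphere) with a
#' positively biased random charge pattern. Descriptors are computed for
#' every entry at the requested order and grid size.
#'
#' @param n_per_class Entries per class (default 25).
#' @param seed Integer seed.
#' @param flat_params,concave_params Named lists overriding
#'   \code{\link{make_patch}} arguments for the two classes.
#' @param order_max,dim,es_mode Descriptor settings (defaults 20, 64,
#'   binary).
#' @param n_points Points per patch.
#' @return List of \code{\link{antibody_entry}} objects.
#' @export
make_classification_dataset <- function(n_per_class = 25L, seed = 1L,
                                        flat_params = list(),
                                        concave_params = list(),
                                        order_max = 20L, dim = 64L,
                                        es_mode = "binary",
                                        n_points = 500L) {
  fp <- modifyList(list(kind = "bumpy", radius = 14, cap_angle = 25,
                        n_bumps = 5L, bump_amplitude = 0.5,
                        charge_pattern = "dipolar", charge_scale = 1),
                   flat_params)
  cp <- modifyList(list(kind = "bumpy", radius = 5.5, cap_angle = 75,
                        n_bumps = 5L, bump_amplitude = 0.5,
                        charge_pattern = "random", charge_scale = 0.6,
                        charge_bias = 0.8),
                   concave_params)
  entries <- vector("list", 2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    pf <- do.call(make_patch, c(fp, list(n_points = n_points,
                                         seed = seed * 10000L + i)))
    pc <- do.call(make_patch, c(cp, list(n_points = n_points,
                                         seed = seed * 10000L + 5000L + i)))
    entries[[i]] <- antibody_entry(
      sprintf("prot%02d", i), "protein",
      describe_patch(pf, order_max = order_max, dim = dim, es_mode = es_mode))
    entries[[n_per_class + i]] <- antibody_entry(
      sprintf("nonp%02d", i), "nonprotein",
      describe_patch(pc, order_max = order_max, dim = dim, es_mode = es_mode))
  }
  entries
}

## ---- toy two-chain complex --------------------------------------------------

toy_atoms <- function(chain, resnums, xyz, radius, charges, resnames, serial0) {
  n <- length(resnums)
  data.frame(serial = serial0 + seq_len(n), name = "CA",
             element = "C", resname = resnames, chain = chain,
             resnum = resnums, icode = "",
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             charge = charges, radius = radius, het = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a toy antibody-antigen PQR complex
#'
#' Builds a synthetic two-molecule system of single-atom pseudo-residues:
#' an antigen of ~100 residues arranged as a hollow sphere (with interior
#' blocker atoms so only the outer shell is solvent-exposed) and a
#' two-chain antibody (heavy chain H, light chain L) hovering within
#' contact distance of the antigen's north pole. Antibody residues facing
#' the antigen carry Chothia CDR numbers, the rest framework numbers, so
#' the complex exercises the whole CDR/epitope/decoy/shell machinery.
#' Both molecules are written as PQR files; the returned structures carry
#' assigned chain roles.
#'
#' @param seed Integer seed (small coordinate jitter).
#' @param dir Output directory for \code{antibody.pqr} and
#'   \code{antigen.pqr} (default \code{tempdir()}).
#' @param n_antigen Number of antigen surface residues (default 100).
#' @return List with \code{complex}, \code{antibody}, \code{antigen}
#'   (structures, roles assigned) and \code{paths} (named character
#'   vector of the written PQR files).
#' @export
make_toy_complex <- function(seed = 1L, dir = tempdir(), n_antigen = 100L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  with_seed(seed, {
    jit <- function(n) matrix(runif(3L * n, -0.15, 0.15), n, 3L)
    aa_cycle <- c("ALA", "SER", "VAL", "THR", "LEU")
    q_cycle <- c(0.4, -0.4, 0, 0.2, -0.2)
    # antigen: outer shell + interior blockers
    Rag <- 13
    outer_xyz <- fibonacci_sphere(n_antigen) * Rag + jit(n_antigen)
    inner_n <- 30L
    inner_xyz <- fibonacci_sphere(inner_n) * 6.5 + jit(inner_n)
    ag_xyz <- rbind(outer_xyz, inner_xyz, c(0, 0, 0))
    nag <- nrow(ag_xyz)
    ag <- toy_atoms("A", seq_len(nag), ag_xyz,
                    radius = c(rep(1.9, n_antigen), rep(2.6, inner_n), 3.2),
                    charges = rep_len(q_cycle, nag),
                    resnames = rep_len(aa_cycle, nag), serial0 = 0L)
    # antibody: two lobes above the north pole
    lobe <- function(center, n) {
      sweep(fibonacci_sphere(n) * 5, 2L, center, "+") + jit(n)
    }
    h_xyz <- lobe(c(-4.5, 0, 21), 30L)
    l_xyz <- lobe(c(4.5, 0, 21), 37L)
    # antigen-facing (low z) residues get CDR numbers
    h_order <- order(h_xyz[, 3L])
    h_num <- integer(30L)
    h_num[h_order] <- c(c(26:32, 52:56, 95:102), 1:10)
    l_order <- order(l_xyz[, 3L])
    l_num <- integer(37L)
    l_num[l_order] <- c(c(24:34, 50:56, 89:97), 1:10)
    ab <- rbind(
      toy_atoms("H", h_num, h_xyz, 1.9, rep_len(q_cycle, 30L),
                rep_len(aa_cycle, 30L), serial0 = 1000L),
      toy_atoms("L", l_num, l_xyz, 1.9, rep_len(q_cycle, 37L),
                rep_len(aa_cycle, 37L), serial0 = 2000L))
    antigen <- assign_chain_roles(new_structure(ag), antigen = "A")
    antibody <- assign_chain_roles(new_structure(ab), heavy = "H", light = "L")
    cplx <- assign_chain_roles(new_structure(rbind(ab, ag)),
                               heavy = "H", light = "L", antigen = "A")
    paths <- c(antibody = file.path(dir, "antibody.pqr"),
               antigen = file.path(dir, "antigen.pqr"))
    write_pqr(antibody, paths[["antibody"]])
    write_pqr(antigen, paths[["antigen"]])
    list(complex = cplx, antibody = antibody, antigen = antigen,
         paths = paths)
  })
}
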