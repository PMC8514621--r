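#' Chothia CDR residue ranges
#'
#' Default residue-number ranges (Chothia numbering) defining the six
#' hypervariable loops: L1 24-34, L2 50-56, L3 89-97 on the light chain
#' and H1 26-32, H2 52-56, H3 95-102 on the heavy chain. Insertion-coded
#' residues inside a range are included.
#'
#' @return Data frame with columns \code{role}, \code{loop}, \code{start},
#'   \code{end}.
#' @export
chothia_cdr_ranges <- function() {
  data.frame(role = c("light", "light", "light", "heavy", "heavy", "heavy"),
             loop = c("L1", "L2", "L3", "H1", "H2", "H3"),
             start = c(24L, 50L, 89L, 26L, 52L, 95L),
             end = c(34L, 56L, 97L, 32L, 56L, 102L),
             stringsAsFactors = FALSE)
}

new_patch <- function(points, kind, pivot = NA_character_,
                      shell_fraction = NA_real_,
                      overlap_with_native = NA_real_) {
  stopifnot(nrow(points) >= 1L)
  structure(list(points = points, kind = kind, pivot = pivot,
                 shell_fraction = shell_fraction,
                 overlap_with_native = overlap_with_native),
            class = "zern_patch")
}

#' @export
print.zern_patch <- function(x, ...) {
  cat("Surface patch [", x$kind, "]: ", nrow(x$points), " points, ",
      length(unique(x$points$residue_key)), " residues", sep = "")
  if (!is.na(x$pivot)) cat(", pivot ", x$pivot, sep = "")
  if (!is.na(x$shell_fraction)) cat(", shell fraction ", x$shell_fraction, sep = "")
  cat("\n")
  invisible(x)
}

#' Residues contributing points to a patch
#'
#' @param patch A \code{zern_patch}.
#' @return Character vector of residue keys.
#' @export
patch_residues <- function(patch) unique(patch$points$residue_key)

#' Combined CDR surface patch of an antibody
#'
#' Collects the surface points of every residue falling inside any of the
#' six Chothia CDR ranges into a single combined patch (one patch per
#' antibody). Ligand (HETATM) residues are excluded by default.
#'
#' @param structure A \code{zern_structure} with heavy/light roles assigned
#'   and Chothia numbering on the antibody chains.
#' @param cloud Surface point cloud of the antibody (residue keys required).
#' @param scheme CDR range table, by default \code{\link{chothia_cdr_ranges}}.
#' @param include_het Include HETATM residues in the patch (default FALSE).
#' @return A \code{zern_patch} of kind \code{"cdr"}.
#' @export
cdr_patch <- function(structure, cloud, scheme = chothia_cdr_ranges(),
                      include_het = FALSE) {
  cloud_requires_keys(cloud, "cdr_patch")
  roles <- structure$chain_roles
  have <- intersect(c("heavy", "light"), roles)
  if (length(have) == 0L)
    stop("no heavy/light chain roles assigned; see assign_chain_roles()")
  if (length(have) == 1L)
    warning("only a ", have, " chain present; CDR patch built from it alone")
  a <- structure$atoms
  keys <- residue_keys(structure)
  in_cdr <- rep(FALSE, nrow(a))
  for (r in seq_len(nrow(scheme))) {
    ch <- names(roles)[roles == scheme$role[r]]
    if (length(ch) == 0L) next
    in_cdr <- in_cdr | (a$chain %in% ch &
                          a$resnum >= scheme$start[r] &
                          a$resnum <= scheme$end[r])
  }
  if (!include_het) in_cdr <- in_cdr & !a$het
  cdr_keys <- unique(keys[in_cdr])
  if (length(cdr_keys) == 0L)
    stop("no residues found in any CDR range; is the antibody Chothia-numbered?")
  pts <- cloud[cloud$residue_key %in% cdr_keys, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("CDR residues contribute no surface points")
  new_patch(as.data.frame(pts), kind = "cdr")
}

# minimum inter-atomic distance between two atom sets, chunked
min_cross_dist <- function(A, B) {
  best <- Inf
  step <- 2000L
  for (i0 in seq(1L, nrow(A), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(A))
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[ii, , drop = FALSE] %*% t(B)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

# per-residue minimum heavy-atom distance from antigen residues to the
# full antibody atom set
antigen_residue_distances <- function(structure) {
  ab <- structure_subset(structure, c("heavy", "light"))
  ag <- structure_subset(structure, "antigen")
  A <- as.matrix(ab$atoms[, c("x", "y", "z")])
  keys <- residue_keys(ag)
  vapply(split(seq_len(nrow(ag$atoms)), keys)[unique(keys)],
         function(i) min_cross_dist(as.matrix(ag$atoms[i, c("x", "y", "z")]), A),
         numeric(1L))
}

#' Native epitope patch on the antigen surface
#'
#' Residue-level contact selection: an antigen residue belongs to the
#' epitope when its minimum heavy-atom distance to any antibody atom is
#' below \code{cutoff} (6 Angstrom for the geometric epitope, 15 for the
#' electrostatic one). The patch collects those residues' surface points
#' and records the pivot residue.
#'
#' @param structure Complex \code{zern_structure} with antibody and
#'   antigen roles assigned.
#' @param antigen_cloud Surface cloud of the antigen (unbound), with
#'   residue keys.
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @param kind \code{"epitope_geom"} (default) or \code{"epitope_elec"}.
#' @return A \code{zern_patch} with pivot set.
#' @export
native_epitope <- function(structure, antigen_cloud, cutoff = 6,
                           kind = c("epitope_geom", "epitope_elec")) {
  kind <- match.arg(kind)
  cloud_requires_keys(antigen_cloud, "native_epitope")
  dists <- antigen_residue_distances(structure)
  hit <- names(dists)[dists < cutoff]
  if (length(hit) == 0L)
    stop("no antigen residue within ", cutoff,
         " A of the antibody: no contact at this cutoff")
  pts <- antigen_cloud[antigen_cloud$residue_key %in% hit, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("epitope residues contribute no surface points")
  p <- new_patch(as.data.frame(pts), kind = kind)
  p$pivot <- pivot_residue(p, structure)
  p
}

# representative atom (CA, else first atom) coordinates per residue
representative_atoms <- function(structure, keys = NULL) {
  a <- structure$atoms
  k <- residue_keys(structure)
  if (is.null(keys)) keys <- unique(k)
  out <- matrix(NA_real_, length(keys), 3L,
                dimnames = list(keys, c("x", "y", "z")))
  for (i in seq_along(keys)) {
    rows <- which(k == keys[i])
    ca <- rows[a$name[rows] == "CA"]
    r <- if (length(ca) > 0L) ca[1L] else rows[1L]
    out[i, ] <- c(a$x[r], a$y[r], a$z[r])
  }
  out
}

#' Pivot residue of a patch
#'
#' The patch residue with the lowest mean representative-atom distance to
#' all residues of the patch (the patch "center" in residue space).
#'
#' @param patch A \code{zern_patch}.
#' @param structure Structure providing atom coordinates for the patch
#'   residues.
#' @return A residue key.
#' @export
pivot_residue <- function(patch, structure) {
  keys <- patch_residues(patch)
  if (length(keys) == 1L) return(keys)
  rep_xyz <- representative_atoms(structure, keys)
  if (anyNA(rep_xyz)) stop("patch residues missing from structure")
  D <- as.matrix(dist(rep_xyz))
  keys[which.min(rowMeans(D))]
}

#' Decoy generation parameters
#'
#' Defaults follow the decoy protocol: pivots drawn from residues with
#' SASA within half a standard deviation of the native-pivot mean
#' (0.48 +/- 0.33 nm^2 as measured over native epitope pivots), growth
#' restricted to solvent-exposed residues (relative SASA > 0.2), at most
#' 50\% residue overlap with the native epitope, and a 15 Angstrom
#' charged-residue radius for the electrostatic extension.
#'
#' @param pivot_sasa_mean Mean pivot SASA in nm^2.
#' @param pivot_sasa_sd Standard deviation of pivot SASA in nm^2.
#' @param pivot_window_halfwidth Half-width of the pivot window in sd units.
#' @param rsasa_min Minimum relative SASA of growth candidates.
#' @param max_overlap Maximum allowed residue overlap with the native
#'   epitope (fraction of native residues).
#' @param elec_radius Electrostatic extension radius in Angstrom.
#' @return A list of class \code{decoy_params}.
#' @export
decoy_params <- function(pivot_sasa_mean = 0.48, pivot_sasa_sd = 0.33,
                         pivot_window_halfwidth = 0.5, rsasa_min = 0.2,
                         max_overlap = 0.5, elec_radius = 15) {
  stopifnot(pivot_sasa_mean > 0, pivot_sasa_sd > 0,
            pivot_window_halfwidth > 0, rsasa_min > 0,
            max_overlap > 0 || max_overlap == 0, max_overlap <= 1,
            elec_radius >= 0)
  structure(list(pivot_sasa_mean = pivot_sasa_mean,
                 pivot_sasa_sd = pivot_sasa_sd,
                 pivot_window_halfwidth = pivot_window_halfwidth,
                 rsasa_min = rsasa_min, max_overlap = max_overlap,
                 elec_radius = elec_radius),
            class = "decoy_params")
}

# run expr with a private, restorable RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# minimum heavy-atom distance between residue groups, as a dense matrix
residue_min_dist_matrix <- function(structure, keys) {
  a <- structure$atoms
  k <- residue_keys(structure)
  idx <- split(seq_len(nrow(a)), k)[keys]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nres <- length(keys)
  D <- matrix(0, nres, nres, dimnames = list(keys, keys))
  for (i in seq_len(nres - 1L)) for (j in (i + 1L):nres) {
    D[i, j] <- D[j, i] <- min_cross_dist(xyz[idx[[i]], , drop = FALSE],
                                         xyz[idx[[j]], , drop = FALSE])
  }
  D
}

#' Generate SASA-matched decoy epitopes
#'
#' Each decoy is built by (1) drawing a pivot uniformly among antigen
#' residues whose SASA lies within the pivot window, (2) growing the
#' patch by repeatedly adding the spatially nearest not-yet-included
#' solvent-exposed residue (relative SASA above \code{rsasa_min}) until
#' the decoy's summed SASA first reaches the native epitope's, and
#' (3) rejecting and resampling any decoy whose residue overlap with the
#' native epitope exceeds \code{max_overlap}. Deterministic under
#' \code{seed}.
#'
#' @param antigen Antigen-only \code{zern_structure}.
#' @param cloud Antigen surface cloud with residue keys.
#' @param native The native geometric epitope patch (pivot required).
#' @param params A \code{\link{decoy_params}} object.
#' @param n_decoys Number of decoys to generate.
#' @param seed Integer seed driving all random draws.
#' @param max_attempts Total resampling budget (default 1000).
#' @param probe,points_per_atom Passed to the SASA computation.
#' @return List of \code{zern_patch} objects of kind \code{"decoy_geom"},
#'   each with \code{pivot} and \code{overlap_with_native} recorded.
#' @export
generate_decoys <- function(antigen, cloud, native, params = decoy_params(),
                            n_decoys = 10L, seed = 1L, max_attempts = 1000L,
                            probe = 1.4, points_per_atom = 256L) {
  cloud_requires_keys(cloud, "generate_decoys")
  if (is.na(native$pivot)) stop("native patch has no pivot residue")
  sasa <- residue_sasa(antigen, probe, points_per_atom)
  rsasa <- relative_sasa(antigen, probe, points_per_atom)
  native_keys <- patch_residues(native)
  native_sasa <- sum(sasa[intersect(native_keys, names(sasa))])
  lo <- params$pivot_sasa_mean - params$pivot_window_halfwidth * params$pivot_sasa_sd
  hi <- params$pivot_sasa_mean + params$pivot_window_halfwidth * params$pivot_sasa_sd
  eligible_pivots <- names(sasa)[sasa >= lo & sasa <= hi]
  if (length(eligible_pivots) == 0L)
    stop("no antigen residue with SASA in the pivot window [",
         signif(lo, 3), ", ", signif(hi, 3), "] nm^2")
  grow_pool <- names(rsasa)[rsasa > params$rsasa_min]
  D <- residue_min_dist_matrix(antigen, unique(c(eligible_pivots, grow_pool)))
  decoys <- with_seed(seed, {
    out <- list()
    attempts <- 0L
    while (length(out) < n_decoys) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("decoy resampling budget exhausted after ", max_attempts,
             " attempts (", length(out), "/", n_decoys, " decoys built)")
      pivot <- sample(eligible_pivots, 1L)
      members <- pivot
      cand <- setdiff(grow_pool, members)
      total <- sasa[pivot]
      while (total < native_sasa && length(cand) > 0L) {
        dmin <- apply(D[cand, members, drop = FALSE], 1L, min)
        nxt <- cand[which.min(dmin)]
        members <- c(members, nxt)
        cand <- setdiff(cand, nxt)
        total <- total + sasa[nxt]
      }
      if (total < native_sasa)
        stop("antigen too small: cannot reach native epitope SASA (",
             signif(native_sasa, 3), " nm^2) from pivot ", pivot)
      overlap <- length(intersect(members, native_keys)) / length(native_keys)
      if (overlap > params$max_overlap) next
      pts <- cloud[cloud$residue_key %in% members, , drop = FALSE]
      if (nrow(pts) == 0L) next
      p <- new_patch(as.data.frame(pts), kind = "decoy_geom", pivot = pivot,
                     overlap_with_native = overlap)
      out[[length(out) + 1L]] <- p
    }
    out
  })
  decoys
}

#' Extend a decoy patch for the electrostatic channel
#'
#' Adds all antigen residues whose representative atom lies within
#' \code{radius} of the decoy's pivot representative atom (the
#' electrostatic epitope convention: charge effects are longer-ranged
#' than shape contact).
#'
#' @param decoy A decoy \code{zern_patch} with pivot set.
#' @param structure The antigen structure.
#' @param cloud Antigen surface cloud supplying the added residues'
#'   points.
#' @param radius Inclusion radius in Angstrom (default 15).
#' @return A \code{zern_patch} of kind \code{"decoy_elec"}.
#' @export
electrostatic_extension <- function(decoy, structure, cloud, radius = 15) {
  if (is.na(decoy$pivot)) stop("decoy has no pivot residue")
  reps <- representative_atoms(structure)
  pv <- reps[decoy$pivot, ]
  d <- sqrt(rowSums(sweep(reps, 2L, pv)^2))
  add <- rownames(reps)[d <= radius]
  members <- union(patch_residues(decoy), add)
  pts <- cloud[cloud$residue_key %in% members, , drop = FALSE]
  new_patch(as.data.frame(pts), kind = "decoy_elec", pivot = decoy$pivot,
            overlap_with_native = decoy$overlap_with_native)
}

#' Interface centerpoint of an antibody-antigen complex
#'
#' The centroid of the \code{n_atoms} antibody atoms closest to any
#' antigen atom; used as the origin of the concentric paratope shells.
#'
#' @param structure Complex with roles assigned.
#' @param n_atoms Number of closest interface atoms (default 10).
#' @return Numeric length-3 vector (Angstrom).
#' @export
interface_centerpoint <- function(structure, n_atoms = 10L) {
  ab <- structure_subset(structure, c("heavy", "light"))
  ag <- structure_subset(structure, "antigen")
  A <- as.matrix(ab$atoms[, c("x", "y", "z")])
  B <- as.matrix(ag$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  sel <- order(dmin)[seq_len(min(n_atoms, nrow(A)))]
  colMeans(A[sel, , drop = FALSE])
}

#' Concentric shell sub-patch of a CDR surface
#'
#' The fraction of the CDR surface points nearest to the interface
#' centerpoint \code{b}: for fraction f the ceiling(f * n) closest points
#' are retained, so shells are nested (f1 <= f2 implies shell(f1) inside
#' shell(f2)) and fraction 1 returns the full patch.
#'
#' @param cdr The combined CDR \code{zern_patch}.
#' @param center The centerpoint \code{b} from
#'   \code{\link{interface_centerpoint}}.
#' @param fraction Fraction of CDR points to keep, in (0, 1].
#' @return A \code{zern_patch} of kind \code{"shell"} with
#'   \code{shell_fraction} recorded.
#' @export
shell_patch <- function(cdr, center, fraction) {
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  pts <- cdr$points
  d2 <- (pts$x - center[1L])^2 + (pts$y - center[2L])^2 + (pts$z - center[3L])^2
  k <- ceiling(fraction * nrow(pts))
  sel <- order(d2)[seq_len(k)]
  new_patch(pts[sel, , drop = FALSE], kind = "shell",
            shell_fraction = fraction)
}
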