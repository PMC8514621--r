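#' Center and scale a patch into the unit sphere
#'
#' Translates the patch so its centroid sits at the origin and scales it
#' uniformly so the farthest point lies at radius \code{fill} (default 0.8,
#' leaving a margin against boundary effects of the unit-ball expansion).
#' The centroid is used as the center because it is covariant under
#' rotation, which keeps the downstream descriptors rotation-invariant up
#' to voxelization noise only. The applied transform is returned in
#' \code{scale_record} for provenance.
#'
#' @param patch A \code{zern_patch} or \code{zern_cloud}, or a numeric
#'   matrix of coordinates (n x 3).
#' @param fill Target radius of the farthest point inside the unit sphere.
#' @return List with \code{points} (n x 3 matrix), \code{es} (numeric
#'   vector, 0 when absent) and \code{scale_record}
#'   (list: \code{translation} in Angstrom, \code{scale} in 1/Angstrom).
#' @export
fit_to_unit_sphere <- function(patch, fill = 0.8) {
  xyz <- patch_coords(patch)
  es <- patch_es(patch)
  if (nrow(xyz) < 2L) stop("cannot scale a patch with fewer than 2 points")
  ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2L, ctr)
  rmax <- sqrt(max(rowSums(centered^2)))
  if (rmax == 0) stop("degenerate patch: all points coincide")
  sc <- fill / rmax
  list(points = centered * sc, es = es,
       scale_record = list(translation = -ctr, scale = sc))
}

# coordinate / es extraction shared by the voxelization entry points
patch_coords <- function(x) {
  if (inherits(x, "zern_patch")) x <- x$points
  if (is.data.frame(x)) return(as.matrix(x[, c("x", "y", "z")]))
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("cannot interpret `patch` as 3D coordinates")
}

patch_es <- function(x) {
  if (inherits(x, "zern_patch")) x <- x$points
  if (is.data.frame(x) && "es" %in% names(x)) return(x$es)
  rep(0, nrow(patch_coords(x)))
}

new_voxel_grid <- function(values, channel, scale_record = NULL) {
  structure(values, channel = channel, scale_record = scale_record,
            class = "voxel_grid")
}

#' Binary shape channel of a scaled point cloud
#'
#' Maps points (already inside the unit ball) onto a cubic grid spanning
#' [-1, 1]^3: a voxel is set to 1 when its center lies closer than
#' \code{reach} voxel edge lengths to any point, 0 otherwise. The reach is
#' expressed in voxel-edge units because the cloud has been rescaled to
#' the unit sphere, so an absolute Angstrom radius would no longer be
#' meaningful.
#'
#' @param points n x 3 matrix of unit-ball coordinates
#'   (from \code{\link{fit_to_unit_sphere}}).
#' @param dim Grid dimension per axis (default 128).
#' @param reach Neighbourhood radius in voxel edges (default 1.7).
#' @return A \code{voxel_grid} with \code{channel = "shape"} and values
#'   in {0, 1}.
#' @export
voxelize_shape <- function(points, dim = 128L, reach = 1.7) {
  points <- patch_coords(points)
  dim <- as.integer(dim)
  g <- array(0, c(dim, dim, dim))
  n <- nrow(points)
  if (n == 0L) return(new_voxel_grid(g, "shape"))
  h <- 2 / dim
  span <- ceiling(reach + 0.5)
  offs <- as.matrix(expand.grid(ox = -span:span, oy = -span:span, oz = -span:span))
  offs <- offs[rowSums(offs^2) <= (reach + sqrt(3) / 2 + 1e-9)^2, , drop = FALSE]
  K <- nrow(offs)
  base <- floor((points + 1) / h)           # 0-based cell of each point
  rix <- rep(seq_len(n), each = K)
  cx <- base[rix, 1L] + offs[, 1L]
  cy <- base[rix, 2L] + offs[, 2L]
  cz <- base[rix, 3L] + offs[, 3L]
  ok <- cx >= 0L & cx < dim & cy >= 0L & cy < dim & cz >= 0L & cz < dim
  cx <- cx[ok]; cy <- cy[ok]; cz <- cz[ok]; pr <- rix[ok]
  dx <- (-1 + (cx + 0.5) * h) - points[pr, 1L]
  dy <- (-1 + (cy + 0.5) * h) - points[pr, 2L]
  dz <- (-1 + (cz + 0.5) * h) - points[pr, 3L]
  hit <- dx * dx + dy * dy + dz * dz < (reach * h)^2
  flat <- unique(cx[hit] + cy[hit] * dim + cz[hit] * dim * dim + 1L)
  g[flat] <- 1
  new_voxel_grid(g, "shape")
}

#' Positive and negative electrostatic voxel channels
#'
#' Each voxel receives the mean electrostatic value of the points it
#' strictly encloses (0 when empty), and the signed field is split into
#' two non-negative channels. In \code{"binary"} mode (default, matching
#' the descriptor protocol) a voxel with positive mean is set to 1 in the
#' positive channel and 0 in the negative one, and vice versa; in
#' \code{"magnitude"} mode the channels keep the mean magnitude instead of
#' being binarized.
#'
#' @param points n x 3 matrix of unit-ball coordinates.
#' @param es Numeric vector of per-point electrostatic values.
#' @param dim Grid dimension per axis.
#' @param mode \code{"binary"} or \code{"magnitude"}.
#' @return List with \code{pos} and \code{neg}, both \code{voxel_grid}s;
#'   the two channels are disjoint (no voxel is nonzero in both).
#' @export
voxelize_electrostatics <- function(points, es, dim = 128L,
                                    mode = c("binary", "magnitude")) {
  mode <- match.arg(mode)
  points <- patch_coords(points)
  dim <- as.integer(dim)
  stopifnot(length(es) == nrow(points))
  h <- 2 / dim
  ci <- floor((points + 1) / h)
  ci[ci < 0L] <- 0L
  ci[ci > dim - 1L] <- dim - 1L
  flat <- ci[, 1L] + ci[, 2L] * dim + ci[, 3L] * dim * dim + 1L
  sums <- rowsum(es, flat)
  cnts <- rowsum(rep(1, length(flat)), flat)
  mean_es <- sums[, 1L] / cnts[, 1L]
  at <- as.integer(rownames(sums))
  gp <- array(0, c(dim, dim, dim))
  gn <- array(0, c(dim, dim, dim))
  if (mode == "binary") {
    gp[at[mean_es > 0]] <- 1
    gn[at[mean_es < 0]] <- 1
  } else {
    pos <- mean_es > 0
    gp[at[pos]] <- mean_es[pos]
    neg <- mean_es < 0
    gn[at[neg]] <- -mean_es[neg]
  }
  list(pos = new_voxel_grid(gp, "elec_pos"),
       neg = new_voxel_grid(gn, "elec_neg"))
}
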