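#' Number of rotation invariants up to a given expansion order
#'
#' The invariant vector holds one entry per pair (n, l) with l <= n and
#' n - l even, so its length is sum over n of (floor(n/2) + 1). At the
#' default maximum order 20 this gives 121 invariants; order 10 gives 36.
#'
#' @param order_max Maximum expansion order n (non-negative integer).
#' @return Integer, the number of (n, l) invariants.
#' @export
#' @examples
#' descriptor_length(20)  # 121
#' descriptor_length(10)  # 36
descriptor_length <- function(order_max) {
  if (length(order_max) != 1L || is.na(order_max) || order_max < 0)
    stop("`order_max` must be a single non-negative integer")
  order_max <- as.integer(order_max)
  sum(0:order_max %/% 2L + 1L)
}

ZERN_ORDER_STABILITY_BOUND <- 46L

#' 3D Zernike moments of a voxel grid
#'
#' Expands the scalar field held by a voxel grid on the unit ball into the
#' orthonormal 3D Zernike basis, returning the complex coefficients C_nlm
#' for all n up to \code{order_max}. Moments are computed by accumulating
#' geometric (monomial) moments of the field and contracting them with the
#' closed-form monomial expansion of the basis polynomials, which is
#' algebraically identical to the direct integral but far cheaper than
#' per-voxel basis evaluation. \code{\link{moments_oracle}} provides the
#' direct Riemann-sum evaluation used for validation.
#'
#' Voxels whose centers fall outside the unit ball are ignored (the basis
#' is only defined inside it).
#'
#' @param grid A \code{voxel_grid} (or plain cubic 3D array).
#' @param order_max Maximum expansion order (default 20).
#' @return An object of class \code{zernike_moments}: list with
#'   \code{index} (data frame of n, l, m) and \code{values} (complex vector).
#' @seealso \code{\link{invariants}}, \code{\link{moments_oracle}}
#' @export
zernike_moments <- function(grid, order_max = 20L) {
  order_max <- as.integer(order_max)
  if (order_max < 0) stop("`order_max` must be non-negative")
  if (order_max > ZERN_ORDER_STABILITY_BOUND)
    stop("expansion order ", order_max, " exceeds the numerical stability bound (",
         ZERN_ORDER_STABILITY_BOUND, ")")
  g <- unclass(grid)
  d <- dim(g)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("`grid` must be a cubic 3D array")
  if (!all(is.finite(g))) stop("grid values must be finite")
  g <- mask_unit_ball(g)
  M <- geometric_moments(g, order_max)
  tensor <- zernike_coeff_tensor(order_max)
  Mflat <- as.vector(M)
  vals <- vapply(tensor$terms,
                 function(tr) sum(tr$coef * Mflat[tr$flat]),
                 complex(1))
  structure(list(index = tensor$index, values = vals,
                 order_max = order_max,
                 channel = attr(grid, "channel")),
            class = "zernike_moments")
}

#' Brute-force Zernike moments (validation oracle)
#'
#' Direct Riemann-sum discretisation of the moment integral: for each
#' (n, l, m) the basis polynomial is evaluated pointwise at every voxel
#' center inside the unit ball (radial part via the Jacobi recurrence,
#' angular part via associated-Legendre recursion) and summed against the
#' field values. Slow but entirely independent of the geometric-moment
#' path; used in the test suite to validate \code{\link{zernike_moments}}.
#'
#' @inheritParams zernike_moments
#' @return A \code{zernike_moments} object.
#' @export
moments_oracle <- function(grid, order_max = 8L) {
  order_max <- as.integer(order_max)
  g <- unclass(grid)
  d <- dim(g)[1L]
  cc <- -1 + (seq_len(d) - 0.5) * (2 / d)
  pts <- as.matrix(expand.grid(x = cc, y = cc, z = cc))
  f <- as.vector(g)
  r <- sqrt(rowSums(pts^2))
  inside <- r <= 1
  pts <- pts[inside, , drop = FALSE]
  f <- f[inside]
  r <- r[inside]
  nz <- f != 0
  pts <- pts[nz, , drop = FALSE]; f <- f[nz]; r <- r[nz]
  vol <- (2 / d)^3
  idx_tab <- zernike_index_table(order_max)
  vals <- complex(nrow(idx_tab))
  if (length(f) > 0L) {
    costheta <- ifelse(r > 0, pts[, 3L] / r, 1)
    phi <- atan2(pts[, 2L], pts[, 1L])
    i <- 1L
    for (n in 0:order_max) {
      for (l in seq(n %% 2L, n, by = 2L)) {
        Rv <- radial_eval(n, l, r)
        for (m in (-l):l) {
          Yv <- sph_harm_eval(l, m, costheta, phi)
          vals[i] <- sum(f * Rv * Conj(Yv)) * vol
          i <- i + 1L
        }
      }
    }
  }
  structure(list(index = idx_tab, values = vals, order_max = order_max,
                 channel = attr(grid, "channel")),
            class = "zernike_moments")
}

#' Rotation-invariant descriptors from Zernike moments
#'
#' Collapses the complex moments C_nlm into the rotation-invariant norms
#' D_nl = sqrt(sum_m |C_nlm|^2), one per (n, l) pair, ordered
#' lexicographically in (n, l).
#'
#' @param moments A \code{zernike_moments} object.
#' @return A \code{zernike_descriptor}: named numeric vector of D_nl with
#'   attributes \code{nl} (data frame), \code{order_max} and \code{channel}.
#' @export
invariants <- function(moments) {
  stopifnot(inherits(moments, "zernike_moments"))
  idx <- moments$index
  grp <- idx$n * (moments$order_max + 1L) + idx$l
  sq <- rowsum(Mod(moments$values)^2, grp)
  # rowsum sorts groups by key; recover (n,l) from the combined key
  keys <- as.integer(rownames(sq))
  kn <- keys %/% (moments$order_max + 1L)
  kl <- keys %% (moments$order_max + 1L)
  o <- order(kn, kl)
  d <- sqrt(sq[o, 1L])
  nl <- data.frame(n = kn[o], l = kl[o])
  structure(as.numeric(d),
            names = paste0("D", nl$n, ".", nl$l),
            nl = nl, order_max = moments$order_max,
            channel = moments$channel,
            class = "zernike_descriptor")
}

#' Truncate a descriptor to a lower expansion order
#'
#' Because the invariant vector is (n, l)-lexicographic and each D_nl
#' depends only on moments of its own order, truncation is a prefix
#' operation: the order-10 descriptor is the first 36 entries of the
#' order-20 descriptor (identical to a direct order-10 computation).
#'
#' @param desc A \code{zernike_descriptor}.
#' @param order_max Target order, at most the descriptor's own order.
#' @return A \code{zernike_descriptor} at the lower order.
#' @export
truncate_descriptor <- function(desc, order_max) {
  stopifnot(inherits(desc, "zernike_descriptor"))
  if (order_max > attr(desc, "order_max"))
    stop("cannot truncate to a higher order than computed")
  nl <- attr(desc, "nl")
  keep <- nl$n <= order_max
  structure(as.numeric(desc)[keep],
            names = names(desc)[keep],
            nl = nl[keep, , drop = FALSE], order_max = as.integer(order_max),
            channel = attr(desc, "channel"),
            class = "zernike_descriptor")
}

#' Descriptor triple (shape + two electrostatic channels) of a patch
#'
#' The patch-level entry point used by every experiment: the patch point
#' cloud is centred and scaled into 80\% of the unit sphere, voxelized into
#' a binary shape channel and positive/negative electrostatic channels,
#' and each channel is expanded into rotation-invariant Zernike
#' descriptors.
#'
#' @param patch A \code{zern_patch} (or \code{zern_cloud}).
#' @param order_max Maximum expansion order (default 20, 121 invariants).
#' @param dim Voxel grid dimension per axis (default 64).
#' @param es_mode Electrostatic voxel encoding, \code{"binary"} (default)
#'   or \code{"magnitude"}; see \code{\link{voxelize_electrostatics}}.
#' @param channels Which channels to compute (default all three).
#' @param reach Shape-channel neighbourhood radius in voxel edges.
#' @param fill Fraction of the unit sphere occupied by the patch.
#' @return List of class \code{zern_triple} with elements \code{shape},
#'   \code{elec_pos}, \code{elec_neg} (those requested), each a
#'   \code{zernike_descriptor}.
#' @export
describe_patch <- function(patch, order_max = 20L, dim = 64L,
                           es_mode = c("binary", "magnitude"),
                           channels = c("shape", "elec_pos", "elec_neg"),
                           reach = 1.7, fill = 0.8) {
  es_mode <- match.arg(es_mode)
  channels <- match.arg(channels, several.ok = TRUE)
  fitted <- fit_to_unit_sphere(patch, fill = fill)
  out <- list()
  if ("shape" %in% channels) {
    g <- voxelize_shape(fitted$points, dim = dim, reach = reach)
    out$shape <- invariants(zernike_moments(g, order_max))
    attr(out$shape, "channel") <- "shape"
  }
  if (any(c("elec_pos", "elec_neg") %in% channels)) {
    eg <- voxelize_electrostatics(fitted$points, fitted$es, dim = dim,
                                  mode = es_mode)
    if ("elec_pos" %in% channels) {
      out$elec_pos <- invariants(zernike_moments(eg$pos, order_max))
      attr(out$elec_pos, "channel") <- "elec_pos"
    }
    if ("elec_neg" %in% channels) {
      out$elec_neg <- invariants(zernike_moments(eg$neg, order_max))
      attr(out$elec_neg, "channel") <- "elec_neg"
    }
  }
  structure(out, scale_record = fitted$scale_record, class = "zern_triple")
}
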