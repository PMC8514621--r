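#' Cosine distance between two descriptor vectors
#'
#' D(x, y) = 1 - (x . y) / (|x| |y|). For the non-negative invariant
#' vectors used here the result lies in [0, 1]; identical vectors give 0.
#'
#' @param x,y Numeric vectors of equal length (and, for
#'   \code{zernike_descriptor}s, identical (n, l) ordering).
#' @return The cosine distance (scalar).
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("descriptor vectors differ in length (", length(x), " vs ",
         length(y), ")")
  if (inherits(x, "zernike_descriptor") && inherits(y, "zernike_descriptor")) {
    if (!identical(attr(x, "nl"), attr(y, "nl")))
      stop("descriptor (n, l) orderings do not match")
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine distance undefined for a zero-norm descriptor")
  1 - sum(as.numeric(x) * as.numeric(y)) / (nx * ny)
}

triple_channel <- function(A, ch) {
  v <- A[[ch]]
  if (is.null(v)) stop("descriptor triple is missing channel `", ch, "`")
  v
}

#' Shape similarity of two patches
#'
#' Cosine distance between the shape-channel descriptors; smaller means
#' more similar.
#'
#' @param A,B Descriptor triples from \code{\link{describe_patch}}.
#' @return The shape distance (scalar).
#' @export
similarity_shape <- function(A, B) {
  cosine_distance(triple_channel(A, "shape"), triple_channel(B, "shape"))
}

#' Electrostatic similarity of two patches
#'
#' Mean of the same-sign channel distances:
#' (D(pos_A, pos_B) + D(neg_A, neg_B)) / 2. A patch with an empty
#' (zero-norm) electrostatic channel has no defined electrostatic
#' similarity; exclude such apolar patches from electrostatic analyses.
#'
#' @inheritParams similarity_shape
#' @return The electrostatic distance (scalar).
#' @export
similarity_elec <- function(A, B) {
  (cosine_distance(triple_channel(A, "elec_pos"), triple_channel(B, "elec_pos")) +
   cosine_distance(triple_channel(A, "elec_neg"), triple_channel(B, "elec_neg"))) / 2
}

#' Shape complementarity of two patches
#'
#' Identical functional form to \code{\link{similarity_shape}}: because
#' the descriptors are rotation- and translation-invariant, a surface and
#' its complementary "mold" yield near-identical invariants, so a small
#' shape distance between two interacting patches signals high
#' complementarity.
#'
#' @inheritParams similarity_shape
#' @return The shape complementarity distance (smaller = more
#'   complementary).
#' @export
complementarity_shape <- function(A, B) similarity_shape(A, B)

#' Electrostatic complementarity of two patches
#'
#' Cross-sign matching: (D(pos_A, neg_B) + D(neg_A, pos_B)) / 2, so a
#' positive patch facing a negative partner scores as complementary.
#'
#' @inheritParams similarity_shape
#' @return The electrostatic complementarity distance.
#' @export
complementarity_elec <- function(A, B) {
  (cosine_distance(triple_channel(A, "elec_pos"), triple_channel(B, "elec_neg")) +
   cosine_distance(triple_channel(A, "elec_neg"), triple_channel(B, "elec_pos"))) / 2
}

#' Swap the electrostatic channels of a descriptor triple
#'
#' Utility for the swap/identity duality:
#' \code{complementarity_elec(A, swap_elec(A)) == 0} and
#' \code{similarity_elec(A, swap_elec(A)) == complementarity_elec(A, A)}.
#'
#' @param A A descriptor triple.
#' @return The triple with \code{elec_pos} and \code{elec_neg} exchanged.
#' @export
swap_elec <- function(A) {
  tmp <- A$elec_pos
  A$elec_pos <- A$elec_neg
  A$elec_neg <- tmp
  A
}

#' Z-score table of paratope-to-candidate distances
#'
#' Computes the complementarity distance of the paratope to the native
#' epitope and to each decoy, then standardises: z = (d - mu) / sigma
#' with mu and sigma taken over the combined native + decoys set (set
#' \code{reference = "decoys"} to standardise against the decoy
#' population only).
#'
#' @param paratope Descriptor triple of the antibody paratope.
#' @param native Descriptor triple of the native epitope.
#' @param decoys List of decoy descriptor triples (at least 2).
#' @param metric \code{"shape"} or \code{"elec"}.
#' @param reference Population for mu/sigma: \code{"combined"} (default)
#'   or \code{"decoys"}.
#' @return Data frame with columns \code{label} ("native"/"decoy"),
#'   \code{distance}, \code{zscore}.
#' @export
zscore_table <- function(paratope, native, decoys,
                         metric = c("shape", "elec"),
                         reference = c("combined", "decoys")) {
  metric <- match.arg(metric)
  reference <- match.arg(reference)
  if (length(decoys) < 2L)
    stop("need at least 2 decoys for a defined z-score")
  fn <- if (metric == "shape") complementarity_shape else complementarity_elec
  d_native <- fn(paratope, native)
  d_decoys <- vapply(decoys, fn, numeric(1L), A = paratope)
  d_all <- c(d_native, d_decoys)
  ref <- if (reference == "combined") d_all else d_decoys
  mu <- mean(ref)
  sig <- sd(ref)
  z <- if (sig == 0) rep(0, length(d_all)) else (d_all - mu) / sig
  data.frame(label = c("native", rep("decoy", length(d_decoys))),
             distance = d_all, zscore = z, stringsAsFactors = FALSE)
}

# rank-statistic (Mann-Whitney) AUC with midrank tie handling
rank_auc <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) stop("AUC needs both positive and negative cases")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

roc_points <- function(scores, positive) {
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(positive[o]); fp <- cumsum(!positive[o])
  # collapse ties so the curve is a function of the threshold
  last <- c(diff(scores[o]) != 0, TRUE)
  data.frame(fpr = c(0, fp[last] / sum(!positive)),
             tpr = c(0, tp[last] / sum(positive)))
}

#' Pooled native-vs-decoy ROC over many complexes
#'
#' Pools the z-scores of all complexes, scores each candidate by -z
#' (more complementary = higher score) and computes the ROC curve and
#' its area (rank statistic, tie-aware) for recovering the native
#' epitopes among the decoys.
#'
#' @param tables List of \code{\link{zscore_table}} outputs.
#' @return List with \code{auc} and \code{roc} (data frame of fpr, tpr).
#' @export
decoy_roc <- function(tables) {
  pooled <- do.call(rbind, tables)
  score <- -pooled$zscore
  positive <- pooled$label == "native"
  list(auc = rank_auc(score, positive), roc = roc_points(score, positive))
}
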