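#' Build an antibody entry for classification
#'
#' @param id Unique identifier.
#' @param label \code{"protein"} or \code{"nonprotein"} (the antigen class
#'   the antibody binds).
#' @param triple Descriptor triple of the full CDR surface, or a named
#'   list of triples keyed by shell fraction (name \code{"1"} = full CDR).
#' @return An object of class \code{antibody_entry}.
#' @export
antibody_entry <- function(id, label = c("protein", "nonprotein"), triple) {
  label <- match.arg(label)
  if (inherits(triple, "zern_triple")) triple <- list("1" = triple)
  stopifnot(is.list(triple), length(triple) >= 1L)
  structure(list(id = id, label = label, descriptors = triple),
            class = "antibody_entry")
}

entry_triple <- function(entry, shell_fraction = 1) {
  key <- as.character(shell_fraction)
  tr <- entry$descriptors[[key]]
  if (is.null(tr))
    stop("entry ", entry$id, " has no descriptors for shell fraction ",
         shell_fraction)
  tr
}

# truncate every channel of a triple
truncate_triple <- function(triple, order_max) {
  out <- lapply(triple, truncate_descriptor, order_max = order_max)
  class(out) <- "zern_triple"
  out
}

#' Nearest-neighbour protein-binder counts
#'
#' For each antibody, finds its k = ceiling(fraction * (N - 1)) most
#' similar peers (leave-one-out, self excluded) under the chosen
#' similarity metric and counts how many of them bind protein antigens
#' (N_pb). Distance ties are broken by entry id for determinism.
#'
#' @param entries List of \code{\link{antibody_entry}} objects.
#' @param metric \code{"shape"} or \code{"elec"}.
#' @param neighbor_fraction Fraction of the dataset used as the
#'   neighbour set (default 0.05).
#' @param order_max Optionally truncate descriptors to this order first.
#' @param shell_fraction Which shell descriptors to use (default 1, the
#'   full CDR surface).
#' @return Named integer vector, id -> N_pb, with attribute \code{k}.
#' @export
neighbor_counts <- function(entries, metric = c("shape", "elec"),
                            neighbor_fraction = 0.05, order_max = NULL,
                            shell_fraction = 1) {
  metric <- match.arg(metric)
  ids <- vapply(entries, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate entry ids")
  N <- length(entries)
  if (neighbor_fraction <= 0 || neighbor_fraction >= 1)
    stop("`neighbor_fraction` must lie in (0, 1)")
  k <- as.integer(ceiling(neighbor_fraction * (N - 1L)))
  if (N < 2L) stop("need at least 2 entries")
  triples <- lapply(entries, entry_triple, shell_fraction = shell_fraction)
  if (!is.null(order_max)) triples <- lapply(triples, truncate_triple, order_max)
  fn <- if (metric == "shape") similarity_shape else similarity_elec
  D <- matrix(0, N, N, dimnames = list(ids, ids))
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    D[i, j] <- D[j, i] <- fn(triples[[i]], triples[[j]])
  }
  labels <- vapply(entries, `[[`, character(1L), "label")
  npb <- setNames(integer(N), ids)
  for (i in seq_len(N)) {
    others <- setdiff(seq_len(N), i)
    o <- others[order(D[i, others], ids[others])]
    npb[i] <- sum(labels[o[seq_len(k)]] == "protein")
  }
  attr(npb, "k") <- k
  npb
}

#' Weighted combination of shape and electrostatic neighbour counts
#'
#' N_pb_bar = A * N_pb_elec + (1 - A) * N_pb_shape, with weight
#' A in [0, 1] (A = 0 is shape-only, A = 1 electrostatics-only).
#'
#' @param npb_shape,npb_elec Neighbour counts (vectors or scalars).
#' @param A Electrostatic weight in [0, 1].
#' @return The combined (possibly fractional) counts.
#' @export
combine_weighted <- function(npb_shape, npb_elec, A) {
  if (A < 0 || A > 1) stop("weight `A` must lie in [0, 1]")
  out <- A * as.numeric(npb_elec) + (1 - A) * as.numeric(npb_shape)
  names(out) <- names(npb_shape)
  k <- attr(npb_shape, "k")
  if (!is.null(k)) attr(out, "k") <- k
  out
}

# expected N_pb under a uniform label distribution, scaled to the
# neighbour-set size k
expected_npb <- function(entries, k) {
  labels <- vapply(entries, `[[`, character(1L), "label")
  k * sum(labels == "protein") / length(labels)
}

#' Predict antigen class from neighbour counts
#'
#' An antibody is labelled protein-binding when its (possibly weighted)
#' N_pb strictly exceeds the random expectation
#' Ex[N_pb] = k * N_prot / N_tot; otherwise non-protein-binding.
#'
#' @param counts Neighbour counts from \code{\link{neighbor_counts}} or
#'   \code{\link{combine_weighted}} (attribute \code{k} required).
#' @param entries The entry list the counts were computed from.
#' @return Named character vector of predicted labels.
#' @export
predict_labels <- function(counts, entries) {
  k <- attr(counts, "k")
  if (is.null(k)) stop("`counts` lacks the neighbour-set size attribute")
  thr <- expected_npb(entries, k)
  setNames(ifelse(as.numeric(counts) > thr, "protein", "nonprotein"),
           names(counts))
}

#' ROC analysis of the neighbour-count classifier
#'
#' Scores every antibody by its (weighted) N_pb with protein as the
#' positive class: AUC via the rank (Mann-Whitney) statistic, accuracy at
#' the Ex[N_pb] operating point, and the ROC curve.
#'
#' @inheritParams predict_labels
#' @return List with \code{auc}, \code{accuracy}, \code{threshold} and
#'   \code{roc} (data frame of fpr, tpr).
#' @export
roc_analysis <- function(counts, entries) {
  labels <- vapply(entries, `[[`, character(1L), "label")
  ids <- vapply(entries, `[[`, character(1L), "id")
  scores <- as.numeric(counts)[match(ids, names(counts))]
  positive <- labels == "protein"
  pred <- predict_labels(counts, entries)[ids]
  list(auc = rank_auc(scores, positive),
       accuracy = mean(pred == labels),
       threshold = expected_npb(entries, attr(counts, "k")),
       roc = roc_points(scores, positive))
}

#' Sweep the classifier over weight, order and shell fraction
#'
#' Evaluates the weighted neighbour-count classifier over a grid of
#' electrostatic weights A, expansion orders (descriptors are truncated
#' from a single high-order computation; truncation is exact) and shell
#' fractions present in the entries.
#'
#' @param entries List of \code{\link{antibody_entry}} objects.
#' @param A_grid Electrostatic weights to evaluate.
#' @param order_grid Expansion orders to evaluate (\code{NULL} = native
#'   order only).
#' @param fractions Shell fractions to evaluate (default: those present).
#' @param neighbor_fraction Neighbour-set fraction (default 0.05).
#' @return Data frame with columns \code{A}, \code{order},
#'   \code{shell_fraction}, \code{auc}, \code{accuracy}.
#' @export
classifier_sweep <- function(entries, A_grid = seq(0, 1, by = 0.2),
                             order_grid = NULL, fractions = NULL,
                             neighbor_fraction = 0.05) {
  if (is.null(fractions))
    fractions <- names(entries[[1L]]$descriptors)
  if (is.null(order_grid))
    order_grid <- attr(entry_triple(entries[[1L]],
                                    fractions[1L])[[1L]], "order_max")
  rows <- list()
  for (fr in fractions) for (ord in order_grid) {
    ns <- neighbor_counts(entries, "shape", neighbor_fraction,
                          order_max = ord, shell_fraction = fr)
    ne <- neighbor_counts(entries, "elec", neighbor_fraction,
                          order_max = ord, shell_fraction = fr)
    for (A in A_grid) {
      res <- roc_analysis(combine_weighted(ns, ne, A), entries)
      rows[[length(rows) + 1L]] <-
        data.frame(A = A, order = ord, shell_fraction = as.numeric(fr),
                   auc = res$auc, accuracy = res$accuracy)
    }
  }
  do.call(rbind, rows)
}
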