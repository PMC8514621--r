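#' Write descriptors to CSV
#'
#' One row per invariant with columns \code{channel}, \code{order_max},
#' \code{n}, \code{l}, \code{value}; a triple writes all its channels into
#' one file.
#'
#' @param x A \code{zernike_descriptor} or \code{zern_triple}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_descriptors <- function(x, path) {
  one <- function(d, ch) {
    nl <- attr(d, "nl")
    data.frame(channel = ch, order_max = attr(d, "order_max"),
               n = nl$n, l = nl$l, value = as.numeric(d))
  }
  df <- if (inherits(x, "zern_triple")) {
    do.call(rbind, Map(one, x, names(x)))
  } else one(x, attr(x, "channel") %||% "shape")
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read descriptors from CSV
#'
#' Inverse of \code{\link{write_descriptors}}. Files with several channels
#' are returned as a \code{zern_triple}.
#'
#' @param path CSV path.
#' @return A \code{zernike_descriptor} or \code{zern_triple}.
#' @export
read_descriptors <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  mk <- function(sub) {
    structure(sub$value, names = paste0("D", sub$n, ".", sub$l),
              nl = data.frame(n = sub$n, l = sub$l),
              order_max = sub$order_max[1L], channel = sub$channel[1L],
              class = "zernike_descriptor")
  }
  chans <- unique(df$channel)
  if (length(chans) == 1L) return(mk(df))
  out <- lapply(chans, function(ch) mk(df[df$channel == ch, , drop = FALSE]))
  names(out) <- chans
  class(out) <- "zern_triple"
  out
}
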