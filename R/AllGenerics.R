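#' @rdname TagSet-class
#' @param object,x a \linkS4class{TagSet}.
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @rdname TagSet-class
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @describeIn TagSet-class tag sequences as a character vector.
#' @export
setMethod("tagSequences", "TagSet", function(x) x@sequence)

#' @describeIn TagSet-class per-library read counts as a two-column integer
#'   matrix with columns \code{HH} and \code{LL}.
#' @export
setMethod("tagCounts", "TagSet", function(x) {
  m <- cbind(HH = x@countHH, LL = x@countLL)
  rownames(m) <- x@sequence
  m
})

#' @describeIn TagSet-class number of tags.
#' @export
setMethod("length", "TagSet", function(x) length(x@sequence))

#' @describeIn TagSet-class subset tags by index or logical vector.
#' @param i index vector.
#' @param j,drop,... ignored (matrix-style calls are accepted for
#'   convenience).
#' @export
setMethod("[", "TagSet", function(x, i, j, ..., drop = FALSE) {
  new("TagSet",
    sequence = x@sequence[i],
    countHH  = x@countHH[i],
    countLL  = x@countLL[i],
    metadata = x@metadata)
})

#' @describeIn TagSet-class coerce to a data.frame with columns
#'   \code{sequence}, \code{length}, \code{countHH}, \code{countLL}.
#' @export
setMethod("as.data.frame", "TagSet", function(x, ...) {
  data.frame(
    sequence = x@sequence,
    length   = nchar(x@sequence),
    countHH  = x@countHH,
    countLL  = x@countLL,
    stringsAsFactors = FALSE)
})

setMethod("show", "TagSet", function(object) {
  n <- length(object)
  cat("TagSet with", n, "tags |",
      "reads HH:", sum(object@countHH),
      " LL:", sum(object@countLL), "\n")
  if (n > 0) {
    k <- min(n, 5L)
    df <- as.data.frame(object)[seq_len(k), ]
    print(df, row.names = FALSE)
    if (n > k) cat("...", n - k, "more tags\n")
  }
})

setMethod("show", "MireapParams", function(object) {
  cat("MireapParams (hairpin prediction constraints)\n")
  for (s in slotNames(object))
    cat(sprintf("  %-15s %s\n", s, slot(object, s)))
})
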