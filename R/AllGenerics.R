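#' Accessor generics for spliceAD classes
#'
#' `exons()` returns the flat exon `GRanges`; `geneTable()` a one-row-per-gene
#' `DataFrame`; `txTable()` the transcript-level table; `exonsByTranscript()`
#' a `GRangesList` keyed by transcript id; `eventTable()` the event catalogue
#' table; `eventIds()`, `eventType()`, `definingSites()` the respective event
#' columns.
#'
#' @param x a [TxModels] or [SpliceEvents] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname accessors
#' @export
setGeneric("txTable", function(x) standardGeneric("txTable"))
#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("exonsByTranscript", function(x) standardGeneric("exonsByTranscript"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("eventIds", function(x) standardGeneric("eventIds"))
#' @rdname accessors
#' @export
setGeneric("eventType", function(x) standardGeneric("eventType"))
#' @rdname accessors
#' @export
setGeneric("definingSites", function(x) standardGeneric("definingSites"))

#' @rdname accessors
setMethod("exons", "TxModels", function(x) x@exons)

#' @rdname accessors
setMethod("txTable", "TxModels", function(x) x@transcripts)

#' @rdname accessors
setMethod("geneTable", "TxModels", function(x) {
  tx <- x@transcripts
  idx <- !duplicated(tx$gene_id)
  DataFrame(gene_id = tx$gene_id[idx], biotype = tx$biotype[idx],
            chrom = tx$chrom[idx], strand = tx$strand[idx],
            n_transcripts = as.integer(table(tx$gene_id)[tx$gene_id[idx]]))
})

#' @rdname accessors
setMethod("exonsByTranscript", "TxModels", function(x) {
  S4Vectors::split(x@exons, factor(mcols(x@exons)$transcript_id,
                                   levels = x@transcripts$transcript_id))
})

#' @rdname accessors
setMethod("eventTable", "SpliceEvents", function(x) x@events)

#' @rdname accessors
setMethod("eventIds", "SpliceEvents", function(x) x@events$event_id)

#' @rdname accessors
setMethod("eventType", "SpliceEvents", function(x) x@events$event_type)

#' @rdname accessors
setMethod("definingSites", "SpliceEvents", function(x) x@events$sites)
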