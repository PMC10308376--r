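#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width reduce findOverlaps
#' @importFrom IRanges IRanges CharacterList IntegerList
NULL

.BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene", "other")
.EVENT_TYPES <- c("SE", "A5", "A3", "MX", "RI", "AF", "AL")

#' Exon-resolved transcript models
#'
#' `TxModels` holds the exon structures of a set of transcripts grouped into
#' host genes: a flat exon [GenomicRanges::GRanges] (1-based, inclusive, as in
#' GTF) carrying `transcript_id` and `gene_id` metadata columns, and a
#' transcript-level [S4Vectors::DataFrame] mapping transcripts to genes and
#' biotypes. It is the annotation object every downstream stage consumes.
#'
#' @slot exons `GRanges` of exons with mcols `transcript_id`, `gene_id`.
#' @slot transcripts `DataFrame` with columns `transcript_id`, `gene_id`,
#'   `biotype` (one of protein_coding, lncRNA, pseudogene, other), `chrom`,
#'   `strand`.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 200), c(100, 300)),
#'   strand = "+", transcript_id = "t1", gene_id = "g1")
#' tx <- S4Vectors::DataFrame(transcript_id = "t1", gene_id = "g1",
#'   biotype = "protein_coding", chrom = "chr1", strand = "+")
#' TxModels(gr, tx)
#' @export
setClass("TxModels", slots = c(exons = "GRanges", transcripts = "DataFrame"))

setValidity("TxModels", function(object) {
  ex <- object@exons
  tx <- object@transcripts
  msgs <- character()
  need <- c("transcript_id", "gene_id", "biotype", "chrom", "strand")
  if (!all(need %in% colnames(tx)))
    msgs <- c(msgs, paste("transcripts table must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(tx$transcript_id))
      msgs <- c(msgs, "transcript_ids must be unique")
    if (!all(tx$biotype %in% .BIOTYPES))
      msgs <- c(msgs, "biotype outside {protein_coding, lncRNA, pseudogene, other}")
    if (!all(as.character(mcols(ex)$transcript_id) %in% tx$transcript_id))
      msgs <- c(msgs, "exon transcript_id missing from transcripts table")
    # all exons of a transcript share chrom and strand; genes share them too
    key <- paste(as.character(seqnames(ex)), as.character(strand(ex)))
    if (any(vapply(split(key, as.character(mcols(ex)$gene_id)),
                   function(k) length(unique(k)) > 1L, logical(1))))
      msgs <- c(msgs, "all exons of a gene must share chrom and strand")
    if (!all(as.character(strand(ex)) %in% c("+", "-")))
      msgs <- c(msgs, "strand must be + or -")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TxModels object
#'
#' @param exons `GRanges` of exons with `transcript_id` and `gene_id` mcols.
#' @param transcripts transcript-level `DataFrame`; if missing it is derived
#'   from the exons (biotype `other`).
#' @return A [TxModels] object with exons sorted by start within transcript.
#' @export
TxModels <- function(exons, transcripts = NULL) {
  if (is.null(transcripts)) {
    idx <- !duplicated(mcols(exons)$transcript_id)
    transcripts <- DataFrame(
      transcript_id = as.character(mcols(exons)$transcript_id[idx]),
      gene_id = as.character(mcols(exons)$gene_id[idx]),
      biotype = "other",
      chrom = as.character(seqnames(exons))[idx],
      strand = as.character(strand(exons))[idx])
  }
  o <- order(as.character(mcols(exons)$transcript_id), start(exons))
  exons <- exons[o]
  new("TxModels", exons = exons, transcripts = transcripts)
}

setMethod("show", "TxModels", function(object) {
  cat("TxModels object\n",
      " ", length(unique(object@transcripts$gene_id)), " genes, ",
      nrow(object@transcripts), " transcripts, ",
      length(object@exons), " exons\n", sep = "")
  bt <- table(geneTable(object)$biotype)
  cat("  gene biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
})

#' Catalogue of local alternative splicing events
#'
#' One row per deduplicated local event: type (SE, A5, A3, MX, RI, AF, AL),
#' host gene, the transcript sets supporting the inclusion and exclusion
#' forms, the genomic splice-site coordinates defining the event, and the
#' length of the variable region (the sequence present in the inclusion form
#' only).
#'
#' @slot events `DataFrame` with columns `event_id`, `event_type`, `gene_id`,
#'   `chrom`, `strand`, `inclusion` (`CharacterList`), `exclusion`
#'   (`CharacterList`), `sites` (`IntegerList`), `var_length`, `biotype`.
#' @export
setClass("SpliceEvents", slots = c(events = "DataFrame"))

setValidity("SpliceEvents", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("event_id", "event_type", "gene_id", "chrom", "strand",
            "inclusion", "exclusion", "sites", "var_length", "biotype")
  if (!all(need %in% colnames(ev)))
    return(paste("events table must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (!all(ev$event_type %in% .EVENT_TYPES))
      msgs <- c(msgs, "unknown event type")
    if (anyDuplicated(ev$event_id))
      msgs <- c(msgs, "event_ids must be unique")
    if (any(lengths(ev$inclusion) == 0L) || any(lengths(ev$exclusion) == 0L))
      msgs <- c(msgs, "inclusion and exclusion sets must be non-empty")
    both <- mapply(function(i, e) length(intersect(i, e)) > 0L,
                   ev$inclusion, ev$exclusion)
    if (any(both))
      msgs <- c(msgs, "inclusion and exclusion sets must be disjoint")
    if (any(lengths(ev$sites) == 0L))
      msgs <- c(msgs, "defining sites must be non-empty")
    if (any(ev$var_length < 1L))
      msgs <- c(msgs, "variable region length must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

SpliceEvents <- function(events) new("SpliceEvents", events = events)

setMethod("show", "SpliceEvents", function(object) {
  cat("SpliceEvents catalogue:", nrow(object@events), "events\n")
  if (nrow(object@events)) {
    tab <- table(factor(object@events$event_type, levels = .EVENT_TYPES))
    cat(" ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("length", "SpliceEvents", function(x) nrow(x@events))

setMethod("[", "SpliceEvents", function(x, i, j, ..., drop = FALSE) {
  SpliceEvents(x@events[i, , drop = FALSE])
})
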