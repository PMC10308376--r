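#' Read a GENCODE-style GTF into transcript models
#'
#' Parses the exon lines of a GTF file and assembles one exon-resolved model
#' per transcript, grouped into host genes. Coordinates stay in the GTF native
#' 1-based inclusive convention. Gene biotype is taken from the
#' `gene_type`/`gene_biotype` attribute and mapped onto the four-level
#' vocabulary `protein_coding`, `lncRNA`, `pseudogene`, `other` (any pseudogene
#' subclass, e.g. `processed_pseudogene`, maps to `pseudogene`; unknown values
#' to `other`). Version-suffixed identifiers are kept verbatim.
#'
#' @param path path to a GTF file.
#' @return A [TxModels] object.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "spliceAD")
#' readGTF(gtf)
#' @export
readGTF <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF '", path, "': ",
                                          conditionMessage(e)))
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon records in ", path)
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("exon record without transcript_id in ", path)
  if (is.null(ex$gene_id) || anyNA(ex$gene_id))
    stop("exon record without gene_id in ", path)
  bt_raw <- if (!is.null(ex$gene_type)) ex$gene_type
            else if (!is.null(ex$gene_biotype)) ex$gene_biotype
            else rep("other", length(ex))
  bt <- mapBiotype(bt_raw)
  idx <- !duplicated(ex$transcript_id)
  tx <- DataFrame(transcript_id = as.character(ex$transcript_id[idx]),
                  gene_id = as.character(ex$gene_id[idx]),
                  biotype = bt[idx],
                  chrom = as.character(seqnames(ex))[idx],
                  strand = as.character(strand(ex))[idx])
  exFlat <- GRanges(seqnames(ex), IRanges(start(ex), end(ex)), strand = strand(ex))
  mcols(exFlat)$transcript_id <- as.character(ex$transcript_id)
  mcols(exFlat)$gene_id <- as.character(ex$gene_id)
  TxModels(exFlat, tx)
}

mapBiotype <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  out[x == "protein_coding"] <- "protein_coding"
  out[x %in% c("lncRNA", "lincRNA", "antisense")] <- "lncRNA"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out
}

#' Write transcript models back to GTF
#'
#' Emits exon lines (GENCODE dialect attributes `gene_id`, `transcript_id`,
#' `gene_type`) such that [readGTF()] on the output reproduces the models.
#'
#' @param models a [TxModels] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGTF <- function(models, path) {
  ex <- exons(models)
  tx <- txTable(models)
  bt <- tx$biotype[match(mcols(ex)$transcript_id, tx$transcript_id)]
  gr <- GRanges(seqnames(ex), IRanges(start(ex), end(ex)), strand = strand(ex))
  mcols(gr)$source <- "spliceAD"
  mcols(gr)$type <- "exon"
  mcols(gr)$gene_id <- as.character(mcols(ex)$gene_id)
  mcols(gr)$transcript_id <- as.character(mcols(ex)$transcript_id)
  mcols(gr)$gene_type <- bt
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Intron intervals of each transcript
#'
#' Gaps between consecutive exons, 1-based inclusive: the intron between exons
#' `(s1,e1)` and `(s2,e2)` is `(e1+1, s2-1)`. Single-exon transcripts have no
#' introns.
#'
#' @param models a [TxModels] object.
#' @param transcript_id optional single transcript id; if given, returns an
#'   integer matrix with columns `start`, `end` (0 rows for single-exon
#'   transcripts), otherwise a named list of such matrices for all transcripts.
#' @examples
#' # exons (1,10),(20,30),(40,50) have introns (11,19) and (31,39)
#' @export
transcriptIntrons <- function(models, transcript_id = NULL) {
  exl <- exonStartsEnds(models)
  out <- lapply(exl, function(m) {
    n <- nrow(m)
    if (n < 2L) return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
    cbind(start = m[-n, "end"] + 1L, end = m[-1L, "start"] - 1L)
  })
  if (!is.null(transcript_id)) {
    if (!transcript_id %in% names(out)) stop("unknown transcript: ", transcript_id)
    return(out[[transcript_id]])
  }
  out
}

# exon coordinates per transcript as sorted (start,end) integer matrices
exonStartsEnds <- function(models) {
  ex <- exons(models)
  s <- start(ex); e <- end(ex)
  txid <- as.character(mcols(ex)$transcript_id)
  o <- order(txid, s)
  split_idx <- split(o, txid[o])
  lapply(split_idx, function(i)
    cbind(start = s[i], end = e[i]))
}

#' Read RBP binding sites from BED
#'
#' Reads a BED file of CLIP-supported binding intervals; the BED name field
#' carries the RBP identifier. rtracklayer converts the BED 0-based half-open
#' coordinates to the package-wide 1-based inclusive convention on read.
#'
#' @param path BED file path.
#' @param rbp_ids optional character vector of valid RBP ids; records with
#'   names outside the list raise an error.
#' @return `GRanges` with mcol `rbp_id`.
#' @export
readBindingSites <- function(path, rbp_ids = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name)) stop("BED file has no name field (RBP id): ", path)
  mcols(gr)$rbp_id <- as.character(gr$name)
  if (!is.null(rbp_ids) && !all(gr$rbp_id %in% rbp_ids))
    stop("binding sites name RBPs absent from the RBP list")
  gr
}

#' Read a plain-text RBP identifier list
#'
#' One identifier per line; blank lines and `#` comments ignored.
#' @param path text file path.
#' @return character vector.
#' @export
readRbpList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Assemble a TPM SummarizedExperiment
#'
#' Convenience constructor for the expression container used throughout the
#' package: assay `tpm` (rows = transcripts/genes/RBPs, columns = samples),
#' with optional sample metadata and group labels in `colData`.
#'
#' @param tpm numeric matrix with row and column names; values must be
#'   non-negative and finite.
#' @param colData optional `DataFrame`/data.frame of per-sample covariates.
#' @param rowData optional row annotation.
#' @return [SummarizedExperiment::SummarizedExperiment].
#' @export
tpmExperiment <- function(tpm, colData = NULL, rowData = NULL) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (any(!is.finite(tpm)) || any(tpm < 0))
    stop("TPM values must be finite and non-negative")
  args <- list(assays = list(tpm = tpm))
  if (!is.null(colData)) args$colData <- colData
  if (!is.null(rowData)) args$rowData <- rowData
  do.call(SummarizedExperiment::SummarizedExperiment, args)
}

#' Read/write a TSV expression matrix
#'
#' First column is the row identifier, remaining columns one per sample.
#' @param path TSV path.
#' @return numeric matrix (read) or `path` invisibly (write).
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpressionTsv
#' @param m numeric matrix with dimnames.
#' @param id_col header of the identifier column.
#' @export
writeExpressionTsv <- function(m, path, id_col = "transcript_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
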