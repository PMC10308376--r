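# in-code fixtures: hand-built transcript models and tiny expression matrices

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

# build a TxModels from a list of transcript specs:
#   list(gene=, tx=, exons=list(c(s,e), ...), strand=, biotype=)
makeModels <- function(specs, chrom = "chr1") {
  ex <- do.call(rbind, lapply(specs, function(s) {
    m <- do.call(rbind, s$exons)
    data.frame(start = m[, 1], end = m[, 2], transcript_id = s$tx,
               gene_id = s$gene, strand = s$strand,
               biotype = if (is.null(s$biotype)) "protein_coding" else s$biotype)
  }))
  gr <- GRanges(chrom, IRanges(ex$start, ex$end), strand = ex$strand)
  mcols(gr)$transcript_id <- ex$transcript_id
  mcols(gr)$gene_id <- ex$gene_id
  idx <- !duplicated(ex$transcript_id)
  TxModels(gr, DataFrame(transcript_id = ex$transcript_id[idx],
                         gene_id = ex$gene_id[idx],
                         biotype = ex$biotype[idx], chrom = chrom,
                         strand = ex$strand[idx]))
}

# hand-enumerated seven-event fixture; identical coordinates on either strand
# (on the minus strand the A5/A3 and AF/AL labels swap, and the MX inclusion
# flips to the other transcript)
sevenTemplateModels <- function(strand = "+") {
  specs <- list(
    list(gene = "gSE", tx = "gSE.t1", strand = strand,
         exons = list(c(101, 200), c(301, 400), c(501, 600))),
    list(gene = "gSE", tx = "gSE.t2", strand = strand,
         exons = list(c(101, 200), c(501, 600))),
    list(gene = "gRI", tx = "gRI.t1", strand = strand,
         exons = list(c(101, 300))),
    list(gene = "gRI", tx = "gRI.t2", strand = strand,
         exons = list(c(101, 200), c(251, 300))),
    list(gene = "gA5", tx = "gA5.t1", strand = strand,
         exons = list(c(101, 250), c(401, 500))),
    list(gene = "gA5", tx = "gA5.t2", strand = strand,
         exons = list(c(101, 200), c(401, 500))),
    list(gene = "gA3", tx = "gA3.t1", strand = strand,
         exons = list(c(101, 200), c(341, 500))),
    list(gene = "gA3", tx = "gA3.t2", strand = strand,
         exons = list(c(101, 200), c(401, 500))),
    list(gene = "gMX", tx = "gMX.t1", strand = strand,
         exons = list(c(101, 200), c(301, 400), c(701, 800))),
    list(gene = "gMX", tx = "gMX.t2", strand = strand,
         exons = list(c(101, 200), c(501, 600), c(701, 800))),
    list(gene = "gAF", tx = "gAF.t1", strand = strand,
         exons = list(c(101, 160), c(401, 500))),
    list(gene = "gAF", tx = "gAF.t2", strand = strand,
         exons = list(c(201, 260), c(401, 500))),
    list(gene = "gAL", tx = "gAL.t1", strand = strand,
         exons = list(c(101, 200), c(301, 360))),
    list(gene = "gAL", tx = "gAL.t2", strand = strand,
         exons = list(c(101, 200), c(401, 460))))
  plus <- strand == "+"
  expected <- data.frame(
    gene_id = c("gSE", "gRI", "gA5", "gA3", "gMX", "gAF", "gAL"),
    event_type = c("SE", "RI",
                   if (plus) "A5" else "A3", if (plus) "A3" else "A5",
                   "MX",
                   if (plus) "AF" else "AL", if (plus) "AL" else "AF"),
    inclusion = c("gSE.t1", "gRI.t1", "gA5.t1", "gA3.t1",
                  if (plus) "gMX.t1" else "gMX.t2", "gAF.t1", "gAL.t2"),
    exclusion = c("gSE.t2", "gRI.t2", "gA5.t2", "gA3.t2",
                  if (plus) "gMX.t2" else "gMX.t1", "gAF.t2", "gAL.t1"),
    var_length = c(100L, 50L, 50L, 60L, 100L, 60L, 60L),
    sites = I(list(c(200L, 301L, 400L, 501L), c(200L, 251L),
                   c(200L, 250L, 401L), c(200L, 341L, 401L),
                   c(200L, 301L, 400L, 501L, 600L, 701L),
                   c(101L, 160L, 201L, 260L, 401L),
                   c(200L, 301L, 360L, 401L, 460L))))
  list(models = makeModels(specs), expected = expected)
}

# small TPM experiment with groups
makeExpr <- function(m, groups) {
  cd <- DataFrame(sample_id = colnames(m), group = groups,
                  row.names = colnames(m))
  tpmExperiment(m, colData = cd)
}

# exhaustive two-sided rank-sum p-value by enumerating all labelings
exactRankSumP <- function(a, b) {
  n <- length(a) + length(b); na <- length(a)
  r <- rank(c(a, b))
  shift <- na * (na + 1) / 2
  W_obs <- sum(r[seq_len(na)]) - shift
  Ws <- apply(utils::combn(n, na), 2, function(ix) sum(r[ix])) - shift
  min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
}

# exhaustive hypergeometric upper tail by enumerating all draws
oraEnumP <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= k)
}
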