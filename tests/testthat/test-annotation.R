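test_that("readGTF assembles grouped, sorted transcript models", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_type "protein_coding";',
    'chr1\tx\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_type "protein_coding";'),
    gtf)
  m <- readGTF(gtf)
  expect_equal(nrow(txTable(m)), 1L)
  expect_equal(start(exons(m)), c(100, 300))
  expect_equal(txTable(m)$biotype, "protein_coding")

  # exons listed in reverse genomic order come back sorted ascending
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf2)
  m2 <- readGTF(gtf2)
  expect_equal(start(exons(m2)), c(100, 300))
})

test_that("interleaved genes parse completely, matching a naive two-pass parser", {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    'chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "tA1";',
    'chr1\tx\texon\t900\t950\t.\t-\t.\tgene_id "gB"; transcript_id "tB1";',
    'chr1\tx\texon\t300\t400\t.\t+\t.\tgene_id "gA"; transcript_id "tA1";',
    'chr1\tx\texon\t1100\t1200\t.\t-\t.\tgene_id "gB"; transcript_id "tB1";',
    'chr1\tx\texon\t100\t400\t.\t+\t.\tgene_id "gA"; transcript_id "tA2";')
  writeLines(lines, gtf)
  m <- readGTF(gtf)
  # independent parse: regex attribute extraction, then group and sort
  fields <- do.call(rbind, strsplit(lines, "\t"))
  naive <- data.frame(
    start = as.integer(fields[, 4]), end = as.integer(fields[, 5]),
    tx = sub('.*transcript_id "([^"]+)".*', "\\1", fields[, 9]),
    gene = sub('.*gene_id "([^"]+)".*', "\\1", fields[, 9]))
  naive <- naive[order(naive$tx, naive$start), ]
  got <- data.frame(start = start(exons(m)), end = end(exons(m)),
                    tx = mcols(exons(m))$transcript_id,
                    gene = mcols(exons(m))$gene_id)
  got <- got[order(got$tx, got$start), ]
  expect_equal(got$start, naive$start)
  expect_equal(got$end, naive$end)
  expect_equal(got$tx, naive$tx)
  expect_equal(got$gene, naive$gene)
  expect_equal(sort(unique(txTable(m)$gene_id)), c("gA", "gB"))
})

test_that("GTF round trip preserves ids, coordinates, strand and biotype", {
  fix <- sevenTemplateModels("+")
  path <- tempfile(fileext = ".gtf")
  writeGTF(fix$models, path)
  back <- readGTF(path)
  o1 <- order(mcols(exons(fix$models))$transcript_id, start(exons(fix$models)))
  o2 <- order(mcols(exons(back))$transcript_id, start(exons(back)))
  expect_equal(start(exons(back))[o2], start(exons(fix$models))[o1])
  expect_equal(end(exons(back))[o2], end(exons(fix$models))[o1])
  expect_equal(as.character(strand(exons(back)))[o2],
               as.character(strand(exons(fix$models)))[o1])
  t1 <- as.data.frame(txTable(fix$models)); t2 <- as.data.frame(txTable(back))
  expect_equal(t2[order(t2$transcript_id), c("transcript_id", "gene_id", "biotype")],
               t1[order(t1$transcript_id), c("transcript_id", "gene_id", "biotype")],
               ignore_attr = TRUE)
})

test_that("introns are the exon gaps, and exons plus introns tile the span", {
  m <- makeModels(list(
    list(gene = "g", tx = "t3", strand = "+",
         exons = list(c(1, 10), c(20, 30), c(40, 50))),
    list(gene = "g2", tx = "t1", strand = "+", exons = list(c(100, 200))),
    list(gene = "g3", tx = "t2", strand = "+",
         exons = list(c(100, 200), c(300, 400)))))
  intr <- transcriptIntrons(m)
  expect_equal(unname(intr[["t2"]]), cbind(201L, 299L), ignore_attr = TRUE)
  expect_equal(nrow(intr[["t1"]]), 0L)
  expect_equal(unname(intr[["t3"]][, "start"]), c(11L, 31L))
  expect_equal(unname(intr[["t3"]][, "end"]), c(19L, 39L))
  # contiguity: union of exons and introns covers first start .. last end
  for (tx in names(intr)) {
    exm <- exonStartsEnds <- exons(m)[mcols(exons(m))$transcript_id == tx]
    covered <- sort(c(start(exm), if (nrow(intr[[tx]])) intr[[tx]][, "start"]))
    ends <- sort(c(end(exm), if (nrow(intr[[tx]])) intr[[tx]][, "end"]))
    expect_true(all(covered[-1] == ends[-length(ends)] + 1L))
  }
})

test_that("malformed GTF and missing attributes raise errors", {
  bad <- tempfile(fileext = ".gtf")
  writeLines('chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "g1";', bad)
  expect_error(readGTF(bad), "transcript_id")
  expect_error(readGTF(tempfile()), "not found")
})

test_that("BED binding sites read back 1-based with the RBP name", {
  bed <- tempfile(fileext = ".bed")
  # BED is 0-based half-open: this record is bases 1001..1100 in 1-based terms
  writeLines("chr1\t1000\t1100\tRBP001\t0\t+", bed)
  gr <- readBindingSites(bed)
  expect_equal(start(gr), 1001L)
  expect_equal(end(gr), 1100L)
  expect_equal(mcols(gr)$rbp_id, "RBP001")
  expect_error(readBindingSites(bed, rbp_ids = "RBP999"), "absent")
})
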