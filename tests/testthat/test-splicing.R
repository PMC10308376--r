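test_that("canonical exon layouts yield the expected SE and RI events", {
  m <- makeModels(list(
    list(gene = "g1", tx = "tA", strand = "+",
         exons = list(c(1, 100), c(200, 300), c(400, 500))),
    list(gene = "g1", tx = "tB", strand = "+",
         exons = list(c(1, 100), c(400, 500)))))
  ev <- eventTable(inferEvents(m))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "SE")
  expect_equal(ev$var_length, 101L)          # region (200, 300)
  expect_equal(ev$inclusion[[1]], "tA")

  m2 <- makeModels(list(
    list(gene = "g1", tx = "tA", strand = "+",
         exons = list(c(1, 100), c(200, 300))),
    list(gene = "g1", tx = "tB", strand = "+", exons = list(c(1, 300)))))
  ev2 <- eventTable(inferEvents(m2))
  expect_equal(ev2$event_type, "RI")
  expect_equal(ev2$var_length, 99L)          # intron (101, 199)
  expect_equal(ev2$inclusion[[1]], "tB")

  # structurally identical pair: nothing to report
  m3 <- makeModels(list(
    list(gene = "g1", tx = "tA", strand = "+",
         exons = list(c(1, 100), c(200, 300))),
    list(gene = "g1", tx = "tB", strand = "+",
         exons = list(c(1, 100), c(200, 300)))))
  expect_equal(length(inferEvents(m3)), 0L)
})

test_that("the seven handcrafted templates each give one event of their type", {
  for (str in c("+", "-")) {
    fix <- sevenTemplateModels(str)
    ev <- eventTable(inferEvents(fix$models))
    expect_equal(nrow(ev), 7L, label = paste("strand", str))
    ord <- match(fix$expected$gene_id, ev$gene_id)
    expect_false(anyNA(ord))
    expect_equal(ev$event_type[ord], fix$expected$event_type)
    expect_equal(ev$var_length[ord], fix$expected$var_length)
    for (i in seq_len(7)) {
      expect_equal(ev$inclusion[[ord[i]]], fix$expected$inclusion[i],
                   label = paste(str, fix$expected$gene_id[i], "inclusion"))
      expect_equal(ev$exclusion[[ord[i]]], fix$expected$exclusion[i])
      expect_equal(sort(ev$sites[[ord[i]]]), fix$expected$sites[[i]],
                   label = paste(str, fix$expected$gene_id[i], "sites"))
    }
  }
})

test_that("event inference is invariant to transcript input order", {
  fix <- sevenTemplateModels("+")
  ex <- exons(fix$models)
  set.seed(3)
  perm <- sample(length(ex))
  shuffled <- TxModels(ex[perm], txTable(fix$models)[
    sample(nrow(txTable(fix$models))), , drop = FALSE])
  a <- eventTable(inferEvents(fix$models))
  b <- eventTable(inferEvents(shuffled))
  expect_equal(a$event_id, b$event_id)
  expect_equal(as.list(a$inclusion), as.list(b$inclusion))
})

test_that("PSI follows the transcript-sum formula with 0/0 as missing", {
  fix <- sevenTemplateModels("+")
  ev <- inferEvents(fix$models)
  se_ev <- ev[which(eventType(ev) == "SE")]
  m <- matrix(0, nrow(txTable(fix$models)), 3,
              dimnames = list(txTable(fix$models)$transcript_id,
                              c("s1", "s2", "s3")))
  m["gSE.t1", ] <- c(3, 0, 0)
  m["gSE.t2", ] <- c(1, 2, 0)
  psi <- SummarizedExperiment::assay(computePsi(se_ev, m), "psi")
  expect_equal(unname(psi[1, ]), c(0.75, 0, NA))
  # mirrored event (inclusion/exclusion swapped) complements to 1
  evtab <- eventTable(se_ev)
  tmp <- evtab$inclusion; evtab$inclusion <- evtab$exclusion
  evtab$exclusion <- tmp
  psi2 <- SummarizedExperiment::assay(
    computePsi(new("SpliceEvents", events = evtab), m), "psi")
  expect_equal(unname(psi[1, 1:2] + psi2[1, 1:2]), c(1, 1))
  expect_error(computePsi(se_ev, m[-1, ]), "absent")
})

test_that("PSI matches a brute-force set-sum oracle on random events", {
  set.seed(99)
  txids <- paste0("t", 1:40)
  m <- matrix(rexp(40 * 12), 40, 12, dimnames = list(txids, paste0("s", 1:12)))
  m[sample(length(m), 60)] <- 0
  ev <- S4Vectors::DataFrame(
    event_id = paste0("e", 1:25), event_type = "SE", gene_id = "g",
    chrom = "chr1", strand = "+",
    inclusion = IRanges::CharacterList(lapply(1:25, function(i)
      sample(txids, sample(1:3, 1)))),
    exclusion = IRanges::CharacterList(lapply(1:25, function(i)
      sample(txids, sample(1:3, 1)))),
    sites = IRanges::IntegerList(as.list(1:25)),
    var_length = 3L, biotype = "protein_coding")
  keep <- !mapply(function(i, e) length(intersect(i, e)) > 0,
                  ev$inclusion, ev$exclusion)
  ev <- ev[keep, ]
  psi <- SummarizedExperiment::assay(
    computePsi(new("SpliceEvents", events = ev), m), "psi")
  for (i in seq_len(nrow(ev))) for (s in seq_len(ncol(m))) {
    inc <- sum(m[ev$inclusion[[i]], s])
    tot <- inc + sum(m[ev$exclusion[[i]], s])
    want <- if (tot == 0) NA_real_ else inc / tot
    expect_equal(unname(psi[i, s]), want, tolerance = 1e-12)
  }
  expect_true(all(psi >= 0 & psi <= 1, na.rm = TRUE))
})

test_that("PSI support filter keeps events expressed in enough samples", {
  p <- rbind(low = rep(0.05, 20),
             rare = c(rep(0.5, 1), rep(0, 19)),
             gone = rep(NA_real_, 20))
  colnames(p) <- paste0("s", 1:20)
  f <- filterEvents(p)            # ceiling(0.05 * 20) = 1 supporting sample
  expect_equal(rownames(f), "rare")
})

test_that("differential splicing finds planted PSI shifts and not null ones", {
  set.seed(17)
  n <- 50
  g <- rep(c("a", "b"), each = n)
  null_psi <- rbeta(2 * n, 20, 20)
  shift <- c(rbeta(n, 8, 32), rbeta(n, 24, 16))   # ~0.2 vs ~0.6
  p <- rbind(null = null_psi, shifted = shift)
  colnames(p) <- paste0("s", 1:(2 * n))
  res <- testDiffSplice(p, "a", "b", groups = g)
  expect_false(res$significant[res$event_id == "null"])
  expect_true(res$significant[res$event_id == "shifted"])
  expect_equal(res$delta_psi[res$event_id == "shifted"], 0.4, tolerance = 0.12)
  expect_equal(res$delta_psi[res$event_id == "null"], 0, tolerance = 0.12)
})

test_that("frame preservation is length mod 3 in coding genes only", {
  ev <- S4Vectors::DataFrame(
    event_id = c("e1", "e2", "e3", "e4"),
    event_type = c("SE", "RI", "SE", "SE"),
    gene_id = "g", chrom = "chr1", strand = "+",
    inclusion = IRanges::CharacterList(list("a", "a", "a", "a")),
    exclusion = IRanges::CharacterList(list("b", "b", "b", "b")),
    sites = IRanges::IntegerList(list(1L, 1L, 1L, 1L)),
    var_length = c(99L, 100L, 3L, 99L),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lncRNA"))
  ic <- intactCodon(new("SpliceEvents", events = ev))
  expect_equal(unname(ic), c(TRUE, FALSE, TRUE, NA))
})

test_that("event summaries tabulate types within biotypes", {
  fix <- sevenTemplateModels("+")
  ev <- inferEvents(fix$models)
  s <- eventSummary(ev)
  pc <- s[s$biotype == "protein_coding", ]
  expect_equal(sum(pc$n), 7L)
  expect_true(all(pc$n == 1L | pc$pct == 0))
  expect_equal(sum(pc$pct), 100)
  empty <- inferEvents(makeModels(list(
    list(gene = "g", tx = "t", strand = "+", exons = list(c(1, 10))))))
  s0 <- eventSummary(empty)
  expect_equal(sum(s0$n), 0L)
})
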