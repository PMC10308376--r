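test_that("rank-sum DET calls respect the fold-change and FDR thresholds", {
  set.seed(5)
  n <- 50
  base <- matrix(rlnorm(3 * 2 * n, 2, 0.2), nrow = 3,
                 dimnames = list(c("same", "up", "weak"),
                                 paste0("s", 1:(2 * n))))
  g <- rep(c("a", "b"), each = n)
  base["same", ] <- rep(base["same", 1:n], 2)      # identical in both groups
  base["up", g == "b"] <- base["up", g == "a"] * 2 # doubled, well separated
  d <- detTest(base, "a", "b", groups = g)
  expect_equal(d$fold_change[d$transcript_id == "same"], 1)
  expect_equal(d$direction[d$transcript_id == "same"], "none")
  expect_equal(d$direction[d$transcript_id == "up"], "up")
  expect_lt(d$p_value[d$transcript_id == "up"], 1e-10)
})

test_that("swapping groups mirrors directions and inverts fold changes", {
  set.seed(8)
  m <- matrix(rlnorm(40 * 30, 2, 0.5), nrow = 40,
              dimnames = list(paste0("t", 1:40), paste0("s", 1:30)))
  m[1:10, 16:30] <- m[1:10, 16:30] * 3
  g <- rep(c("x", "y"), each = 15)
  fwd <- detTest(m, "x", "y", groups = g)
  rev <- detTest(m, "y", "x", groups = g)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-12)
  map <- c(up = "down", down = "up", none = "none")
  expect_equal(unname(map[fwd$direction]), rev$direction)
})

test_that("20% change sets classify means against the reference group", {
  m <- rbind(t1 = c(10, 10, 12.5, 12.5, 7, 7),
             t2 = c(10, 10, 11, 11, 11, 11),
             t0 = c(0, 0, 1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:6)
  g <- rep(c("ref", "a", "b"), each = 2)
  expect_message(tw <- twentyPercentSets(m, "ref", "a", "b", groups = g),
                 "zero reference mean")
  cl <- tw$classes
  expect_equal(cl$transcript_id, c("t1", "t2"))   # t0 excluded
  expect_equal(as.character(cl$class_a), c("up", "flat"))
  expect_equal(as.character(cl$class_b), c("down", "flat"))
  expect_equal(unname(tw$table["up", "down"]), 1L)
  expect_equal(sum(tw$table), 2L)
})

test_that("host-gene correlation labels follow the r and p thresholds", {
  set.seed(21)
  n <- 200
  models <- makeModels(list(
    list(gene = "g1", tx = "solo", strand = "+", exons = list(c(1, 100))),
    list(gene = "g2", tx = "p1", strand = "+", exons = list(c(1, 100))),
    list(gene = "g2", tx = "p2", strand = "+", exons = list(c(1, 50))),
    list(gene = "g3", tx = "c1", strand = "+", exons = list(c(1, 100))),
    list(gene = "g3", tx = "c2", strand = "+", exons = list(c(1, 50)))))
  solo <- rlnorm(n, 2, 0.5)
  p1 <- rlnorm(n, 2, 0.5)
  # orthogonalise p2's contribution: gene sum = p1 + p2 where p2 is built so
  # that p2 is uncorrelated with the sum by construction (residual method)
  noise <- rnorm(n)
  gsum <- p1 + abs(noise) + 5
  p2 <- gsum - p1
  p2 <- p2 - (cov(p2, gsum) / var(gsum)) * (gsum - mean(gsum))
  p2 <- p2 - min(p2) + 0.1
  c1 <- rlnorm(n, 2, 0.5)
  c2 <- 50 - c1                      # constant gene sum
  m <- rbind(solo = solo, p1 = p1, p2 = p2, c1 = c1, c2 = c2)
  colnames(m) <- paste0("s", 1:n)
  res <- suppressMessages(hostGeneCorrelation(m, models))
  expect_equal(res$r[res$transcript_id == "solo"], 1, tolerance = 1e-12)
  expect_equal(res$label[res$transcript_id == "solo"], "positive")
  expect_lt(abs(res$r[res$transcript_id == "p2"]), 0.1)
  expect_equal(res$label[res$transcript_id == "c1"], "irrelevant")
})

test_that("expression fractions of positive transcripts are ratios of means", {
  models <- makeModels(list(
    list(gene = "gA", tx = "a1", strand = "+", exons = list(c(1, 10))),
    list(gene = "gA", tx = "a2", strand = "+", exons = list(c(1, 5))),
    list(gene = "gB", tx = "b1", strand = "+", exons = list(c(1, 10))),
    list(gene = "gC", tx = "c1", strand = "+", exons = list(c(1, 10)))))
  m <- rbind(a1 = c(4, 4), a2 = c(4, 4), b1 = c(3, 3), c1 = c(2, 2))
  colnames(m) <- c("s1", "s2")
  corr <- data.frame(transcript_id = c("a1", "b1"),
                     label = c("positive", "positive"))
  ef <- expressionFraction(m, models, corr)
  expect_equal(ef$fraction[ef$gene_id == "gA"], 0.5)  # one of two equal tx
  expect_equal(ef$fraction[ef$gene_id == "gB"], 1)    # all expression positive
  expect_equal(ef$fraction[ef$gene_id == "gC"], 0)    # no positive transcript
})
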