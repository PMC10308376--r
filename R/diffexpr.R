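.groupsOf <- function(x, groups = NULL) {
  if (is.null(groups)) {
    if (!methods::is(x, "SummarizedExperiment") ||
        is.null(SummarizedExperiment::colData(x)$group))
      stop("supply 'groups' or a SummarizedExperiment with colData column 'group'")
    groups <- SummarizedExperiment::colData(x)$group
  }
  g <- as.character(groups)
  names(g) <- colnames(x)
  g
}

.assayTpm <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1L) else x
}

#' Differential transcript expression between two diagnostic groups
#'
#' Per transcript: two-sided Wilcoxon rank-sum test of TPM between the two
#' groups, fold change as the ratio of group means with a small pseudocount
#' (`(mean_b + eps) / (mean_a + eps)`), and BH FDR across all tested rows. A
#' transcript is called up if fold change > `fc_up` and FDR < `fdr_max`,
#' down if fold change < `fc_down` and FDR < `fdr_max`.
#'
#' @param x SummarizedExperiment (assay `tpm`) or matrix, rows already passed
#'   through [filterLowExpression()].
#' @param group_a,group_b labels of the reference and contrast group.
#' @param groups per-sample labels (defaults to `colData(x)$group`).
#' @param fc_up,fc_down,fdr_max decision thresholds.
#' @param eps pseudocount added to both group means (TPM units).
#' @return data.frame `transcript_id`, `mean_a`, `mean_b`, `fold_change`,
#'   `p_value`, `fdr`, `direction` (up/down/none).
#' @export
detTest <- function(x, group_a, group_b, groups = NULL,
                    fc_up = 1.5, fc_down = 0.67, fdr_max = 0.05, eps = 0.01) {
  g <- .groupsOf(x, groups)
  m <- .assayTpm(x)
  ia <- which(g == group_a); ib <- which(g == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least 2 samples")
  ma <- m[, ia, drop = FALSE]; mb <- m[, ib, drop = FALSE]
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  p <- vapply(seq_len(nrow(m)), function(i) {
    a <- ma[i, ]; b <- mb[i, ]
    if (max(c(a, b)) == min(c(a, b))) 1 else rankTest(a, b, "rank_sum")
  }, numeric(1))
  fc <- (mean_b + eps) / (mean_a + eps)
  fdr <- bhFdr(p)
  direction <- rep("none", nrow(m))
  direction[fc > fc_up & fdr < fdr_max] <- "up"
  direction[fc < fc_down & fdr < fdr_max] <- "down"
  data.frame(transcript_id = rownames(m), mean_a = mean_a, mean_b = mean_b,
             fold_change = fc, p_value = p, fdr = fdr, direction = direction,
             row.names = NULL)
}

#' Cross-tabulate 20 percent expression changes against a reference group
#'
#' For each transcript and each of two disease groups, the mean TPM change
#' relative to the reference group is classified as up (> +`threshold`),
#' down (< -`threshold`) or flat, and the 3 x 3 cross-tabulation over the two
#' groups is returned — including the discordant cells (up in one group, down
#' in the other). Transcripts with zero reference mean are excluded.
#'
#' @param x expression container as in [detTest()].
#' @param group_ref,group_a,group_b group labels (reference plus the two
#'   groups being compared against it).
#' @param groups per-sample labels.
#' @param threshold relative-change cutoff (0.2 = 20 percent).
#' @return list with `classes` (data.frame transcript_id, class_a, class_b)
#'   and `table` (3 x 3 contingency table, up/down/flat in a x same in b).
#' @export
twentyPercentSets <- function(x, group_ref, group_a, group_b, groups = NULL,
                              threshold = 0.2) {
  g <- .groupsOf(x, groups)
  m <- .assayTpm(x)
  mu_ref <- rowMeans(m[, g == group_ref, drop = FALSE])
  mu_a <- rowMeans(m[, g == group_a, drop = FALSE])
  mu_b <- rowMeans(m[, g == group_b, drop = FALSE])
  ok <- mu_ref > 0
  if (any(!ok))
    message(sum(!ok), " transcript(s) with zero reference mean excluded")
  cls <- function(mu) {
    rel <- (mu[ok] - mu_ref[ok]) / mu_ref[ok]
    ifelse(rel > threshold, "up", ifelse(rel < -threshold, "down", "flat"))
  }
  lv <- c("up", "down", "flat")
  class_a <- factor(cls(mu_a), levels = lv)
  class_b <- factor(cls(mu_b), levels = lv)
  list(classes = data.frame(transcript_id = rownames(m)[ok],
                            class_a = class_a, class_b = class_b),
       table = table(a = class_a, b = class_b))
}

#' Transcript versus host-gene expression correlation
#'
#' Pearson correlation of each transcript's TPM with its host gene's
#' expression across all samples, the gene profile being the sum of its
#' member transcripts' TPM (an independent gene-level matrix may be supplied
#' instead). A transcript is labelled positive if r > `r_min` and
#' p < `p_max`, negative if r < `-r_min` and p < `p_max`, otherwise
#' irrelevant; zero-variance transcripts or genes are irrelevant by
#' definition.
#'
#' @param x transcript expression container.
#' @param models [TxModels] mapping transcripts to host genes.
#' @param gene_tpm optional gene-level matrix (rows = gene ids, same samples);
#'   defaults to member-transcript sums.
#' @param r_min,p_max classification thresholds.
#' @return data.frame `transcript_id`, `gene_id`, `r`, `p_value`, `label`.
#' @export
hostGeneCorrelation <- function(x, models, gene_tpm = NULL,
                                r_min = 0.3, p_max = 0.05) {
  m <- .assayTpm(x)
  if (ncol(m) < 3L) stop("need at least 3 samples for correlation")
  tx <- txTable(models)
  gene_of <- stats::setNames(tx$gene_id, tx$transcript_id)
  keep <- rownames(m) %in% names(gene_of)
  m <- m[keep, , drop = FALSE]
  if (is.null(gene_tpm)) gene_tpm <- geneSums(m, gene_of)
  res <- lapply(seq_len(nrow(m)), function(i) {
    tid <- rownames(m)[i]; gid <- unname(gene_of[tid])
    tvec <- m[i, ]; gvec <- gene_tpm[gid, ]
    if (stats::sd(tvec) == 0 || stats::sd(gvec) == 0)
      return(data.frame(transcript_id = tid, gene_id = gid, r = NA_real_,
                        p_value = NA_real_, label = "irrelevant"))
    ct <- stats::cor.test(tvec, gvec, method = "pearson")
    lab <- if (!is.na(ct$p.value) && ct$p.value < p_max) {
      if (ct$estimate > r_min) "positive"
      else if (ct$estimate < -r_min) "negative" else "irrelevant"
    } else "irrelevant"
    data.frame(transcript_id = tid, gene_id = gid, r = unname(ct$estimate),
               p_value = ct$p.value, label = lab)
  })
  do.call(rbind, res)
}

# gene-level TPM as the sum of member transcripts present in the matrix
geneSums <- function(m, gene_of) {
  gid <- unname(gene_of[rownames(m)])
  rowsum(m, group = gid)
}

#' Expression fraction of positively correlated transcripts per host gene
#'
#' For each gene: the sum of mean TPM over its positively correlated
#' transcripts divided by the gene's mean TPM (member-transcript sum),
#' stratified by the gene's transcript count. Genes with zero mean are
#' excluded.
#'
#' @param x transcript expression container (same rows as used for the
#'   correlations).
#' @param models [TxModels].
#' @param corr output of [hostGeneCorrelation()].
#' @return data.frame `gene_id`, `n_transcripts`, `fraction` plus a
#'   `by_count` attribute with the median fraction per transcript count.
#' @export
expressionFraction <- function(x, models, corr) {
  m <- .assayTpm(x)
  tx <- txTable(models)
  gene_of <- stats::setNames(tx$gene_id, tx$transcript_id)
  keep <- rownames(m) %in% names(gene_of)
  m <- m[keep, , drop = FALSE]
  mu <- rowMeans(m)
  gid <- unname(gene_of[rownames(m)])
  gene_mu <- tapply(mu, gid, sum)
  pos <- corr$transcript_id[corr$label == "positive"]
  pos_mu <- tapply(mu * (rownames(m) %in% pos), gid, sum)
  n_tx <- tapply(rownames(m), gid, length)
  ok <- gene_mu > 0
  out <- data.frame(gene_id = names(gene_mu)[ok],
                    n_transcripts = as.integer(n_tx[ok]),
                    fraction = as.numeric(pos_mu[ok] / gene_mu[ok]),
                    row.names = NULL)
  attr(out, "by_count") <- vapply(split(out$fraction, out$n_transcripts),
                                  stats::median, numeric(1))
  out
}
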