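#' Isoform fractions
#'
#' The isoform fraction IF of transcript `t` in sample `s` is its TPM divided
#' by the summed TPM of all transcripts of its host gene in that sample.
#' Samples where the gene is entirely unexpressed get missing values (absence
#' of the gene is not evidence about relative isoform usage). Per gene and
#' sample with positive expression the member IFs sum to one; the matrix is
#' invariant to rescaling any sample's TPM column by a positive constant.
#'
#' @param x transcript expression container.
#' @param models [TxModels] mapping transcripts to host genes (transcripts
#'   absent from the annotation are dropped with a message).
#' @return SummarizedExperiment with assay `if` (transcripts x samples) and
#'   rowData columns `transcript_id`, `gene_id`.
#' @export
computeIF <- function(x, models) {
  m <- .assayTpm(x)
  tx <- txTable(models)
  gene_of <- stats::setNames(tx$gene_id, tx$transcript_id)
  keep <- rownames(m) %in% names(gene_of)
  if (any(!keep))
    message(sum(!keep), " transcript(s) absent from the annotation dropped")
  m <- m[keep, , drop = FALSE]
  gid <- unname(gene_of[rownames(m)])
  tot <- rowsum(m, group = gid)[gid, , drop = FALSE]
  ifm <- ifelse(tot > 0, m / tot, NA_real_)
  dimnames(ifm) <- dimnames(m)
  cd <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::colData(x)[colnames(m), , drop = FALSE] else NULL
  args <- list(assays = list(`if` = ifm),
               rowData = DataFrame(transcript_id = rownames(m), gene_id = gid))
  if (!is.null(cd)) args$colData <- cd
  do.call(SummarizedExperiment::SummarizedExperiment, args)
}

#' Detect isoform switching between two groups
#'
#' Per transcript: dIF = mean IF in `group_b` minus mean IF in `group_a`
#' (over non-missing values), a two-sided two-sample Student t-test on the IF
#' values (pooled variance as printed; Welch available), and BH FDR across
#' all tested transcripts. Usage is `increased` when dIF > `dif_min` with
#' FDR < `fdr_max`, `decreased` when dIF < -`dif_min` with FDR < `fdr_max`,
#' otherwise `none`. A gene has an isoform switching event when at least one
#' member transcript has non-`none` usage.
#'
#' @param ifm isoform-fraction container from [computeIF()].
#' @param group_a,group_b group labels.
#' @param groups per-sample labels (defaults to `colData(ifm)$group`).
#' @param dif_min,fdr_max significance thresholds.
#' @param welch use the Welch t-test instead of pooled variance.
#' @param fdr_by `"all"` (one BH family across all transcripts, default) or
#'   `"gene"` (BH within each gene).
#' @return data.frame `transcript_id`, `gene_id`, `dif`, `p_value`, `fdr`,
#'   `usage`, `gene_switching`.
#' @export
detectSwitches <- function(ifm, group_a, group_b, groups = NULL,
                           dif_min = 0.1, fdr_max = 0.05, welch = FALSE,
                           fdr_by = c("all", "gene")) {
  fdr_by <- match.arg(fdr_by)
  g <- .groupsOf(ifm, groups)
  m <- SummarizedExperiment::assay(ifm, "if")
  gene_of <- SummarizedExperiment::rowData(ifm)$gene_id
  ia <- which(g == group_a); ib <- which(g == group_b)
  res <- lapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ia]; b <- m[i, ib]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    p <- if (welch) {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else stats::t.test(a, b)$p.value
    } else rankTest(a, b, kind = "t")
    data.frame(transcript_id = rownames(m)[i], gene_id = gene_of[i],
               dif = mean(b) - mean(a), p_value = p)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(transcript_id = character(),
    gene_id = character(), dif = numeric(), p_value = numeric(),
    fdr = numeric(), usage = character(), gene_switching = logical()))
  out$fdr <- if (fdr_by == "all") bhFdr(out$p_value) else
    stats::ave(out$p_value, out$gene_id, FUN = bhFdr)
  out$usage <- ifelse(out$fdr < fdr_max & out$dif > dif_min, "increased",
               ifelse(out$fdr < fdr_max & out$dif < -dif_min, "decreased",
                      "none"))
  sw_genes <- unique(out$gene_id[out$usage != "none"])
  out$gene_switching <- out$gene_id %in% sw_genes
  out
}

#' Gene-level expression context of switching genes
#'
#' For each gene with an isoform switching event, tests whether the host gene
#' itself is differentially expressed (Wilcoxon rank-sum on member-transcript
#' TPM sums with the same fold-change/FDR thresholds as the transcript-level
#' analysis) and flags the headline class: genes that switch isoforms while
#' showing no gene-level expression change.
#'
#' @param x transcript expression container.
#' @param models [TxModels].
#' @param switches output of [detectSwitches()].
#' @param group_a,group_b,groups as in [detTest()].
#' @param ... thresholds passed on to [detTest()].
#' @return data.frame `gene_id`, `gene_fold_change`, `gene_fdr`,
#'   `gene_direction`, `switch_without_gene_change`.
#' @export
switchVsGeneExpression <- function(x, models, switches, group_a, group_b,
                                   groups = NULL, ...) {
  sw_genes <- unique(switches$gene_id[switches$gene_switching])
  if (!length(sw_genes))
    return(data.frame(gene_id = character(), gene_fold_change = numeric(),
                      gene_fdr = numeric(), gene_direction = character(),
                      switch_without_gene_change = logical()))
  g <- .groupsOf(x, groups)
  m <- .assayTpm(x)
  tx <- txTable(models)
  gene_of <- stats::setNames(tx$gene_id, tx$transcript_id)
  keep <- rownames(m) %in% names(gene_of)
  gm <- geneSums(m[keep, , drop = FALSE], gene_of)
  det <- detTest(gm, group_a, group_b, groups = g, ...)
  det <- det[det$transcript_id %in% sw_genes, , drop = FALSE]
  data.frame(gene_id = det$transcript_id,
             gene_fold_change = det$fold_change, gene_fdr = det$fdr,
             gene_direction = det$direction,
             switch_without_gene_change = det$direction == "none",
             row.names = NULL)
}
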