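#' Classify samples by neuropathology and cognition
#'
#' Assigns each sample one of `control`, `asymad`, `ad`, `unclassified` from
#' its CERAD neuritic-plaque score (1-4, lower = more pathology), Braak
#' neurofibrillary-tangle stage (0-6) and MMSE cognitive score (0-30).
#' Dementia is defined as MMSE < 24. The printed group definitions are:
#' control = CERAD 3-4 and Braak 0-3 without dementia; AsymAD = CERAD 1-3 and
#' Braak 3-6 without dementia; AD = CERAD 1-2 and Braak 3-6 with dementia.
#'
#' The control and AsymAD definitions overlap at CERAD 3 / Braak 3 without
#' dementia; rules are therefore evaluated in a fixed precedence (default
#' AD, then AsymAD, then control — a pathology-forward reading under which the
#' overlap cell resolves to AsymAD). The precedence is configurable and any
#' sample landing in the overlap is reported via a warning-level message.
#'
#' @param metadata data.frame/DataFrame with columns `sample_id`, `cerad`,
#'   `braak`, `mmse` (or a SummarizedExperiment whose colData has them).
#' @param precedence character vector ordering `c("ad","asymad","control")`.
#' @param quiet suppress the ambiguity message.
#' @return factor of labels (levels control, asymad, ad, unclassified), named
#'   by sample id.
#' @examples
#' m <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                 cerad = c(2, 4, 1), braak = c(4, 1, 5),
#'                 mmse = c(20, 29, 27))
#' classifySamples(m)   # ad, control, asymad
#' @export
classifySamples <- function(metadata,
                            precedence = c("ad", "asymad", "control"),
                            quiet = FALSE) {
  if (methods::is(metadata, "SummarizedExperiment"))
    metadata <- as.data.frame(SummarizedExperiment::colData(metadata))
  stopifnot(all(c("sample_id", "cerad", "braak", "mmse") %in% colnames(metadata)))
  if (anyDuplicated(metadata$sample_id)) stop("sample_ids must be unique")
  cerad <- metadata$cerad; braak <- metadata$braak; mmse <- metadata$mmse
  if (any(cerad < 1 | cerad > 4)) stop("CERAD score out of range 1-4")
  if (any(braak < 0 | braak > 6)) stop("Braak stage out of range 0-6")
  if (any(mmse < 0 | mmse > 30)) stop("MMSE out of range 0-30")
  if (!setequal(precedence, c("ad", "asymad", "control")))
    stop("precedence must order ad, asymad, control")
  dementia <- mmse < 24
  rules <- list(
    control = cerad >= 3 & cerad <= 4 & braak >= 0 & braak <= 3 & !dementia,
    asymad  = cerad >= 1 & cerad <= 3 & braak >= 3 & braak <= 6 & !dementia,
    ad      = cerad >= 1 & cerad <= 2 & braak >= 3 & braak <= 6 & dementia)
  ambiguous <- rules$control & rules$asymad
  if (any(ambiguous) && !quiet)
    message(sum(ambiguous), " sample(s) fall in the CERAD 3/Braak 3 ",
            "control-AsymAD overlap; resolved by precedence (",
            paste(precedence, collapse = " > "), ")")
  out <- rep("unclassified", nrow(metadata))
  for (lab in rev(precedence)) out[rules[[lab]]] <- lab
  factor(stats::setNames(out, metadata$sample_id),
         levels = c("control", "asymad", "ad", "unclassified"))
}

#' Remove low-expression rows
#'
#' Keeps rows whose TPM exceeds `tpm_min` in no less than `frac_min` of the
#' samples; "no less than 5%" is read conservatively as
#' `ceiling(frac_min * n_samples)` supporting samples. Applied jointly over
#' all samples, never per group. Idempotent.
#'
#' @param x SummarizedExperiment with assay `tpm`, or a plain numeric matrix.
#' @param tpm_min TPM threshold a sample must exceed (strictly) to count.
#' @param frac_min minimum supporting fraction of samples.
#' @return the filtered object, same class and row order as the input.
#' @export
filterLowExpression <- function(x, tpm_min = 0.1, frac_min = 0.05) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "tpm") else x
  if (!nrow(m)) stop("empty expression matrix")
  need <- ceiling(frac_min * ncol(m))
  keep <- rowSums(m > tpm_min) >= need
  if (!any(keep)) warning("no rows survive the low-expression filter")
  if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep, ]
}
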