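#' Infer local alternative splicing events from transcript structures
#'
#' Pairwise comparison of the exon structures of each gene's transcripts
#' yields local events of the seven canonical types — skipped exon (SE),
#' alternative 5'/3' splice site (A5/A3), mutually exclusive exons (MX),
#' retained intron (RI), alternative first/last exon (AF/AL) — deduplicated
#' by (gene, type, sorted defining splice-site coordinates), with transcripts
#' from all supporting pairs unioned into the inclusion and exclusion sets.
#' All definitions are strand-aware: a shared-acceptor/alternative-donor
#' configuration is A5 on the plus strand and A3 on the minus strand, and the
#' inclusion form is the transcript whose mature product contains the variable
#' region (for AF/AL, the transcript whose alternative terminal exon lies
#' furthest 5'/3'). Genes with a single transcript yield no events.
#'
#' @param models a [TxModels] object.
#' @return a [SpliceEvents] catalogue.
#' @examples
#' # an exon present in one transcript and bridged by a single intron in the
#' # other, with shared flanking splice sites, is a skipped exon (SE) event
#' @export
inferEvents <- function(models) {
  tx <- as.data.frame(txTable(models))
  exl <- exonStartsEnds(models)
  acc <- new.env(parent = emptyenv())
  txsplit <- split(tx, tx$gene_id)
  for (gid in names(txsplit)) {
    rows <- txsplit[[gid]]
    if (nrow(rows) < 2L) next
    str <- rows$strand[1L]; chrom <- rows$chrom[1L]; bt <- rows$biotype[1L]
    ids <- rows$transcript_id
    ex <- exl[ids]
    intr <- lapply(ex, function(m) {
      n <- nrow(m)
      if (n < 2L) matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
      else cbind(start = m[-n, "end"] + 1L, end = m[-1L, "start"] - 1L)
    })
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      cands <- .pairEvents(ex[[i]], ex[[j]], intr[[i]], intr[[j]], str)
      for (cv in cands) {
        key <- paste(gid, cv$type, paste(sort(cv$sites), collapse = "-"),
                     sep = ";")
        cur <- if (!is.null(acc[[key]])) acc[[key]] else
          list(gene_id = gid, type = cv$type, chrom = chrom, strand = str,
               biotype = bt, sites = sort(cv$sites),
               var_length = cv$var_length,
               incl = character(), excl = character())
        cur$incl <- union(cur$incl, ids[c(i, j)][cv$incl])
        cur$excl <- union(cur$excl, ids[c(i, j)][cv$excl])
        acc[[key]] <- cur
      }
    }
  }
  evs <- as.list(acc)
  if (length(evs)) evs <- evs[order(names(evs))]
  if (!length(evs)) {
    return(SpliceEvents(DataFrame(
      event_id = character(), event_type = character(), gene_id = character(),
      chrom = character(), strand = character(),
      inclusion = CharacterList(), exclusion = CharacterList(),
      sites = IntegerList(), var_length = integer(), biotype = character())))
  }
  # identical structures supporting both forms cannot occur; guard anyway
  evs <- Filter(function(e) !length(intersect(e$incl, e$excl)), evs)
  evs <- unname(evs)
  ev <- DataFrame(
    event_id = vapply(evs, function(e)
      paste0(e$gene_id, ";", e$type, ";", e$chrom, ":",
             paste(e$sites, collapse = "-"), ":", e$strand), character(1)),
    event_type = vapply(evs, `[[`, character(1), "type"),
    gene_id = vapply(evs, `[[`, character(1), "gene_id"),
    chrom = vapply(evs, `[[`, character(1), "chrom"),
    strand = vapply(evs, `[[`, character(1), "strand"),
    inclusion = CharacterList(lapply(evs, function(e) sort(e$incl))),
    exclusion = CharacterList(lapply(evs, function(e) sort(e$excl))),
    sites = IntegerList(lapply(evs, `[[`, "sites")),
    var_length = vapply(evs, function(e) as.integer(e$var_length), integer(1)),
    biotype = vapply(evs, `[[`, character(1), "biotype"))
  ev <- ev[order(ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  SpliceEvents(ev)
}

# Candidate events between one transcript pair. Coordinates genomic, 1-based
# inclusive; strand only decides type labels and inclusion orientation.
# Returns list of list(type, sites, var_length, incl, excl) with incl/excl in
# {1, 2} indexing the pair.
.pairEvents <- function(e1, e2, i1, i2, strand) {
  out <- list()
  emit <- function(type, sites, var_length, incl, excl)
    out[[length(out) + 1L]] <<- list(type = type, sites = as.integer(sites),
                                     var_length = var_length,
                                     incl = incl, excl = excl)
  hasIntron <- function(intr, s, e)
    nrow(intr) > 0L && any(intr[, "start"] == s & intr[, "end"] == e)
  hasExon <- function(ex, s, e)
    any(ex[, "start"] == s & ex[, "end"] == e)
  ov <- function(s1, x1, s2, x2) s1 <= x2 && s2 <= x1

  exl <- list(e1, e2); inl <- list(i1, i2)

  # SE: internal exon of one, bridged by a single intron of the other
  for (k in 1:2) {
    ein <- exl[[k]]; eex <- exl[[3 - k]]; iex <- inl[[3 - k]]
    n <- nrow(ein)
    if (n >= 3L) for (q in 2:(n - 1L)) {
      d <- ein[q - 1L, "end"]; a <- ein[q + 1L, "start"]
      if (hasIntron(iex, d + 1L, a - 1L))
        emit("SE", c(d, ein[q, "start"], ein[q, "end"], a),
             ein[q, "end"] - ein[q, "start"] + 1L, k, 3L - k)
    }
  }

  # RI: intron of one contained in an exon of the other with matched bounds
  for (k in 1:2) {
    espl <- exl[[k]]; ispl <- inl[[k]]; eret <- exl[[3 - k]]
    if (nrow(ispl)) for (q in seq_len(nrow(ispl))) {
      us <- espl[q, "start"]; de <- espl[q + 1L, "end"]
      if (hasExon(eret, us, de))
        emit("RI", c(ispl[q, "start"] - 1L, ispl[q, "end"] + 1L),
             ispl[q, "end"] - ispl[q, "start"] + 1L, 3L - k, k)
    }
  }

  # alternative donor/acceptor: introns sharing one boundary, with the
  # alternative exons overlapping
  if (nrow(i1) && nrow(i2)) for (q1 in seq_len(nrow(i1))) for (q2 in seq_len(nrow(i2))) {
    s1 <- i1[q1, "start"]; en1 <- i1[q1, "end"]
    s2 <- i2[q2, "start"]; en2 <- i2[q2, "end"]
    if (en1 == en2 && s1 != s2) {
      # shared acceptor (genomic right); donors differ at the upstream exon
      u1 <- e1[q1, ]; u2 <- e2[q2, ]       # upstream exons end at s-1
      if (ov(u1["start"], u1["end"], u2["start"], u2["end"])) {
        type <- if (strand == "+") "A5" else "A3"
        incl <- if (s1 > s2) 1L else 2L     # longer exon keeps variable region
        emit(type, c(s1 - 1L, s2 - 1L, en1 + 1L), abs(s1 - s2), incl, 3L - incl)
      }
    }
    if (s1 == s2 && en1 != en2) {
      # shared donor (genomic left); acceptors differ at the downstream exon
      d1 <- e1[q1 + 1L, ]; d2 <- e2[q2 + 1L, ]
      if (ov(d1["start"], d1["end"], d2["start"], d2["end"])) {
        type <- if (strand == "+") "A3" else "A5"
        incl <- if (en1 < en2) 1L else 2L
        emit(type, c(s1 - 1L, en1 + 1L, en2 + 1L), abs(en1 - en2), incl, 3L - incl)
      }
    }
  }

  # MX: non-overlapping internal exons sharing both outer splice sites
  n1 <- nrow(e1); n2 <- nrow(e2)
  if (n1 >= 3L && n2 >= 3L) for (q1 in 2:(n1 - 1L)) for (q2 in 2:(n2 - 1L)) {
    E1 <- e1[q1, ]; E2 <- e2[q2, ]
    if (ov(E1["start"], E1["end"], E2["start"], E2["end"])) next
    if (e1[q1 - 1L, "end"] == e2[q2 - 1L, "end"] &&
        e1[q1 + 1L, "start"] == e2[q2 + 1L, "start"]) {
      d <- e1[q1 - 1L, "end"]; a <- e1[q1 + 1L, "start"]
      fivemost <- if (strand == "+") {
        if (E1["start"] < E2["start"]) 1L else 2L
      } else {
        if (E1["end"] > E2["end"]) 1L else 2L
      }
      Ein <- if (fivemost == 1L) E1 else E2
      emit("MX", c(d, E1["start"], E1["end"], E2["start"], E2["end"], a),
           Ein["end"] - Ein["start"] + 1L, fivemost, 3L - fivemost)
    }
  }

  # AF/AL: distinct non-overlapping terminal exons splicing into a shared
  # internal site (overlapping terminal exons fall under A5/A3 above)
  if (n1 >= 2L && n2 >= 2L) {
    F1 <- e1[1L, ]; F2 <- e2[1L, ]
    if (!(F1["start"] == F2["start"] && F1["end"] == F2["end"]) &&
        !ov(F1["start"], F1["end"], F2["start"], F2["end"]) &&
        i1[1L, "end"] == i2[1L, "end"]) {
      a <- i1[1L, "end"] + 1L
      type <- if (strand == "+") "AF" else "AL"
      incl <- if (F1["start"] < F2["start"]) 1L else 2L
      Fin <- if (incl == 1L) F1 else F2
      emit(type, c(sort(c(F1["start"], F1["end"], F2["start"], F2["end"])), a),
           Fin["end"] - Fin["start"] + 1L, incl, 3L - incl)
    }
    L1 <- e1[n1, ]; L2 <- e2[n2, ]
    if (!(L1["start"] == L2["start"] && L1["end"] == L2["end"]) &&
        !ov(L1["start"], L1["end"], L2["start"], L2["end"]) &&
        i1[n1 - 1L, "start"] == i2[n2 - 1L, "start"]) {
      d <- i1[n1 - 1L, "start"] - 1L
      type <- if (strand == "+") "AL" else "AF"
      incl <- if (L1["end"] > L2["end"]) 1L else 2L
      Lin <- if (incl == 1L) L1 else L2
      emit(type, c(d, sort(c(L1["start"], L1["end"], L2["start"], L2["end"]))),
           Lin["end"] - Lin["start"] + 1L, incl, 3L - incl)
    }
  }
  out
}

#' Percent-spliced-in from transcript abundances
#'
#' For each event and sample, PSI is the summed TPM of the inclusion
#' transcripts divided by the summed TPM of all event transcripts (inclusion
#' plus exclusion). A sample where the event's total abundance is zero gets a
#' missing value.
#'
#' @param events a [SpliceEvents] catalogue.
#' @param x transcript expression container (all event transcripts must be
#'   present as rows).
#' @return SummarizedExperiment with assay `psi` (events x samples) and the
#'   event table as rowData.
#' @export
computePsi <- function(events, x) {
  m <- .assayTpm(x)
  ev <- eventTable(events)
  allTx <- unique(c(unlist(ev$inclusion), unlist(ev$exclusion)))
  missing <- setdiff(allTx, rownames(m))
  if (length(missing))
    stop("event transcripts absent from the expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) " ...")
  psi <- matrix(NA_real_, nrow(ev), ncol(m),
                dimnames = list(ev$event_id, colnames(m)))
  incl_ix <- lapply(as.list(ev$inclusion), match, table = rownames(m))
  excl_ix <- lapply(as.list(ev$exclusion), match, table = rownames(m))
  for (i in seq_len(nrow(ev))) {
    inc <- colSums(m[incl_ix[[i]], , drop = FALSE])
    tot <- inc + colSums(m[excl_ix[[i]], , drop = FALSE])
    psi[i, ] <- ifelse(tot > 0, inc / tot, NA_real_)
  }
  cd <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::colData(x) else NULL
  args <- list(assays = list(psi = psi), rowData = ev)
  if (!is.null(cd)) args$colData <- cd
  do.call(SummarizedExperiment::SummarizedExperiment, args)
}

#' Filter splicing events on PSI support
#'
#' Keeps events whose PSI exceeds `psi_min` in no less than `frac_min` of the
#' samples (`ceiling(frac_min * n_samples)` supporting samples; missing PSI
#' values never count).
#'
#' @param psi PSI container from [computePsi()] (or matrix).
#' @param psi_min,frac_min filter thresholds.
#' @return filtered object, same class, order preserved.
#' @export
filterEvents <- function(psi, psi_min = 0.1, frac_min = 0.05) {
  m <- if (methods::is(psi, "SummarizedExperiment"))
    SummarizedExperiment::assay(psi, "psi") else psi
  need <- ceiling(frac_min * ncol(m))
  keep <- rowSums(m > psi_min, na.rm = TRUE) >= need
  if (is.matrix(psi)) psi[keep, , drop = FALSE] else psi[keep, ]
}

#' Differential splicing between two groups
#'
#' Per event: a two-sided rank-based comparison of PSI between the groups
#' (unpaired Wilcoxon rank-sum by default; a paired signed-rank variant is
#' available for equal-sized groups), the difference of group median PSI, and
#' BH FDR across events. An event is significant when |delta PSI| exceeds
#' `dpsi_min` and FDR is below `fdr_max`; setting `literal_median = TRUE`
#' instead requires the larger group-median PSI itself to exceed `dpsi_min`.
#' Events with fewer than 2 non-missing PSI values in either group are
#' skipped.
#'
#' @param psi PSI container from [computePsi()].
#' @param group_a,group_b group labels.
#' @param groups per-sample labels (defaults to `colData(psi)$group`).
#' @param test `"rank_sum"` (default) or `"signed_rank"`.
#' @param dpsi_min,fdr_max significance thresholds.
#' @param literal_median use the literal reading of the median-PSI rule.
#' @return data.frame `event_id`, `median_a`, `median_b`, `delta_psi`,
#'   `p_value`, `fdr`, `significant`.
#' @export
testDiffSplice <- function(psi, group_a, group_b, groups = NULL,
                           test = c("rank_sum", "signed_rank"),
                           dpsi_min = 0.1, fdr_max = 0.05,
                           literal_median = FALSE) {
  test <- match.arg(test)
  g <- .groupsOf(psi, groups)
  m <- if (methods::is(psi, "SummarizedExperiment"))
    SummarizedExperiment::assay(psi, "psi") else psi
  ia <- which(g == group_a); ib <- which(g == group_b)
  res <- lapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ia]; b <- m[i, ib]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    p <- rankTest(a, b, kind = test)
    data.frame(event_id = rownames(m)[i],
               median_a = stats::median(a), median_b = stats::median(b),
               delta_psi = stats::median(b) - stats::median(a),
               p_value = p)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped) message(skipped, " event(s) skipped for insufficient data")
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(event_id = character(),
    median_a = numeric(), median_b = numeric(), delta_psi = numeric(),
    p_value = numeric(), fdr = numeric(), significant = logical()))
  out$fdr <- bhFdr(out$p_value)
  effect <- if (literal_median) pmax(out$median_a, out$median_b) else
    abs(out$delta_psi)
  out$significant <- effect > dpsi_min & out$fdr < fdr_max
  out
}

#' Reading-frame preservation of the variable region
#'
#' An event preserves the reading frame when the length of its variable
#' region (in nucleotides of genomic span, not CDS-projected) is divisible by
#' three. Evaluated for events in protein-coding genes only; others are `NA`
#' (not applicable).
#'
#' @param events a [SpliceEvents] catalogue.
#' @return named logical vector along the event ids.
#' @export
intactCodon <- function(events) {
  ev <- eventTable(events)
  out <- ifelse(ev$biotype == "protein_coding", ev$var_length %% 3L == 0L, NA)
  stats::setNames(out, ev$event_id)
}

#' Tabulate events by type, biotype and sample group
#'
#' Counts (and within-biotype percentages) of expressed events across the
#' seven types and the gene biotypes. When a PSI container and group labels
#' are given, the PSI support filter is applied per group over that group's
#' samples; otherwise the whole catalogue is tabulated once (group `all`).
#'
#' @param events a [SpliceEvents] catalogue.
#' @param psi optional PSI container.
#' @param groups optional per-sample labels.
#' @param psi_min,frac_min per-group expression filter (see [filterEvents()]).
#' @return data.frame `group`, `biotype`, `event_type`, `n`, `pct` where `pct`
#'   sums to 100 within each group x biotype.
#' @export
eventSummary <- function(events, psi = NULL, groups = NULL,
                         psi_min = 0.1, frac_min = 0.05) {
  ev <- eventTable(events)
  tab1 <- function(ids, grp) {
    sub <- ev[ev$event_id %in% ids, , drop = FALSE]
    tt <- as.data.frame(table(
      biotype = factor(sub$biotype, levels = .BIOTYPES),
      event_type = factor(sub$event_type, levels = .EVENT_TYPES)))
    names(tt)[3] <- "n"
    tt$group <- grp
    bt_tot <- stats::ave(tt$n, tt$biotype, FUN = sum)
    tt$pct <- ifelse(bt_tot > 0, 100 * tt$n / bt_tot, 0)
    tt[, c("group", "biotype", "event_type", "n", "pct")]
  }
  if (is.null(psi)) return(tab1(ev$event_id, "all"))
  g <- .groupsOf(psi, groups)
  m <- if (methods::is(psi, "SummarizedExperiment"))
    SummarizedExperiment::assay(psi, "psi") else psi
  do.call(rbind, lapply(unique(g), function(grp) {
    sub <- m[, g == grp, drop = FALSE]
    kept <- rownames(filterEvents(sub, psi_min, frac_min))
    tab1(kept, grp)
  }))
}
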