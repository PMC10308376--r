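#' Filter RBPs on between-group expression change
#'
#' An RBP enters the network stage when its mean expression changes by no
#' less than `min_change` (relative to the `group_a` mean) between the two
#' groups: `|mean_b - mean_a| / mean_a >= min_change`. The boundary is
#' inclusive ("no less than 10%"). RBPs with zero reference mean are
#' excluded with a message.
#'
#' @param xr RBP expression container (rows = RBP ids).
#' @param group_a,group_b group labels (reference first).
#' @param groups per-sample labels.
#' @param min_change minimum relative change (0.1 = 10 percent).
#' @return data.frame `rbp_id`, `mean_a`, `mean_b`, `rel_change`,
#'   `direction` (up/down) for the passing RBPs.
#' @export
rbpExpressionFilter <- function(xr, group_a, group_b, groups = NULL,
                                min_change = 0.1) {
  g <- .groupsOf(xr, groups)
  m <- .assayTpm(xr)
  ia <- which(g == group_a); ib <- which(g == group_b)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  mean_a <- rowMeans(m[, ia, drop = FALSE])
  mean_b <- rowMeans(m[, ib, drop = FALSE])
  zero <- mean_a == 0
  if (any(zero))
    message(sum(zero), " RBP(s) with zero reference mean excluded")
  rel <- (mean_b - mean_a) / mean_a
  pass <- !zero & abs(rel) >= min_change
  data.frame(rbp_id = rownames(m)[pass], mean_a = mean_a[pass],
             mean_b = mean_b[pass], rel_change = rel[pass],
             direction = ifelse(rel[pass] > 0, "up", "down"),
             row.names = NULL)
}

#' Count CLIP binding sites near an event's splice sites
#'
#' For each event, windows of `window_bp` on either side of every defining
#' splice-site coordinate are merged (so one CLIP peak spanning two nearby
#' windows counts once) and binding intervals overlapping the merged windows
#' are counted per RBP. Overlap means non-empty interval intersection.
#'
#' @param events a [SpliceEvents] catalogue.
#' @param sites `GRanges` of binding intervals with mcol `rbp_id`
#'   (from [readBindingSites()]).
#' @param window_bp half-window size in bp (default 300).
#' @return data.frame `event_id`, `rbp_id`, `n_sites` (only pairs with
#'   `n_sites >= 1`).
#' @export
bindingEvidence <- function(events, sites, window_bp = 300) {
  ev <- eventTable(events)
  if (!nrow(ev) || !length(sites))
    return(data.frame(event_id = character(), rbp_id = character(),
                      n_sites = integer()))
  win <- lapply(seq_len(nrow(ev)), function(i) {
    s <- ev$sites[[i]]
    reduce(GRanges(ev$chrom[i],
                   IRanges(pmax(1L, s - window_bp), s + window_bp)))
  })
  nwin <- lengths(win)
  wgr <- do.call(c, win)
  evix <- rep(seq_len(nrow(ev)), nwin)
  hits <- findOverlaps(wgr, sites, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(event_id = character(), rbp_id = character(),
                      n_sites = integer()))
  df <- unique(data.frame(
    event = evix[S4Vectors::queryHits(hits)],
    site = S4Vectors::subjectHits(hits)))
  df$rbp_id <- mcols(sites)$rbp_id[df$site]
  agg <- stats::aggregate(site ~ event + rbp_id, data = df, FUN = length)
  data.frame(event_id = ev$event_id[agg$event], rbp_id = agg$rbp_id,
             n_sites = as.integer(agg$site), row.names = NULL)
}

#' Build an RBP-ASE regulatory network
#'
#' For every pair of an expression-change-passing RBP and a differentially
#' spliced event with at least one CLIP binding site within the
#' `window_bp` windows around the event's splice sites, the Spearman
#' correlation between RBP TPM and event PSI is computed across the samples
#' of the two compared groups (non-missing PSI only). Pairs with
#' `|rho| > rho_min` and p < `p_max` become edges. Binding is a hard filter:
#' pairs without binding evidence are never tested.
#'
#' @param psi PSI container ([computePsi()]).
#' @param xr RBP expression container (same samples).
#' @param events the [SpliceEvents] catalogue the PSI rows come from.
#' @param sites binding-site `GRanges`.
#' @param diff_events character vector of differentially spliced event ids
#'   (must be a subset of the PSI rows).
#' @param group_a,group_b groups whose samples enter the correlation; use
#'   `all_samples = TRUE` to correlate over every sample instead.
#' @param groups per-sample labels.
#' @param rho_min,p_max edge thresholds; `adjust` applies BH to edge p-values
#'   (off by default: the raw-p rule is the printed one).
#' @param window_bp,min_change forwarded to [bindingEvidence()] and
#'   [rbpExpressionFilter()].
#' @param gene_sets optional named list of gene sets; per-RBP enriched-pathway
#'   counts ([oraTest()] on the host genes of its regulated events, FDR <
#'   0.05, universe = all event host genes) are then reported.
#' @param all_samples correlate across all samples.
#' @return list with `edges` (data.frame `rbp_id`, `event_id`, `rho`,
#'   `p_value`, `n_sites`, `rbp_direction`) and `rbp_summary` (data.frame
#'   `rbp_id`, `direction`, `n_events`, `n_pathways`).
#' @export
buildRbpNetwork <- function(psi, xr, events, sites, diff_events,
                            group_a, group_b, groups = NULL,
                            rho_min = 0.5, p_max = 0.05, adjust = FALSE,
                            window_bp = 300, min_change = 0.1,
                            gene_sets = NULL, all_samples = FALSE) {
  g <- .groupsOf(psi, groups)
  pm <- if (methods::is(psi, "SummarizedExperiment"))
    SummarizedExperiment::assay(psi, "psi") else psi
  if (!all(diff_events %in% rownames(pm)))
    stop("diff_events must be a subset of the PSI rows")
  rm_ <- .assayTpm(xr)
  rbps <- rbpExpressionFilter(xr, group_a, group_b, groups = g,
                              min_change = min_change)
  sel <- if (all_samples) seq_along(g) else which(g %in% c(group_a, group_b))
  ev <- events[match(diff_events, eventIds(events))]
  bind <- bindingEvidence(ev, sites, window_bp = window_bp)
  bind <- bind[bind$rbp_id %in% rbps$rbp_id, , drop = FALSE]
  edges <- NULL
  if (nrow(bind)) {
    rows <- lapply(seq_len(nrow(bind)), function(i) {
      eid <- bind$event_id[i]; rid <- bind$rbp_id[i]
      y <- pm[eid, sel]; xv <- rm_[rid, sel]
      ok <- !is.na(y)
      if (sum(ok) < 3L) return(NULL)
      ct <- suppressWarnings(stats::cor.test(xv[ok], y[ok],
                                             method = "spearman"))
      data.frame(rbp_id = rid, event_id = eid, rho = unname(ct$estimate),
                 p_value = ct$p.value, n_sites = bind$n_sites[i])
    })
    nskip <- sum(vapply(rows, is.null, logical(1)))
    if (nskip) message(nskip, " pair(s) skipped: fewer than 3 observations")
    edges <- do.call(rbind, rows)
  }
  if (is.null(edges))
    edges <- data.frame(rbp_id = character(), event_id = character(),
                        rho = numeric(), p_value = numeric(),
                        n_sites = integer())
  pv <- if (adjust && nrow(edges)) bhFdr(edges$p_value) else edges$p_value
  keep <- nrow(edges) > 0 & abs(edges$rho) > rho_min & pv < p_max
  edges <- edges[which(keep), , drop = FALSE]
  edges$rbp_direction <- rbps$direction[match(edges$rbp_id, rbps$rbp_id)]
  evtab <- eventTable(events)
  gene_of_event <- stats::setNames(evtab$gene_id, evtab$event_id)
  summ <- if (nrow(edges)) {
    do.call(rbind, lapply(split(edges, edges$rbp_id), function(e) {
      npw <- NA_integer_
      if (!is.null(gene_sets)) {
        uni <- unique(unname(gene_of_event))
        q <- unique(unname(gene_of_event[e$event_id]))
        o <- oraTest(q, gene_sets, uni)
        npw <- sum(o$fdr < 0.05)
      }
      data.frame(rbp_id = e$rbp_id[1], direction = e$rbp_direction[1],
                 n_events = nrow(e), n_pathways = npw)
    }))
  } else data.frame(rbp_id = character(), direction = character(),
                    n_events = integer(), n_pathways = integer())
  rownames(summ) <- NULL
  list(edges = edges, rbp_summary = summ)
}
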