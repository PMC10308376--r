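#' Synthetic cohort configuration
#'
#' Collects every knob of the synthetic-data generator: cohort sizes, the
#' log-normal expression noise model, and the planted effects (transcript
#' fold changes, reciprocal isoform switches with their PSI shift, RBP
#' drivers with CLIP binding). Defaults instantiate a desk-scale cohort in
#' which every planted effect is detectable by the pipeline's printed
#' thresholds: 60 samples per diagnostic group, fold change 3, isoform-
#' fraction shift 0.3, driver strength 0.8, binding windows of 300 bp.
#'
#' @param n_genes number of multi-transcript genes (each instantiates one
#'   local splicing event).
#' @param transcripts_per_gene integer range `c(min, max)`; genes beyond two
#'   transcripts carry structural duplicates of the inclusion isoform.
#' @param n_control,n_asymad,n_ad samples per diagnostic group.
#' @param tpm_log_mean,tpm_log_sd mean and per-sample sd of gene-level
#'   log-TPM; `gene_log_sd` is the between-gene spread of baselines.
#' @param frac_det fraction of genes whose transcripts get a planted fold
#'   change (half up, half down) in the affected group(s).
#' @param planted_fc planted fold change (> 1).
#' @param frac_switch fraction of genes with a planted reciprocal isoform
#'   switch (which also shifts the event's PSI by `planted_dif`).
#' @param planted_dif planted isoform-fraction shift, in (0, 0.5].
#' @param n_rbp number of RBP pseudo-genes.
#' @param frac_driven_events fraction of switched events coupled to an RBP
#'   driver (only differentially spliced events enter the network).
#' @param driver_strength coupling scale in \[0, 1\] between the latent driver
#'   variable, RBP expression and event inclusion balance.
#' @param binding_window_bp half-window for planted binding sites.
#' @param if_sd per-sample sd of the within-pair inclusion fraction.
#' @param extra_share expression share of duplicate transcripts in genes with
#'   more than two isoforms.
#' @param frac_inframe fraction of events whose variable region length is a
#'   multiple of three.
#' @param affected_groups diagnostic group(s) carrying the planted effects.
#' @param event_types splicing event types to cycle through.
#' @param seed RNG seed.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_genes = 500,
                             transcripts_per_gene = c(2L, 3L),
                             n_control = 60L, n_asymad = 60L, n_ad = 60L,
                             tpm_log_mean = 2, tpm_log_sd = 0.5,
                             gene_log_sd = 1,
                             frac_det = 0.1, planted_fc = 3,
                             frac_switch = 0.15, planted_dif = 0.3,
                             n_rbp = 30L, frac_driven_events = 0.25,
                             driver_strength = 0.8, binding_window_bp = 300L,
                             if_sd = 0.05, extra_share = 0.2,
                             frac_inframe = 1 / 3,
                             affected_groups = "ad",
                             event_types = c("SE", "A5", "A3", "MX", "RI",
                                             "AF", "AL"),
                             seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_det, cfg$frac_switch, cfg$frac_driven_events,
          cfg$frac_inframe, cfg$extra_share)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$planted_fc <= 1) stop("planted_fc must exceed 1")
  if (cfg$planted_dif <= 0 || cfg$planted_dif > 0.5)
    stop("planted_dif must lie in (0, 0.5]")
  if (any(c(cfg$n_genes, cfg$n_control, cfg$n_asymad, cfg$n_ad, cfg$n_rbp) < 1))
    stop("counts must be positive")
  if (cfg$driver_strength < 0 || cfg$driver_strength > 1)
    stop("driver_strength must lie in [0, 1]")
  if (!all(cfg$event_types %in% .EVENT_TYPES)) stop("unknown event type")
  stopifnot(length(cfg$transcripts_per_gene) == 2L,
            cfg$transcripts_per_gene[1] >= 1L,
            cfg$transcripts_per_gene[2] >= cfg$transcripts_per_gene[1])
  class(cfg) <- "SimulationConfig"
  cfg
}

# genomic two-transcript template for one event type; coordinates laid out
# left to right from `anchor`. `vlen` is the variable-region length the event
# must end up with. Returns exon matrices, the index (1/2) of the inclusion
# transcript under the strand-aware event definitions, the defining sites
# and the realised event label.
.template <- function(type, strand, anchor, vlen, rl) {
  ex <- function(s, w) c(s, s + w - 1L)
  mat <- function(...) {
    m <- do.call(rbind, list(...))
    colnames(m) <- c("start", "end"); m
  }
  # map intended label to the genomic configuration that yields it
  gtype <- type
  if (strand == "-") gtype <- c(SE = "SE", RI = "RI", MX = "MX", A5 = "A3",
                                A3 = "A5", AF = "AL", AL = "AF")[[type]]
  li <- rl; p <- anchor
  if (gtype == "SE") {
    A <- ex(p, rl()); E <- ex(A[2] + li() , vlen); B <- ex(E[2] + li(), rl())
    t1 <- mat(A, E, B); t2 <- mat(A, B)
    list(t1 = t1, t2 = t2, incl = 1L,
         sites = c(A[2], E[1], E[2], B[1]), type = type)
  } else if (gtype == "RI") {
    A <- ex(p, rl()); B <- ex(A[2] + vlen + 1L, rl())
    t1 <- mat(c(A[1], B[2])); t2 <- mat(A, B)
    list(t1 = t1, t2 = t2, incl = 1L, sites = c(A[2], B[1]), type = type)
  } else if (gtype == "A5") {
    w <- rl()
    Along <- ex(p, w + vlen); Ashort <- ex(p, w)
    B <- ex(Along[2] + li(), rl())
    t1 <- mat(Along, B); t2 <- mat(Ashort, B)
    incl <- if (strand == "+") 1L else 1L  # longer exon holds the region
    list(t1 = t1, t2 = t2, incl = incl,
         sites = c(Along[2], Ashort[2], B[1]), type = type)
  } else if (gtype == "A3") {
    A <- ex(p, rl()); b1 <- A[2] + li()
    Blong <- ex(b1, rl() + vlen); Bshort <- c(b1 + vlen, Blong[2])
    t1 <- mat(A, Blong); t2 <- mat(A, Bshort)
    list(t1 = t1, t2 = t2, incl = 1L,
         sites = c(A[2], Blong[1], Bshort[1]), type = type)
  } else if (gtype == "MX") {
    A <- ex(p, rl()); E1 <- ex(A[2] + li(), rl()); E2 <- ex(E1[2] + li(), rl())
    # the 5'-most exon is the variable region; set its width to vlen
    if (strand == "+") {
      w2 <- E2[2] - E2[1] + 1L
      E1 <- ex(E1[1], vlen)
      if (E2[1] <= E1[2]) E2 <- ex(E1[2] + li(), w2)
    } else E2 <- ex(E2[1], vlen)
    B <- ex(E2[2] + li(), rl())
    t1 <- mat(A, E1, B); t2 <- mat(A, E2, B)
    incl <- if (strand == "+") 1L else 2L
    list(t1 = t1, t2 = t2, incl = incl,
         sites = c(A[2], E1[1], E1[2], E2[1], E2[2], B[1]), type = type)
  } else if (gtype == "AF") {
    # genomic-left alternative terminal exons, shared downstream acceptor
    F1 <- ex(p, if (strand == "+") vlen else rl())
    F2 <- ex(F1[2] + li(), if (strand == "+") rl() else vlen)
    B <- ex(F2[2] + li(), rl())
    t1 <- mat(F1, B); t2 <- mat(F2, B)
    incl <- if (strand == "+") 1L else 1L  # AF incl 5'-most; AL(-) incl 3'-most
    list(t1 = t1, t2 = t2, incl = incl,
         sites = c(sort(c(F1, F2)), B[1]), type = type)
  } else { # gtype AL: genomic-right alternative terminal exons, shared donor
    A <- ex(p, rl())
    L1 <- ex(A[2] + li(), if (strand == "+") rl() else vlen)
    L2 <- ex(L1[2] + li(), if (strand == "+") vlen else rl())
    t1 <- mat(A, L1); t2 <- mat(A, L2)
    incl <- 2L  # genomic-rightmost terminal exon holds the variable region
    list(t1 = t1, t2 = t2, incl = incl,
         sites = c(A[2], sort(c(L1, L2))), type = type)
  }
}

#' Simulate an annotation with one planted splicing event per gene
#'
#' Builds `n_genes` genes from two-transcript templates cycling through the
#' requested event types on alternating strands; additional transcripts (up
#' to `transcripts_per_gene[2]`) are structural duplicates of the inclusion
#' isoform, so each gene carries exactly one local event. A `frac_inframe`
#' fraction of variable-region lengths is forced to a multiple of three.
#' Deterministic for a fixed config.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `models` ([TxModels]) and `templates` (`DataFrame` of
#'   per-gene ground truth: intended event id, type, inclusion/exclusion/extra
#'   transcripts, defining sites, variable length).
#' @export
simulateAnnotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed %% 2147483647L)
  types <- rep(cfg$event_types, length.out = cfg$n_genes)
  rl <- function() sample(60:240, 1L)
  exrows <- vector("list", cfg$n_genes)
  trows <- vector("list", cfg$n_genes)
  tmpl <- vector("list", cfg$n_genes)
  biotypes <- sample(c("protein_coding", "lncRNA", "pseudogene"),
                     cfg$n_genes, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%05d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    vlen <- sample(30:180, 1L)
    inframe <- stats::runif(1) < cfg$frac_inframe
    vlen <- vlen - vlen %% 3L + if (inframe) 0L else sample(1:2, 1L)
    tp <- .template(types[i], strand, anchor = (i - 1L) * 100000L + 1001L,
                    vlen = as.integer(vlen), rl = rl)
    tx_rng <- seq(cfg$transcripts_per_gene[1], cfg$transcripts_per_gene[2])
    n_tx <- if (length(tx_rng) == 1L) tx_rng else sample(tx_rng, 1L)
    n_extra <- max(0L, n_tx - 2L)
    incl_id <- sprintf("%s.T1", gid); excl_id <- sprintf("%s.T2", gid)
    exin <- if (tp$incl == 1L) tp$t1 else tp$t2
    exex <- if (tp$incl == 1L) tp$t2 else tp$t1
    if (n_tx < 2L) {   # single-isoform gene: no event is instantiated
      txs <- list(exin); txids <- incl_id
    } else {
      extra_ids <- if (n_extra > 0L) sprintf("%s.T%d", gid, 2L + seq_len(n_extra))
                   else character()
      txs <- c(list(exin, exex), rep(list(exin), n_extra))
      txids <- c(incl_id, excl_id, extra_ids)
    }
    exrows[[i]] <- data.frame(
      start = unlist(lapply(txs, function(m) m[, "start"])),
      end = unlist(lapply(txs, function(m) m[, "end"])),
      transcript_id = rep(txids, vapply(txs, nrow, integer(1))),
      gene_id = gid, strand = strand)
    trows[[i]] <- data.frame(transcript_id = txids, gene_id = gid,
                             biotype = biotypes[i], chrom = "chr1",
                             strand = strand)
    sites <- sort(as.integer(tp$sites))
    tmpl[[i]] <- data.frame(
      gene_id = gid, event_type = if (n_tx < 2L) NA_character_ else tp$type,
      chrom = "chr1", strand = strand,
      inclusion_tx = incl_id,
      exclusion_tx = if (n_tx < 2L) NA_character_ else excl_id,
      n_extra = n_extra, biotype = biotypes[i],
      var_length = as.integer(vlen),
      sites_str = paste(sites, collapse = ","),
      event_id = if (n_tx < 2L) NA_character_ else
        paste0(gid, ";", tp$type, ";chr1:",
               paste(sites, collapse = "-"), ":", strand))
  }
  exdf <- do.call(rbind, exrows)
  gr <- GRanges("chr1", IRanges(exdf$start, exdf$end), strand = exdf$strand)
  mcols(gr)$transcript_id <- exdf$transcript_id
  mcols(gr)$gene_id <- exdf$gene_id
  tx <- DataFrame(do.call(rbind, trows))
  templates <- DataFrame(do.call(rbind, tmpl))
  templates$sites <- IntegerList(lapply(strsplit(templates$sites_str, ","),
                                        as.integer))
  templates$sites_str <- NULL
  list(models = TxModels(gr, tx), templates = templates)
}

#' Simulate the cohort expression matrix with planted effects
#'
#' Gene totals are drawn log-normally per sample; each gene's two event
#' isoforms split a (jittered) share of the total according to a per-sample
#' inclusion fraction, so planted switches redistribute expression within a
#' fixed per-sample gene total. Planted fold changes multiply all transcripts
#' of selected non-switch genes in the affected group(s); planted switches
#' shift the inclusion fraction so the inclusion isoform's IF moves by
#' `planted_dif` (and the sibling by the opposite amount), which also shifts
#' the event's PSI by `planted_dif`; RBP drivers add a latent per-sample
#' variable to both the RBP's log expression and the inclusion balance of
#' their event. Sample metadata is drawn uniformly from the defining CERAD/
#' Braak/MMSE ranges of each intended group (never the ambiguous overlap
#' cell), so classification recovers the groups exactly.
#'
#' @param ann output of [simulateAnnotation()].
#' @param cfg the same [simulationConfig()].
#' @return list with `expr` (transcript SummarizedExperiment; colData holds
#'   sample_id, cerad, braak, mmse, group), `rbp` (RBP SummarizedExperiment),
#'   and `truth` (planted-effect sets: `det_up`, `det_down`, `switch_up`,
#'   `switch_down`, `differential_events`, `driver_edges`, plus the planted
#'   gene sets).
#' @export
simulateExpression <- function(ann, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed((cfg$seed + 1000003L) %% 2147483647L)
  tmpl <- ann$templates
  n_genes <- nrow(tmpl)
  groups <- rep(c("control", "asymad", "ad"),
                c(cfg$n_control, cfg$n_asymad, cfg$n_ad))
  ns <- length(groups)
  sample_id <- sprintf("S%04d", seq_len(ns))
  affected <- groups %in% cfg$affected_groups

  meta <- .drawMetadata(groups, sample_id)

  # planted effect assignment; only multi-isoform genes can carry a switch
  event_genes <- tmpl$gene_id[!is.na(tmpl$event_id)]
  n_switch <- min(round(cfg$frac_switch * n_genes), length(event_genes))
  switch_genes <- if (n_switch > 0)
    sort(sample(event_genes, n_switch)) else character()
  det_pool <- setdiff(tmpl$gene_id, switch_genes)
  n_det <- min(round(cfg$frac_det * n_genes), length(det_pool))
  det_genes <- if (n_det > 0) sort(sample(det_pool, n_det)) else character()
  det_up_genes <- det_genes[seq_len(floor(n_det / 2))]
  det_dn_genes <- setdiff(det_genes, det_up_genes)
  n_driven <- round(cfg$frac_driven_events * length(switch_genes))
  driven_genes <- if (n_driven > 0) sort(sample(switch_genes, n_driven))
                  else character()
  rbp_ids <- sprintf("RBP%03d", seq_len(cfg$n_rbp))
  driver_rbp <- if (n_driven > 0)
    sample(rbp_ids, n_driven, replace = n_driven > cfg$n_rbp) else character()
  names(driver_rbp) <- driven_genes
  switch_sign <- stats::setNames(sample(c(-1, 1), n_switch, replace = TRUE),
                                 switch_genes)

  tx <- txTable(ann$models)
  tpm <- matrix(0, nrow(tx), ns, dimnames = list(tx$transcript_id, sample_id))
  truth_sw_up <- truth_sw_dn <- character()
  # latent driver variables on their own stream, and the matrix noise on a
  # stream untouched by how many planted-effect draws happened above, so that
  # configs differing only in planted fractions share per-sample gene totals
  set.seed((cfg$seed + 5000003L) %% 2147483647L)
  zmat <- if (n_driven > 0)
    matrix(stats::rnorm(n_driven * ns), nrow = n_driven) else NULL
  set.seed((cfg$seed + 4000003L) %% 2147483647L)

  # plain-vector views of the template table and a rowname index for the
  # assignment-heavy loop
  tm_gene <- tmpl$gene_id; tm_incl <- tmpl$inclusion_tx
  tm_excl <- tmpl$exclusion_tx; tm_extra <- tmpl$n_extra
  rowix <- stats::setNames(seq_len(nrow(tpm)), rownames(tpm))
  tx_by_gene <- split(tx$transcript_id, tx$gene_id)

  for (i in seq_len(n_genes)) {
    gid <- tm_gene[i]
    b_g <- stats::rnorm(1, cfg$tpm_log_mean, cfg$gene_log_sd)
    G <- exp(b_g + stats::rnorm(ns, 0, cfg$tpm_log_sd))
    n_extra <- tm_extra[i]
    pair_share0 <- if (n_extra > 0) 1 - cfg$extra_share else 1
    # shares of the duplicate isoforms, jittered then renormalised
    if (n_extra > 0) {
      w_extra <- matrix(cfg$extra_share / n_extra *
                          exp(stats::rnorm(n_extra * ns, 0, 0.15)),
                        nrow = n_extra)
      tot_w <- pair_share0 + colSums(w_extra)
      pair_share <- pair_share0 / tot_w
      w_extra <- sweep(w_extra, 2, tot_w, "/")
    } else pair_share <- rep(1, ns)
    # inclusion balance on the logit scale: group shifts, latent driver and
    # noise stay monotone in the driver variable and never saturate
    l0 <- rep(0, ns)
    if (gid %in% switch_genes) {
      dshift <- switch_sign[[gid]] * cfg$planted_dif / pair_share0
      l0[affected] <- stats::qlogis(pmin(0.98, pmax(0.02, 0.5 + dshift)))
    }
    if (gid %in% driven_genes) {
      k <- match(gid, driven_genes)
      l0 <- l0 + cfg$driver_strength * zmat[k, ]
    }
    f <- stats::plogis(l0 + stats::rnorm(ns, 0, 4 * cfg$if_sd))
    incl <- tm_incl[i]; excl <- tm_excl[i]
    if (is.na(excl)) {
      tpm[rowix[[incl]], ] <- G
    } else {
      tpm[rowix[[incl]], ] <- G * pair_share * f
      tpm[rowix[[excl]], ] <- G * pair_share * (1 - f)
    }
    if (n_extra > 0) {
      eids <- sprintf("%s.T%d", gid, 2L + seq_len(n_extra))
      for (k in seq_len(n_extra)) tpm[rowix[[eids[k]]], ] <- G * w_extra[k, ]
    }
    if (gid %in% det_up_genes) {
      rows <- rowix[tx_by_gene[[gid]]]
      tpm[rows, affected] <- tpm[rows, affected] * cfg$planted_fc
    } else if (gid %in% det_dn_genes) {
      rows <- rowix[tx_by_gene[[gid]]]
      tpm[rows, affected] <- tpm[rows, affected] / cfg$planted_fc
    }
    if (gid %in% switch_genes) {
      if (switch_sign[[gid]] > 0) {
        truth_sw_up <- c(truth_sw_up, incl); truth_sw_dn <- c(truth_sw_dn, excl)
      } else {
        truth_sw_up <- c(truth_sw_up, excl); truth_sw_dn <- c(truth_sw_dn, incl)
      }
    }
  }

  # RBP pseudo-genes
  rbp <- matrix(0, cfg$n_rbp, ns, dimnames = list(rbp_ids, sample_id))
  for (r in seq_len(cfg$n_rbp)) {
    b_r <- stats::rnorm(1, cfg$tpm_log_mean, cfg$gene_log_sd)
    lt <- b_r + stats::rnorm(ns, 0, cfg$tpm_log_sd)
    rbp[r, ] <- exp(lt)
  }
  # driver RBPs covary with the latent variable of their event and carry a
  # group shift aligned with the event's usage shift, so the within-group and
  # between-group association components add rather than cancel
  for (gid in driven_genes) {
    k <- match(gid, driven_genes)
    rid <- driver_rbp[[gid]]
    shift <- log(2) * switch_sign[[gid]]
    rbp[rid, ] <- rbp[rid, ] * exp(cfg$driver_strength * zmat[k, ]) *
      exp(ifelse(affected, shift, 0))
  }

  cd <- DataFrame(meta, group = groups, row.names = sample_id)
  expr <- tpmExperiment(tpm, colData = cd,
                        rowData = DataFrame(transcript_id = rownames(tpm),
                                            gene_id = tx$gene_id))
  rbp_se <- tpmExperiment(rbp, colData = cd)
  det_tx <- function(gs) tx$transcript_id[tx$gene_id %in% gs]
  # a planted switch also shifts the two event isoforms' own expression
  # (up for the isoform gaining usage, down for its sibling) while the gene
  # total is conserved -- record every truly expression-shifted transcript
  truth <- list(
    det_up = det_tx(det_up_genes), det_down = det_tx(det_dn_genes),
    expr_up = c(det_tx(det_up_genes), truth_sw_up),
    expr_down = c(det_tx(det_dn_genes), truth_sw_dn),
    det_genes_up = det_up_genes, det_genes_down = det_dn_genes,
    switch_up = truth_sw_up, switch_down = truth_sw_dn,
    switch_genes = switch_genes,
    differential_events = tmpl$event_id[tmpl$gene_id %in% switch_genes],
    driver_edges = data.frame(
      rbp_id = unname(driver_rbp),
      event_id = tmpl$event_id[match(driven_genes, tmpl$gene_id)],
      gene_id = driven_genes, row.names = NULL))
  list(expr = expr, rbp = rbp_se, truth = truth)
}

# uniform metadata draws from each group's defining score ranges; the
# ambiguous CERAD 3 / Braak 3 non-demented cell is never emitted
.drawMetadata <- function(groups, sample_id) {
  cells <- list(
    control = within(expand.grid(cerad = 3:4, braak = 0:3), mmse_lo <- 24),
    asymad = within(expand.grid(cerad = 1:3, braak = 3:6), mmse_lo <- 24),
    ad = within(expand.grid(cerad = 1:2, braak = 3:6), mmse_lo <- 0))
  cells$control <- cells$control[!(cells$control$cerad == 3 &
                                     cells$control$braak == 3), ]
  cells$asymad <- cells$asymad[!(cells$asymad$cerad == 3 &
                                   cells$asymad$braak == 3), ]
  cerad <- braak <- mmse <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    pick <- cells[[g]][sample(nrow(cells[[g]]), length(idx), replace = TRUE), ]
    cerad[idx] <- pick$cerad; braak[idx] <- pick$braak
    mmse[idx] <- if (g == "ad") sample(0:23, length(idx), replace = TRUE)
                 else sample(24:30, length(idx), replace = TRUE)
  }
  DataFrame(sample_id = sample_id, cerad = cerad, braak = braak, mmse = mmse)
}

#' Simulate CLIP binding sites
#'
#' For every planted driver edge, one binding interval (width 21) is placed
#' inside the `binding_window_bp` window around one of the event's defining
#' splice sites; in addition, decoy intervals for non-driver RBP-event pairs
#' are placed strictly outside every window of their event (distance greater
#' than the window from all defining coordinates).
#'
#' @param ann output of [simulateAnnotation()].
#' @param truth `truth` element of [simulateExpression()].
#' @param cfg the [simulationConfig()].
#' @param n_decoys_per_event decoy RBP-event pairs per event.
#' @return `GRanges` with mcols `rbp_id` and `role` (driver/decoy).
#' @export
simulateBindingSites <- function(ann, truth, cfg, n_decoys_per_event = 2L) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed((cfg$seed + 2000003L) %% 2147483647L)
  tmpl <- ann$templates
  w <- cfg$binding_window_bp
  rbp_ids <- sprintf("RBP%03d", seq_len(cfg$n_rbp))
  site_list <- as.list(tmpl$sites)
  de <- truth$driver_edges
  chrom <- character(); st <- integer(); en <- integer()
  rbp <- character(); role <- character()
  if (nrow(de)) {
    centers <- vapply(seq_len(nrow(de)), function(i) {
      s <- site_list[[match(de$event_id[i], tmpl$event_id)]]
      site <- s[sample(length(s), 1L)]
      site + if (w > 0) sample((-w):w, 1L) else 0L
    }, numeric(1))
    chrom <- c(chrom, tmpl$chrom[match(de$event_id, tmpl$event_id)])
    st <- c(st, as.integer(pmax(1, centers - 10L)))
    en <- c(en, as.integer(centers + 10L))
    rbp <- c(rbp, de$rbp_id); role <- c(role, rep("driver", nrow(de)))
  }
  if (n_decoys_per_event > 0L) {
    drv_by_event <- split(de$rbp_id, de$event_id)
    maxs <- vapply(site_list, max, numeric(1))
    for (i in which(!is.na(tmpl$event_id))) {
      pool <- setdiff(rbp_ids, drv_by_event[[tmpl$event_id[i]]])
      picks <- sample(pool, min(n_decoys_per_event, length(pool)))
      s0 <- maxs[i] + w + 22L + sample(0:500, length(picks), replace = TRUE)
      chrom <- c(chrom, rep(tmpl$chrom[i], length(picks)))
      st <- c(st, as.integer(s0)); en <- c(en, as.integer(s0 + 20L))
      rbp <- c(rbp, picks); role <- c(role, rep("decoy", length(picks)))
    }
  }
  gr <- GRanges(chrom, IRanges(st, en))
  mcols(gr)$rbp_id <- rbp
  mcols(gr)$role <- role
  gr
}

#' Simulate GMT gene sets with known enrichment structure
#'
#' One set per planted-effect category (fold-change up, fold-change down,
#' isoform switch) plus random sets drawn from all genes, so that
#' over-representation analysis has known-enriched and null sets.
#'
#' @param ann output of [simulateAnnotation()].
#' @param truth `truth` element of [simulateExpression()].
#' @param cfg the [simulationConfig()].
#' @param n_random number of random sets.
#' @return named list of gene-id vectors.
#' @export
simulateGeneSets <- function(ann, truth, cfg, n_random = 5L) {
  set.seed((cfg$seed + 3000003L) %% 2147483647L)
  genes <- unique(txTable(ann$models)$gene_id)
  sets <- list()
  if (length(truth$det_genes_up)) sets$planted_det_up <- truth$det_genes_up
  if (length(truth$det_genes_down)) sets$planted_det_down <- truth$det_genes_down
  if (length(truth$switch_genes)) sets$planted_switch <- truth$switch_genes
  for (i in seq_len(n_random))
    sets[[sprintf("random_set_%02d", i)]] <-
      sort(sample(genes, min(length(genes), sample(10:30, 1L))))
  sets
}

#' Generate a complete synthetic cohort
#'
#' Runs the annotation, expression, binding-site and gene-set generators in
#' order and optionally writes every artefact to disk (GTF, TSV expression
#' matrix of transcripts plus RBP pseudo-genes, TSV metadata, BED6 binding
#' sites, GMT gene sets, JSON ground truth). Deterministic for a fixed
#' config.
#'
#' @param cfg a [simulationConfig()].
#' @param dir optional output directory.
#' @return list with `models`, `templates`, `expr`, `rbp`, `truth`, `sites`,
#'   `gene_sets` (and `paths` when written).
#' @export
simulateCohort <- function(cfg = simulationConfig(), dir = NULL) {
  ann <- simulateAnnotation(cfg)
  ex <- simulateExpression(ann, cfg)
  sites <- simulateBindingSites(ann, ex$truth, cfg)
  gene_sets <- simulateGeneSets(ann, ex$truth, cfg)
  out <- list(models = ann$models, templates = ann$templates,
              expr = ex$expr, rbp = ex$rbp, truth = ex$truth,
              sites = sites, gene_sets = gene_sets)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      gtf = file.path(dir, "annotation.gtf"),
      expr = file.path(dir, "expression.tsv"),
      metadata = file.path(dir, "metadata.tsv"),
      bed = file.path(dir, "binding_sites.bed"),
      gmt = file.path(dir, "gene_sets.gmt"),
      rbp_list = file.path(dir, "rbp_list.txt"),
      truth = file.path(dir, "ground_truth.json"))
    writeGTF(ann$models, paths$gtf)
    allTpm <- rbind(SummarizedExperiment::assay(ex$expr, "tpm"),
                    SummarizedExperiment::assay(ex$rbp, "tpm"))
    writeExpressionTsv(allTpm, paths$expr, id_col = "feature_id")
    utils::write.table(as.data.frame(SummarizedExperiment::colData(ex$expr))[
      , c("sample_id", "cerad", "braak", "mmse")],
      paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
    bed <- sites
    mcols(bed)$name <- mcols(sites)$rbp_id
    mcols(bed)$score <- 0L
    rtracklayer::export(bed, paths$bed, format = "bed")
    writeGMT(gene_sets, paths$gmt)
    writeLines(sprintf("RBP%03d", seq_len(cfg$n_rbp)), paths$rbp_list)
    jsonlite::write_json(ex$truth, paths$truth, auto_unbox = FALSE,
                         dataframe = "columns", digits = NA)
    out$paths <- paths
  }
  out
}
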