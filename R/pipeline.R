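#' Default run configuration
#'
#' All pipeline thresholds at their printed defaults — TPM filter 0.1 in 5%
#' of samples, fold change 1.5 / 0.67, FDR 0.05, PSI filter 0.1 in 5%,
#' |delta PSI| 0.1, |dIF| 0.1, Spearman |rho| 0.5, binding window 300 bp, RBP
#' change 10%, Pearson |r| 0.3, 20% change sets — plus the comparison list
#' (control vs asymad, control vs ad, asymad vs ad), the simulation config
#' and the seed. Any field may be overridden via `...` or a YAML file
#' ([readRunConfig()]).
#'
#' @param ... fields to override (nested lists are merged shallowly).
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    comparisons = list(c("control", "asymad"), c("control", "ad"),
                       c("asymad", "ad")),
    thresholds = list(tpm_min = 0.1, frac_min = 0.05, fc_up = 1.5,
                      fc_down = 0.67, fdr = 0.05, psi_min = 0.1,
                      dpsi_min = 0.1, dif_min = 0.1, rho_min = 0.5,
                      window_bp = 300, rbp_change_min = 0.1, pearson_r = 0.3,
                      change_frac = 0.2, eps = 0.01),
    simulate = NULL,   # filled from seed at run time when simulating
    paths = list(gtf = NULL, expr = NULL, metadata = NULL, bed = NULL,
                 rbp_list = NULL, gmt = NULL))
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("thresholds", "paths") && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  bad <- unlist(cfg$comparisons)[!unlist(cfg$comparisons) %in%
                                   c("control", "asymad", "ad")]
  if (length(bad)) stop("unknown group label(s) in comparisons: ",
                        paste(unique(bad), collapse = ", "))
  th <- cfg$thresholds
  if (any(unlist(th[c("fc_up", "fdr", "psi_min", "dpsi_min", "dif_min",
                      "rho_min", "window_bp", "rbp_change_min")]) <= 0))
    stop("thresholds must be positive")
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys override [runConfig()] defaults.
#' @return `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$comparisons))
    y$comparisons <- lapply(y$comparisons, as.character)
  if (!is.null(y$simulate)) y$simulate <- do.call(simulationConfig, y$simulate)
  do.call(runConfig, y)
}

.stageLog <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or input loading), sample classification,
#' low-expression filtering, differential transcript expression per
#' comparison, transcript-host-gene correlation, event inference, PSI
#' quantification and filtering, differential splicing, isoform-fraction
#' switch detection, the 20%-change cross-tabulation, RBP-ASE network
#' construction and gene-set over-representation, writing every intermediate
#' table as TSV plus a JSON run manifest (seed, thresholds, row counts per
#' stage). Outputs are byte-reproducible for a fixed config.
#'
#' @param config a [runConfig()] (or [readRunConfig()]) list.
#' @param out_dir output directory, created if needed.
#' @param simulate generate the cohort with [simulateCohort()] (default);
#'   otherwise all input paths in `config$paths` must exist.
#' @return (invisibly) list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
runPipeline <- function(config = runConfig(), out_dir, simulate = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  th <- config$thresholds
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "spliceAD",
                   version = as.character(utils::packageVersion("spliceAD")),
                   seed = config$seed, thresholds = th, counts = list())
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (simulate) {
    .stageLog("simulate", "generating synthetic cohort (seed ", config$seed, ")")
    sim_cfg <- if (is.null(config$simulate))
      simulationConfig(seed = config$seed) else config$simulate
    cohort <- simulateCohort(sim_cfg, dir = file.path(out_dir, "inputs"))
    models <- cohort$models
    expr <- cohort$expr
    rbp <- cohort$rbp
    sites <- cohort$sites
    gene_sets <- cohort$gene_sets
    meta <- as.data.frame(SummarizedExperiment::colData(expr))[
      , c("sample_id", "cerad", "braak", "mmse")]
  } else {
    p <- config$paths
    missing <- names(p)[vapply(p, function(x) is.null(x) || !file.exists(x),
                               logical(1))]
    if (length(missing)) stop("missing input path(s): ",
                              paste(missing, collapse = ", "))
    .stageLog("load", "reading inputs")
    models <- readGTF(p$gtf)
    allTpm <- readExpressionTsv(p$expr)
    rbp_ids <- readRbpList(p$rbp_list)
    meta <- utils::read.delim(p$metadata)
    txrows <- setdiff(rownames(allTpm), rbp_ids)
    cd <- DataFrame(meta, row.names = meta$sample_id)
    expr <- tpmExperiment(allTpm[txrows, , drop = FALSE], colData = cd)
    rbp <- tpmExperiment(allTpm[intersect(rownames(allTpm), rbp_ids), ,
                                drop = FALSE], colData = cd)
    sites <- readBindingSites(p$bed, rbp_ids = rbp_ids)
    gene_sets <- readGMT(p$gmt)
  }

  .stageLog("classify", "assigning diagnostic groups")
  labels <- classifySamples(meta)
  SummarizedExperiment::colData(expr)$group <- as.character(labels)
  SummarizedExperiment::colData(rbp)$group <- as.character(labels)
  tsv(data.frame(sample_id = meta$sample_id, label = as.character(labels)),
      "labels.tsv")
  manifest$counts$samples <- as.list(table(labels))

  .stageLog("filter", "low-expression filter (>", th$tpm_min, " TPM in >=",
            th$frac_min * 100, "% samples)")
  filtered <- filterLowExpression(expr, th$tpm_min, th$frac_min)
  manifest$counts$transcripts_total <- nrow(expr)
  manifest$counts$transcripts_kept <- nrow(filtered)

  cmp_name <- function(cmp) paste(cmp, collapse = "_vs_")
  groups <- as.character(labels)
  usable <- vapply(config$comparisons,
                   function(cmp) all(table(factor(groups,
                     levels = cmp))[cmp] >= 2), logical(1))
  comparisons <- config$comparisons[usable]

  .stageLog("det", "differential transcript expression")
  det <- lapply(comparisons, function(cmp) {
    d <- detTest(filtered, cmp[1], cmp[2], fc_up = th$fc_up,
                 fc_down = th$fc_down, fdr_max = th$fdr, eps = th$eps)
    tsv(d, paste0("det_", cmp_name(cmp), ".tsv"))
    d
  })
  names(det) <- vapply(comparisons, cmp_name, character(1))
  manifest$counts$det <- lapply(det, function(d) sum(d$direction != "none"))

  .stageLog("hostcorr", "transcript-host-gene correlation")
  corr <- hostGeneCorrelation(filtered, models, r_min = th$pearson_r)
  tsv(corr, "host_gene_correlation.tsv")
  efrac <- expressionFraction(filtered, models, corr)
  tsv(efrac, "expression_fraction.tsv")
  manifest$counts$correlation <- as.list(table(corr$label))

  .stageLog("events", "inferring splicing events")
  events <- inferEvents(models)
  ev <- eventTable(events)
  tsv(data.frame(event_id = ev$event_id, event_type = ev$event_type,
                 gene_id = ev$gene_id, chrom = ev$chrom, strand = ev$strand,
                 sites = vapply(ev$sites, paste, character(1), collapse = ","),
                 inclusion = vapply(ev$inclusion, paste, character(1),
                                    collapse = ","),
                 exclusion = vapply(ev$exclusion, paste, character(1),
                                    collapse = ","),
                 var_length = ev$var_length, biotype = ev$biotype,
                 intact_codon = unname(intactCodon(events))),
      "events.tsv")
  ioe <- data.frame(event_id = rep(ev$event_id,
                                   lengths(ev$inclusion) + lengths(ev$exclusion)),
                    transcript_id = unlist(mapply(c, ev$inclusion, ev$exclusion,
                                                  SIMPLIFY = FALSE)))
  tsv(ioe, "events.ioe.tsv")
  manifest$counts$events <- nrow(ev)

  .stageLog("psi", "computing PSI")
  psi <- computePsi(events, expr)
  psi_f <- filterEvents(psi, th$psi_min, th$frac_min)
  pm <- SummarizedExperiment::assay(psi_f, "psi")
  tsv(data.frame(event_id = rownames(pm), round(pm, 6), check.names = FALSE),
      "psi.tsv")
  manifest$counts$events_expressed <- nrow(psi_f)

  .stageLog("diffsplice", "differential splicing")
  ds <- lapply(comparisons, function(cmp) {
    d <- testDiffSplice(psi_f, cmp[1], cmp[2], dpsi_min = th$dpsi_min,
                        fdr_max = th$fdr)
    tsv(d, paste0("diffsplice_", cmp_name(cmp), ".tsv"))
    d
  })
  names(ds) <- names(det)
  manifest$counts$diff_events <- lapply(ds, function(d) sum(d$significant))

  .stageLog("switch", "isoform switch detection")
  ifm <- computeIF(expr, models)
  SummarizedExperiment::colData(ifm)$group <- groups
  sw <- lapply(comparisons, function(cmp) {
    s <- detectSwitches(ifm, cmp[1], cmp[2], dif_min = th$dif_min,
                        fdr_max = th$fdr)
    tsv(s, paste0("switch_", cmp_name(cmp), ".tsv"))
    g <- switchVsGeneExpression(expr, models, s, cmp[1], cmp[2],
                                groups = groups, fc_up = th$fc_up,
                                fc_down = th$fc_down, fdr_max = th$fdr,
                                eps = th$eps)
    tsv(g, paste0("switch_gene_context_", cmp_name(cmp), ".tsv"))
    list(switches = s, gene_context = g)
  })
  names(sw) <- names(det)
  manifest$counts$switch_transcripts <-
    lapply(sw, function(s) sum(s$switches$usage != "none"))

  if (all(c("control", "asymad", "ad") %in% groups)) {
    .stageLog("change20", "20% change cross-tabulation vs control")
    tw <- twentyPercentSets(filtered, "control", "asymad", "ad",
                            threshold = th$change_frac)
    tsv(as.data.frame(tw$table), "change20_table.tsv")
    tsv(tw$classes, "change20_classes.tsv")
  }

  .stageLog("rbpnet", "RBP-ASE regulatory network")
  net <- lapply(comparisons, function(cmp) {
    dsig <- ds[[cmp_name(cmp)]]
    n <- buildRbpNetwork(psi_f, rbp, events, sites,
                         diff_events = dsig$event_id[dsig$significant],
                         group_a = cmp[1], group_b = cmp[2], groups = groups,
                         rho_min = th$rho_min, window_bp = th$window_bp,
                         min_change = th$rbp_change_min,
                         gene_sets = gene_sets)
    tsv(n$edges, paste0("rbpnet_edges_", cmp_name(cmp), ".tsv"))
    tsv(n$rbp_summary, paste0("rbpnet_summary_", cmp_name(cmp), ".tsv"))
    n
  })
  names(net) <- names(det)
  manifest$counts$rbp_edges <- lapply(net, function(n) nrow(n$edges))

  .stageLog("ora", "gene-set over-representation of DET host genes")
  tx <- txTable(models)
  gene_of <- stats::setNames(tx$gene_id, tx$transcript_id)
  pc_genes <- unique(tx$gene_id[tx$biotype == "protein_coding"])
  universe <- intersect(unique(unname(gene_of[rownames(filtered)])), pc_genes)
  ora <- lapply(names(det), function(nm) {
    d <- det[[nm]]
    q <- intersect(unique(unname(
      gene_of[d$transcript_id[d$direction != "none"]])), universe)
    o <- oraTest(q, gene_sets, universe)
    tsv(o, paste0("ora_det_", nm, ".tsv"))
    o
  })
  names(ora) <- names(det)

  manifest$comparisons <- names(det)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stageLog("done", "run written to ", out_dir)
  invisible(list(dir = out_dir, manifest = manifest, labels = labels,
                 models = models, expr = expr, filtered = filtered, rbp = rbp,
                 events = events, psi = psi_f, det = det, diffsplice = ds,
                 switches = sw, network = net, ora = ora, corr = corr))
}

#' Summarise a completed pipeline run
#'
#' Reads the tables of a run directory and assembles the descriptive
#' summaries: the cross-comparison DET overlap table (shared/specific
#' up/down, including discordant cells), event-type tabulations, switch
#' usage counts and per-RBP network summaries. Missing stage outputs are
#' listed as absent rather than failing.
#'
#' @param run_dir directory produced by [runPipeline()].
#' @return list with `det_overlap`, `event_counts`, `switch_usage`,
#'   `rbp_summary`, `absent`.
#' @export
pipelineReport <- function(run_dir) {
  rd <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, check.names = FALSE)
  }
  absent <- character()
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  cmps <- unlist(manifest$comparisons)
  dets <- lapply(cmps, function(nm) rd(paste0("det_", nm, ".tsv")))
  names(dets) <- cmps
  det_overlap <- NULL
  have <- !vapply(dets, is.null, logical(1))
  if (sum(have) >= 2) {
    d1 <- dets[have][[1]]; d2 <- dets[have][[2]]
    common <- intersect(d1$transcript_id, d2$transcript_id)
    det_overlap <- table(
      factor(d1$direction[match(common, d1$transcript_id)],
             levels = c("up", "down", "none")),
      factor(d2$direction[match(common, d2$transcript_id)],
             levels = c("up", "down", "none")),
      dnn = names(dets[have])[1:2])
  } else absent <- c(absent, "det tables")
  evt <- rd("events.tsv")
  event_counts <- if (!is.null(evt))
    table(type = evt$event_type, biotype = evt$biotype)
  else { absent <- c(absent, "events.tsv"); NULL }
  switch_usage <- lapply(cmps, function(nm) {
    s <- rd(paste0("switch_", nm, ".tsv"))
    if (is.null(s)) { absent <<- c(absent, paste0("switch_", nm)); NULL }
    else table(factor(s$usage, levels = c("increased", "decreased", "none")))
  })
  names(switch_usage) <- cmps
  rbp_summary <- lapply(cmps, function(nm)
    rd(paste0("rbpnet_summary_", nm, ".tsv")))
  names(rbp_summary) <- cmps
  list(det_overlap = det_overlap, event_counts = event_counts,
       switch_usage = switch_usage, rbp_summary = rbp_summary,
       absent = absent)
}
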