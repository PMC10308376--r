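test_that("generators are deterministic under a fixed seed", {
  cfg <- simulationConfig(n_genes = 30, n_control = 8, n_asymad = 8,
                          n_ad = 8, seed = 5)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeGTF(a$models, f1); writeGTF(b$models, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(SummarizedExperiment::assay(a$expr),
                   SummarizedExperiment::assay(b$expr))
  expect_identical(SummarizedExperiment::assay(a$rbp),
                   SummarizedExperiment::assay(b$rbp))
  expect_identical(as.data.frame(a$sites), as.data.frame(b$sites))
  expect_identical(a$truth, b$truth)
  # a different seed changes the data
  c2 <- simulateCohort(simulationConfig(n_genes = 30, n_control = 8,
                                        n_asymad = 8, n_ad = 8, seed = 6))
  expect_false(identical(SummarizedExperiment::assay(a$expr),
                         SummarizedExperiment::assay(c2$expr)))
})

test_that("simulated annotation instantiates exactly the requested events", {
  cfg <- simulationConfig(n_genes = 7, n_control = 3, n_asymad = 3, n_ad = 3,
                          seed = 9)
  ann <- simulateAnnotation(cfg)
  ev <- inferEvents(ann$models)
  expect_equal(length(ev), 7L)
  expect_setequal(eventType(ev), c("SE", "A5", "A3", "MX", "RI", "AF", "AL"))
  expect_setequal(eventIds(ev), ann$templates$event_id)
  # inclusion isoforms agree with the generator's record
  evtab <- eventTable(ev)
  ord <- match(ann$templates$event_id, evtab$event_id)
  for (i in seq_len(7))
    expect_true(ann$templates$inclusion_tx[i] %in% evtab$inclusion[[ord[i]]])
  # single-isoform configuration yields no events at all
  cfg1 <- simulationConfig(n_genes = 10, transcripts_per_gene = c(1, 1),
                           n_control = 3, n_asymad = 3, n_ad = 3, seed = 9)
  expect_equal(length(inferEvents(simulateAnnotation(cfg1)$models)), 0L)
})

test_that("null configuration plants nothing", {
  cfg <- simulationConfig(n_genes = 25, n_control = 6, n_asymad = 6, n_ad = 6,
                          frac_det = 0, frac_switch = 0,
                          frac_driven_events = 0, seed = 21)
  co <- simulateCohort(cfg)
  expect_equal(lengths(co$truth[c("det_up", "det_down", "switch_up",
                                  "switch_down", "differential_events")]),
               c(det_up = 0L, det_down = 0L, switch_up = 0L,
                 switch_down = 0L, differential_events = 0L))
  expect_equal(nrow(co$truth$driver_edges), 0L)
})

test_that("planted fold changes reproduce the configured ratio at low noise", {
  cfg <- simulationConfig(n_genes = 100, n_control = 30, n_asymad = 5,
                          n_ad = 30, tpm_log_sd = 0.01, if_sd = 0.003,
                          planted_fc = 3, frac_det = 0.2, frac_switch = 0,
                          frac_driven_events = 0, seed = 33)
  co <- simulateCohort(cfg)
  m <- SummarizedExperiment::assay(co$expr)
  g <- SummarizedExperiment::colData(co$expr)$group
  ratio <- rowMeans(m[co$truth$det_up, g == "ad", drop = FALSE]) /
    rowMeans(m[co$truth$det_up, g == "control", drop = FALSE])
  expect_equal(unname(ratio), rep(3, length(ratio)), tolerance = 0.05)
  ratio_dn <- rowMeans(m[co$truth$det_down, g == "ad", drop = FALSE]) /
    rowMeans(m[co$truth$det_down, g == "control", drop = FALSE])
  expect_equal(unname(ratio_dn), rep(1 / 3, length(ratio_dn)),
               tolerance = 0.05)
})

test_that("planted switches conserve per-sample gene totals", {
  base <- list(n_genes = 40, n_control = 10, n_asymad = 10, n_ad = 10,
               frac_det = 0, frac_driven_events = 0, seed = 77)
  on <- do.call(simulationConfig, c(base, frac_switch = 0.3))
  off <- do.call(simulationConfig, c(base, frac_switch = 0))
  ann_on <- simulateAnnotation(on); ann_off <- simulateAnnotation(off)
  ex_on <- simulateExpression(ann_on, on)
  ex_off <- simulateExpression(ann_off, off)
  gene_of <- txTable(ann_on$models)$gene_id
  sum_on <- rowsum(SummarizedExperiment::assay(ex_on$expr), gene_of)
  sum_off <- rowsum(SummarizedExperiment::assay(ex_off$expr), gene_of)
  sw <- ex_on$truth$switch_genes
  expect_gt(length(sw), 0)
  expect_equal(sum_on[sw, ], sum_off[sw, ], tolerance = 1e-9)
})

test_that("metadata draws stay inside each group's defining ranges", {
  cfg <- simulationConfig(n_genes = 10, n_control = 40, n_asymad = 40,
                          n_ad = 40, seed = 55)
  ex <- simulateExpression(simulateAnnotation(cfg), cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(ex$expr))
  ctl <- cd[cd$group == "control", ]
  expect_true(all(ctl$cerad %in% 3:4 & ctl$braak %in% 0:3 & ctl$mmse >= 24))
  asy <- cd[cd$group == "asymad", ]
  expect_true(all(asy$cerad %in% 1:3 & asy$braak %in% 3:6 & asy$mmse >= 24))
  ad <- cd[cd$group == "ad", ]
  expect_true(all(ad$cerad %in% 1:2 & ad$braak %in% 3:6 & ad$mmse < 24))
  # the ambiguous overlap cell is never emitted
  expect_false(any(cd$cerad == 3 & cd$braak == 3 & cd$mmse >= 24))
  expect_equal(as.character(suppressMessages(classifySamples(cd))), cd$group)
})

test_that("driver binding lands inside windows and decoys strictly outside", {
  cfg <- simulationConfig(n_genes = 40, n_control = 10, n_asymad = 10,
                          n_ad = 10, frac_switch = 0.4,
                          frac_driven_events = 0.5, seed = 19)
  co <- simulateCohort(cfg)
  w <- cfg$binding_window_bp
  tmpl <- co$templates
  sites_of <- function(eid) tmpl$sites[[match(eid, tmpl$event_id)]]
  drv <- co$sites[mcols(co$sites)$role == "driver"]
  de <- co$truth$driver_edges
  expect_equal(length(drv), nrow(de))
  for (i in seq_along(drv)) {
    s <- sites_of(de$event_id[i])
    expect_true(any(start(drv[i]) <= s + w & end(drv[i]) >= s - w))
  }
  # every decoy of an event keeps distance > w from all its defining sites
  ev <- inferEvents(co$models)
  be <- bindingEvidence(ev, co$sites[mcols(co$sites)$role == "decoy"],
                        window_bp = w)
  expect_equal(nrow(be), 0L)
  # degenerate window: driver intervals contain a defining coordinate
  cfg0 <- simulationConfig(n_genes = 20, n_control = 5, n_asymad = 5,
                           n_ad = 5, frac_switch = 0.5,
                           frac_driven_events = 0.5, binding_window_bp = 0L,
                           seed = 19)
  co0 <- simulateCohort(cfg0)
  drv0 <- co0$sites[mcols(co0$sites)$role == "driver"]
  de0 <- co0$truth$driver_edges
  for (i in seq_along(drv0)) {
    s <- co0$templates$sites[[match(de0$event_id[i], co0$templates$event_id)]]
    expect_true(any(s >= start(drv0[i]) & s <= end(drv0[i])))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(planted_fc = 0.9), "planted_fc")
  expect_error(simulationConfig(planted_dif = 0.7), "planted_dif")
  expect_error(simulationConfig(frac_det = 1.2), "fractions")
  expect_error(simulationConfig(n_genes = 0), "positive")
})
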