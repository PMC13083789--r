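test_that("CSV event tables round-trip losslessly and deterministically", {
  tab <- simulate_events(default_sc_islet_config(seed = 4), 500,
                         timepoint = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(tab, f)
  back <- read_events(f)
  expect_equal(n_events(back), 500)
  expect_equal(channel_names(back), channel_names(tab))
  expect_equal(back$intensities, tab$intensities, tolerance = 1e-8)
  expect_equal(as.character(back$labels), as.character(tab$labels))
  expect_equal(back$timepoint, 7L)
  expect_equal(back$event_id, tab$event_id)

  # identical tables write byte-identical files
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_events(tab, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # empty and unlabeled tables
  empty <- make_table(numeric(0))
  fe <- withr::local_tempfile(fileext = ".csv")
  write_events(empty, fe)
  expect_equal(readLines(fe), "event_id,label,timepoint,CD133")
  expect_equal(n_events(read_events(fe)), 0)

  unlab <- make_table(c(1.5, 2.5))
  fu <- withr::local_tempfile(fileext = ".csv")
  write_events(unlab, fu)
  expect_null(read_events(fu)$labels)
})

test_that("malformed CSV input is rejected with the offending record named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,label,timepoint,CD133",
               "1,beta,7,2.5", "2,beta,7,-1.0"), f)
  expect_error(read_events(f), "row 2.*CD133")

  writeLines(c("id,cls,CD133", "1,beta,2.5"), f)
  expect_error(read_events(f), "malformed header")

  writeLines(c("event_id,label,timepoint,CD133", "1,weird_class,7,2.5"), f)
  expect_error(read_events(f), "weird_class")

  expect_error(read_events("/nonexistent/events.csv"), "not found")
})

test_that("the FCS reader handles float and integer list-mode layouts", {
  set.seed(8)
  m <- matrix(10^runif(60, 1, 4), ncol = 3,
              dimnames = list(NULL, c("FL1-A", "FL2-A", "FL3-A")))

  f <- withr::local_tempfile(fileext = ".fcs")
  write_synthetic_fcs(f, m, datatype = "F",
                      stain_names = c("CD133", "CD49a", "INS"))
  tab <- read_fcs(f)
  expect_equal(n_events(tab), 20)
  expect_equal(channel_names(tab), c("CD133", "CD49a", "INS"))  # $PnS wins
  expect_equal(tab$intensities[, "CD133"], m[, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_null(tab$labels)

  # big-endian doubles, names falling back to $PnN
  f2 <- withr::local_tempfile(fileext = ".fcs")
  write_synthetic_fcs(f2, m, datatype = "D", endian = "big")
  tab2 <- read_fcs(f2)
  expect_equal(channel_names(tab2), colnames(m))
  expect_equal(tab2$intensities[, 2], m[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)

  # 16-bit integer data
  mi <- matrix(sample(1:30000, 40), ncol = 2,
               dimnames = list(NULL, c("FSC-A", "SSC-A")))
  f3 <- withr::local_tempfile(fileext = ".fcs")
  write_synthetic_fcs(f3, mi, datatype = "I")
  tab3 <- read_events(f3, format = "fcs")
  expect_equal(tab3$intensities[, 1], as.numeric(mi[, 1]),
               ignore_attr = TRUE)

  # unsupported version is refused
  f4 <- withr::local_tempfile(fileext = ".fcs")
  write_synthetic_fcs(f4, m)
  raw <- readBin(f4, "raw", file.size(f4))
  raw[1:6] <- charToRaw("FCS2.0")
  writeBin(raw, f4)
  expect_error(read_fcs(f4), "FCS version")
})

test_that("gating reports serialize to JSON/TSV and round-trip their counts", {
  tab <- simulate_events(default_sc_islet_config(seed = 6), 1000,
                         timepoint = 7)

  # identity gate: composition unchanged
  rep_id <- gating_report(tab, list(gate_threshold("CD133", 1e-9)))
  expect_equal(rep_id$composition_in$fractions,
               rep_id$composition_out$fractions)

  rep_dual <- gating_report(tab, dual_sort_gates())
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep_dual, f)
  back <- read_report(f)
  expect_identical(back$n_in, rep_dual$n_in)
  expect_identical(back$n_out, rep_dual$n_out)
  expect_equal(back$composition_out$fractions,
               rep_dual$composition_out$fractions, tolerance = 1e-8)
  expect_equal(back$gates_applied, rep_dual$gates_applied)

  # TSV flattening: one row per class plus header
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep_dual, ft, format = "tsv")
  lines <- readLines(ft)
  expect_length(lines, 1 + length(cell_classes()))
  expect_match(lines[1], "^class\\t")

  # empty input: compositions serialized as null
  rep0 <- gating_report(make_table(numeric(0)), list(gate_threshold("CD133", 1)))
  f0 <- withr::local_tempfile(fileext = ".json")
  write_report(rep0, f0)
  obj <- jsonlite::fromJSON(f0)
  expect_null(obj$composition_in)
  expect_null(obj$composition_out)
})

test_that("simulation configs and gate lists round-trip through JSON", {
  cfg <- default_sc_islet_config(seed = 123)
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$weights, cfg$weights)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$channel_models$location, cfg$channel_models$location)
  expect_equal(nrow(back$drifts), nrow(cfg$drifts))

  # a round-tripped config simulates identically
  expect_identical(simulate_events(back, 200, 7)$intensities,
                   simulate_events(cfg, 200, 7)$intensities)

  gates <- c(dual_sort_gates(),
             list(gate_threshold("INS", 50, "below"),
                  gate_positive_split("GCG", cutoff = 100)))
  fg <- withr::local_tempfile(fileext = ".json")
  write_gates(gates, fg)
  gback <- read_gates(fg)
  expect_equal(length(gback), 4)
  tab <- simulate_events(cfg, 500, 7)
  expect_equal(apply_gates(tab, gback)$event_id,
               apply_gates(tab, gates)$event_id)
})
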