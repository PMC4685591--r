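# Sweep orchestration, CSV output and the schematic figure

small_policy <- survival_policy(batch_size = 20, n_keep = 5, max_batches = 200)

test_that("a small equal-rates sweep is deterministic down to the CSV bytes", {
  spec <- sweep_spec("equal_rates", rates = c(0.1, 0.5), duration = 6,
                     policy = small_policy, seed = 3)
  a <- run_equal_rates(spec)
  b <- run_equal_rates(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 2L)
  expect_true(all(is.finite(a$sd_fraction)))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_sweep_csv(a, f1); write_sweep_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the diversification grid omits cells with speciation above 0.9", {
  spec <- sweep_spec("diversification")
  expect_equal(nrow(spec$conditions), 14L)
  expect_equal(nrow(spec$skipped), 6L)
  expect_true(all(spec$conditions$S <= 0.9 + 1e-9))
  expect_true(all(spec$skipped$S > 0.9))
  expect_true(all(spec$conditions$T == 15))
  # the historically intractable D = 0.8 cell only appears on request
  hard <- sweep_spec("diversification", include_hard_cells = TRUE)
  expect_true(any(abs(hard$conditions$S - hard$conditions$E - 0.8) < 1e-9))
  expect_false(any(abs(spec$conditions$S - spec$conditions$E - 0.8) < 1e-9))
})

test_that("skipped cells are logged, not silently absent", {
  spec <- sweep_spec("diversification", extinction_rates = 0.9,
                     div_rates = c(0, 0.4), duration = 4,
                     policy = small_policy, seed = 9)
  expect_message(run_diversification(spec), "skipping 1 grid cell")
})

test_that("mode mismatches between spec and runner are refused", {
  expect_error(run_equal_rates(sweep_spec("diversification")),
               class = "crownsim_bad_spec")
  expect_error(run_diversification(sweep_spec("equal_rates")),
               class = "crownsim_bad_spec")
})

test_that("a failing condition is dropped with a diagnostic, others survive", {
  # the D = 0.6 cell explodes past a tight lineage cap; the D = 0 cell is fine
  spec <- sweep_spec("diversification", extinction_rates = 0.2,
                     div_rates = c(0, 0.6), duration = 15,
                     policy = small_policy, seed = 12, max_lineages = 2000)
  expect_message(out <- run_sweep(spec), "aborted.*lineage cap")
  expect_equal(nrow(out), 1L)
  expect_equal(out$D, 0)
  expect_equal(out$n, 5L)
})

test_that("zero extinction pins every crown fraction to the origin", {
  res <- run_condition(0.4, 0, duration = 5, policy = small_policy,
                       seed = 5, keep_records = TRUE)
  expect_identical(unique(res$records$fraction), 0)
  expect_equal(res$summary$acceptance_rate, 1)
})

test_that("per-tree records travel with the sweep when requested", {
  spec <- sweep_spec("equal_rates", rates = c(0.3), duration = 5,
                     policy = small_policy, seed = 8)
  out <- run_sweep(spec, keep_records = TRUE)
  recs <- attr(out, "records")
  expect_length(recs, nrow(out))
  expect_equal(nrow(recs[[1]]), out$n[1])
  expect_equal(mean(recs[[1]]$fraction), out$mean_fraction[1])
})

test_that("the tree figure shades exactly the crown clade", {
  f <- tempfile(fileext = ".png")
  info <- render_tree_figure(make_fixture("two_tip_extant"), f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_identical(info$crown_node, "origin")   # shading spans the whole tree

  f2 <- tempfile(fileext = ".png")
  tr <- make_fixture("one_side_extinct")
  info2 <- render_tree_figure(tr, f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
  expect_equal(info2$crown_time, 4)             # extinct subtree excluded

  expect_error(render_tree_figure(make_fixture("single_survivor"),
                                  tempfile(fileext = ".png")),
               class = "crownsim_undefined_crown")
  expect_error(render_tree_figure(tr, tempfile(fileext = ".bmp")),
               class = "crownsim_bad_figure")
})

test_that("figure annotation agrees with the crown statistics", {
  smp <- simulate_surviving(bd_params(0.5, 0.5, duration = 20, seed = 31),
                            survival_policy(batch_size = 50, n_keep = 1))
  tr <- smp$trees[[1]]
  f <- tempfile(fileext = ".pdf")
  info <- render_tree_figure(tr, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_identical(info$crown_node, crown_node(tr))
  expect_equal(info$crown_time, crown_fraction(tr)$crown_time)
})
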