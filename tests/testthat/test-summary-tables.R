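# raw and iterated molt summary tables

test_that("raw summary is additive over records", {
  recs <- bind_records(make_record(P4 = 2, P5 = 0.3, P6 = 2, id = "a"),
                       make_record(P4 = 2, P5 = 0.4, P6 = 2, id = "b"))
  tab <- raw_summary(recs, "wing")
  expect_equal(tab$locus_counts$nodal[tab$locus_counts$locus == "P5"], 2)
  expect_equal(sum(tab$locus_counts$nodal), 2)
  expect_equal(sum(tab$locus_counts$terminal), 0)
  expect_equal(sum(tab$pair_counts[, c("distal", "proximal", "ambiguous")]), 0)
  expect_equal(tab$locus_counts$n_growing[tab$locus_counts$locus == "P5"], 2)

  one <- raw_summary(make_record(P1 = 1, P2 = 1, P3 = 0.6, P4 = 2, P5 = 2,
                                 P6 = 2, P7 = 2, P8 = 2, P9 = 2, P10 = 2),
                     "wing")
  expect_equal(one$pair_counts$distal[one$pair_counts$pair == "P2/P3"], 1)
  expect_equal(one$pair_counts$distal[one$pair_counts$pair == "P3/P4"], 1)
  expect_equal(sum(one$pair_counts$distal), 2)

  empty <- raw_summary(recs[0, ], "wing")
  expect_equal(moltwave:::summary_mass(empty), 0)
  expect_equal(sum(empty$locus_counts$n_growing), 0)
})

test_that("raw summary column sums equal an independent per-record recount", {
  sim <- simulate_dataset(simulation_params(seed = 311), 100,
                          window = c(0, 800))
  recs <- sim$records
  tab <- suppressWarnings(raw_summary(recs, "wing"))
  long <- suppressWarnings(annotate_records(recs, "wing"))
  # recount from the long export
  for (loc in wing_chain()) {
    expect_equal(tab$locus_counts$nodal[tab$locus_counts$locus == loc],
                 sum(long$kind == "nodal" & long$locus_or_pair == loc))
    expect_equal(tab$locus_counts$terminal[tab$locus_counts$locus == loc],
                 sum(long$kind == "terminal" & long$locus_or_pair == loc))
    expect_equal(tab$locus_counts$n_growing[tab$locus_counts$locus == loc],
                 sum(is_active_score(recs[[loc]])))
  }
  for (j in seq_len(20)) {
    lab <- pair_label("wing", j)
    for (d in c("distal", "proximal", "ambiguous"))
      expect_equal(tab$pair_counts[j, d],
                   sum(long$kind == "pair" & long$locus_or_pair == lab &
                         long$direction == d))
  }
})

test_that("wrist scores from growing S1 move to nodal S1 on iteration", {
  # two immatures early in secondary molt: S1 growing, P1 new, S2 old
  recs <- bind_records(make_record(S2 = 2, S1 = 0.4, P1 = 1, id = "a"),
                       make_record(S2 = 2, S1 = 0.2, P1 = 1, id = "b"))
  raw <- suppressWarnings(raw_summary(recs, "wing"))
  expect_equal(raw$pair_counts$proximal[raw$pair_counts$pair == "P1/S1"], 2)
  it <- suppressWarnings(iterate_summary(raw, recs, default_series_config()))
  expect_equal(it$locus_counts$nodal[it$locus_counts$locus == "S1"], 2)
  expect_equal(sum(it$pair_counts[it$pair_counts$pair == "P1/S1",
                                  c("distal", "proximal", "ambiguous")]), 0)
  # within-series S1/S2 proximal scores stay where they are
  expect_equal(it$pair_counts$proximal[it$pair_counts$pair == "S1/S2"],
               raw$pair_counts$proximal[raw$pair_counts$pair == "S1/S2"])
  expect_equal(moltwave:::summary_mass(it), moltwave:::summary_mass(raw))
})

test_that("an ambiguous S7/S8 pair splits 0.5 terminal to each member", {
  rec <- make_record(S7 = 0.5, S8 = 0.5)
  raw <- suppressWarnings(raw_summary(rec, "wing"))
  expect_equal(raw$pair_counts$ambiguous[raw$pair_counts$pair == "S7/S8"], 1)
  it <- suppressWarnings(iterate_summary(raw, rec, default_series_config()))
  expect_equal(it$locus_counts$terminal[it$locus_counts$locus == "S7"], 0.5)
  expect_equal(it$locus_counts$terminal[it$locus_counts$locus == "S8"], 0.5)
  expect_equal(sum(it$pair_counts[it$pair_counts$pair == "S7/S8",
                                  c("distal", "proximal", "ambiguous")]), 0)
})

test_that("rectrix boundary scores reassign by the seed/terminal rules", {
  cfg <- default_series_config()
  # R5 growing, R4 old: already nodal in the raw summary (chain edge)
  raw <- raw_summary(make_record(R4 = 2, R5 = 0.3), "tail")
  expect_equal(raw$locus_counts$nodal[raw$locus_counts$locus == "R5"], 1)
  expect_equal(sum(raw$pair_counts[, c("distal", "proximal", "ambiguous")]), 0)
  # R5 growing, R4 new: raw distal pair -> terminal R5 (own series)
  rec <- make_record(R4 = 1, R5 = 0.3)
  raw <- raw_summary(rec, "tail")
  expect_equal(raw$pair_counts$distal[raw$pair_counts$pair == "R4/R5"], 1)
  it <- iterate_summary(raw, rec, cfg)
  expect_equal(it$locus_counts$terminal[it$locus_counts$locus == "R5"], 1)
  # R4 growing, R5 new, R3 old: proximal pair -> nodal R4 (fresh seed)
  rec <- make_record(R3 = 2, R4 = 0.3, R5 = 1)
  raw <- raw_summary(rec, "tail")
  expect_equal(raw$pair_counts$proximal[raw$pair_counts$pair == "R4/R5"], 1)
  it <- iterate_summary(raw, rec, cfg)
  expect_equal(it$locus_counts$nodal[it$locus_counts$locus == "R4"], 1)
  # R4 growing, R5 new, R3 unscored: still nodal (conservative)
  rec <- make_record(R4 = 0.3, R5 = 1)
  it <- suppressWarnings(iterate_summary(raw_summary(rec, "tail"), rec, cfg))
  expect_equal(it$locus_counts$nodal[it$locus_counts$locus == "R4"], 1)
  # R4 growing, R5 new, R3 growing: wave ahead -> terminal R4
  rec <- make_record(R3 = 0.5, R4 = 0.3, R5 = 1)
  it <- suppressWarnings(iterate_summary(raw_summary(rec, "tail"), rec, cfg))
  expect_equal(it$locus_counts$terminal[it$locus_counts$locus == "R4"], 1)
})

test_that("iteration conserves mass, zeroes boundaries, and is idempotent", {
  cfg <- default_series_config()
  bp <- moltwave:::boundary_pairs(cfg, "wing")
  for (seed in c(7, 19, 83)) {
    recs <- random_records(40, seed = seed)
    raw <- suppressWarnings(raw_summary(recs, "wing"))
    it <- suppressWarnings(iterate_summary(raw, recs, cfg))
    expect_equal(moltwave:::summary_mass(it), moltwave:::summary_mass(raw))
    expect_equal(sum(it$pair_counts[bp, c("distal", "proximal", "ambiguous")]),
                 0)
    expect_identical(it$locus_counts$n_growing, raw$locus_counts$n_growing)
    # counts may be half-integers but nothing else
    expect_true(all(abs(2 * it$locus_counts$nodal -
                          round(2 * it$locus_counts$nodal)) < 1e-12))
    again <- suppressWarnings(iterate_summary(it, recs, cfg))
    expect_equal(again, it)
  }
})

test_that("a table with no cross-boundary scores iterates to itself", {
  recs <- make_record(P4 = 2, P5 = 0.3, P6 = 2)
  raw <- raw_summary(recs, "wing")
  it <- iterate_summary(raw, recs, default_series_config())
  expect_identical(it$variant, "iterated")
  expect_equal(it$locus_counts, raw$locus_counts)
  expect_equal(it$pair_counts, raw$pair_counts)
})

test_that("rendering flags the predominant direction per series segment", {
  recs <- bind_records(make_record(P1 = 1, P2 = 0.5, P3 = 2, id = "a"),
                       make_record(P4 = 1, P5 = 0.5, P6 = 2, id = "b"))
  tab <- raw_summary(recs, "wing")
  r <- render_table(tab, default_series_config())
  expect_true(all(r$emphasis$direction == "distal"))
  expect_true("P1/P2" %in% r$emphasis$pair)
  # ties are not flagged
  tie <- raw_summary(bind_records(
    make_record(P1 = 1, P2 = 0.5, P3 = 2, id = "a"),
    make_record(P4 = 2, P5 = 0.5, P6 = 1, id = "b")), "wing")
  expect_equal(nrow(render_table(tie, default_series_config())$emphasis), 0)
  # all-zero table renders without emphasis
  r0 <- render_table(moltwave:::empty_molt_summary("wing"))
  expect_equal(nrow(r0$emphasis), 0)
  expect_output(print(r0), "S11")
})

test_that("summary tables round-trip through the CSV layout", {
  recs <- random_records(15, seed = 5)
  tab <- suppressWarnings(raw_summary(recs, "wing"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_molt_summary(tab, path)
  back <- read_molt_summary(path, n_records = tab$n_records)
  expect_equal(back$locus_counts, tab$locus_counts)
  expect_equal(back$pair_counts, tab$pair_counts)
  expect_identical(back$variant, "raw")
})
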