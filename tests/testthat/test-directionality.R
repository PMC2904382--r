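# nodal/terminal classification and pairwise direction scores

test_that("pair scores follow the replacement-direction rules", {
  expect_equal(score_pair(c(P1 = 1, P2 = 0.5), "P1", "P2"), "distal")
  # chain stores proximal-first by rank: S2 is proximal to S1
  expect_equal(score_pair(c(S2 = 0.3, S1 = 1), "S2", "S1"), "proximal")
  expect_equal(score_pair(c(P4 = 0.6, P5 = 0.6), "P4", "P5"), "ambiguous")
  # missing participates as a growing feather of fraction 0
  expect_equal(score_pair(c(P4 = 0.05, P5 = 0.3), "P4", "P5"), "proximal")
  expect_equal(score_pair(c(P4 = 0.05, P5 = 2), "P4", "P5"), "distal")
  expect_true(is.na(score_pair(c(P4 = 1, P5 = 2), "P4", "P5")))
  expect_warning(score_pair(c(P4 = NA, P5 = 0.3), "P4", "P5"), "unscored")
  expect_error(score_pair(c(P1 = 0.5, P3 = 1), "P1", "P3"), "not adjacent")
})

test_that("a growing feather's two neighbors map to the hand-built truth table", {
  # interior growing P5 = 0.4 against every age combination of P4 and P6;
  # growing neighbors use 0.6 (longer). Expected classification and pair
  # directions enumerated by hand from the rules.
  cases <- list(
    list(p4 = 2,   p6 = 2,   kind = "nodal",    dirs = NULL),
    list(p4 = 1,   p6 = 1,   kind = "terminal", dirs = NULL),
    list(p4 = 1,   p6 = 2,   kind = "pair", dirs = c("distal", "distal")),
    list(p4 = 2,   p6 = 1,   kind = "pair", dirs = c("proximal", "proximal")),
    list(p4 = 0.6, p6 = 2,   kind = "pair", dirs = c("distal", "distal")),
    list(p4 = 0.6, p6 = 1,   kind = "pair", dirs = c("distal", "proximal")),
    list(p4 = 2,   p6 = 0.6, kind = "pair", dirs = c("proximal", "proximal")),
    list(p4 = 1,   p6 = 0.6, kind = "pair", dirs = c("distal", "proximal")),
    list(p4 = 0.6, p6 = 0.6, kind = "pair", dirs = c("distal", "proximal"))
  )
  for (cs in cases) {
    rec <- make_record(P4 = cs$p4, P5 = 0.4, P6 = cs$p6)
    ann <- suppressWarnings(annotate_record(rec))
    if (cs$kind == "nodal") {
      expect_identical(ann$nodal, "P5")
      expect_equal(nrow(ann$pairs[ann$pairs$pair %in% c("P4/P5", "P5/P6"), ]), 0)
    } else if (cs$kind == "terminal") {
      expect_identical(ann$terminal, "P5")
      expect_equal(nrow(ann$pairs[ann$pairs$pair %in% c("P4/P5", "P5/P6"), ]), 0)
    } else {
      got <- ann$pairs$direction[match(c("P4/P5", "P5/P6"), ann$pairs$pair)]
      expect_equal(got, cs$dirs,
                   label = sprintf("P4=%s P6=%s", cs$p4, cs$p6))
    }
  }
})

test_that("edge feathers: single old neighbor is nodal, single new gives a pair", {
  ann <- annotate_record(make_record(P9 = 2, P10 = 0.3))
  expect_identical(ann$nodal, "P10")
  expect_equal(nrow(ann$pairs), 0)
  ann <- annotate_record(make_record(P9 = 1, P10 = 0.3))
  expect_length(ann$terminal, 0)  # raw edge policy: pair score, not terminal
  expect_equal(ann$pairs$direction[ann$pairs$pair == "P9/P10"], "distal")
})

test_that("spec composites: nodal wave start and a single passing wave", {
  ann <- annotate_record(make_record(P4 = 2, P5 = 0.3, P6 = 2))
  expect_identical(ann$nodal, "P5")
  expect_equal(nrow(ann$pairs), 0)

  scores <- stats::setNames(c(1, 1, 0.6, 2, 2, 2, 2, 2, 2, 2), paste0("P", 1:10))
  ann <- annotate_record(make_record(P1 = 1, P2 = 1, P3 = 0.6, P4 = 2, P5 = 2,
                                     P6 = 2, P7 = 2, P8 = 2, P9 = 2, P10 = 2))
  expect_identical(ann$pairs$pair, c("P2/P3", "P3/P4"))
  expect_identical(ann$pairs$direction, c("distal", "distal"))

  ann <- suppressWarnings(annotate_record(make_record(S2 = 2, S1 = 0.4, P1 = 1)))
  expect_identical(sort(ann$pairs$pair), c("P1/S1", "S1/S2"))
  expect_identical(unique(ann$pairs$direction), "proximal")
})

test_that("every active locus is nodal, terminal, or contributes a pair score", {
  recs <- random_records(40, seed = 101)
  for (i in seq_len(nrow(recs))) {
    s <- record_scores(recs, i, "wing")
    ann <- suppressWarnings(annotate_record(s))
    active <- names(s)[is_active_score(s)]
    for (loc in active) {
      in_pairs <- any(vapply(strsplit(ann$pairs$pair, "/"), function(p)
        loc %in% p, logical(1)))
      n_roles <- (loc %in% ann$nodal) + (loc %in% ann$terminal) +
        (loc %in% ann$unclassified) + in_pairs
      expect_true(n_roles >= 1L, label = paste("locus", loc, "record", i))
      expect_false(loc %in% ann$nodal && loc %in% ann$terminal)
    }
  }
})

test_that("one wave flanked by new and old scores one direction throughout", {
  fracs <- c(0.9, 0.6, 0.3, 0.05)
  for (len in 1:3) {
    for (start in c(2, 8, 14)) {  # varying chain offsets
      run <- fracs[seq_len(len)]  # decreasing toward the front
      ch <- wing_chain()
      vals <- c(1, run, 2)        # new behind, old ahead -> distal wave
      loci <- ch[start:(start + len + 1)]
      args <- stats::setNames(as.list(vals), loci)
      rec <- do.call(make_record, args)
      ann <- suppressWarnings(annotate_record(rec))
      expect_identical(unique(ann$pairs$direction), "distal",
                       label = sprintf("len=%d start=%d", len, start))
      # mirrored wave: old behind, new ahead -> proximal
      args <- stats::setNames(as.list(c(2, rev(run), 1)), loci)
      rec <- do.call(make_record, args)
      ann <- suppressWarnings(annotate_record(rec))
      expect_identical(unique(ann$pairs$direction), "proximal")
    }
  }
})

test_that("relabeling new and old flips single-active pair directions", {
  recs <- random_records(30, seed = 202)
  flip <- as.data.frame(recs)
  for (loc in wing_chain()) {
    v <- flip[[loc]]
    flip[[loc]] <- ifelse(!is.na(v) & v == 1, 2, ifelse(!is.na(v) & v == 2, 1, v))
  }
  flip <- as_wing_records(flip)
  for (i in seq_len(nrow(recs))) {
    s <- record_scores(recs, i, "wing")
    a1 <- suppressWarnings(annotate_record(s))
    a2 <- suppressWarnings(annotate_record(record_scores(flip, i, "wing")))
    shared <- intersect(a1$pairs$pair, a2$pairs$pair)
    for (pr in shared) {
      members <- strsplit(pr, "/", fixed = TRUE)[[1]]
      both_active <- all(is_active_score(s[members]))
      d1 <- a1$pairs$direction[a1$pairs$pair == pr]
      d2 <- a2$pairs$direction[a2$pairs$pair == pr]
      if (both_active) {
        expect_identical(d1, d2)  # length comparison: unaffected by ages
      } else if (d1 == "ambiguous") {
        expect_identical(d2, "ambiguous")
      } else {
        expect_identical(d2, setdiff(c("distal", "proximal"), d1),
                         label = paste("pair", pr, "record", i))
      }
    }
  }
  # nodal and terminal swap under the relabeling
  a1 <- annotate_record(make_record(P4 = 2, P5 = 0.3, P6 = 2))
  a2 <- annotate_record(make_record(P4 = 1, P5 = 0.3, P6 = 1))
  expect_identical(a1$nodal, a2$terminal)
})

test_that("annotation export covers all records in long form", {
  recs <- bind_records(make_record(P4 = 2, P5 = 0.3, P6 = 2, id = "a"),
                       make_record(P1 = 1, P2 = 0.5, P3 = 2, id = "b"))
  long <- annotate_records(recs, "wing")
  expect_identical(sort(unique(long$record_id)), c("a", "b"))
  expect_identical(long$kind[long$record_id == "a"], "nodal")
  expect_setequal(long$locus_or_pair[long$record_id == "b"],
                  c("P1/P2", "P2/P3"))
  empty <- annotate_records(recs[0, ], "wing")
  expect_equal(nrow(empty), 0)
})
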