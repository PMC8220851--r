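test_that("the six-motif screen calls the constructed fixture with the expected geometry", {
  out <- screen_protein("fix", fixture_alph())
  expect_s3_class(out, "screen_outcome")
  expect_equal(out$status, "alph")
  call <- out$call
  expect_equal(call$extended_count, 0L)
  expect_true(all(call$hits$flavour == "narrow"))
  expect_equal(unname(call$distances[c("d12", "d23", "d56")]), c(29L, 26L, 19L))
  expect_equal(call$hits$matched,
               c("GDVHG", "GDLVGKG", "GNHE", "HGG", "VIFGH", "LDTG"))
  # hits strictly ordered and non-overlapping
  expect_true(all(diff(call$hits$start) > 0))
  expect_true(all(call$hits$start[-1] > call$hits$end[-6]))
  # self-audit: every hit re-checks against its matrix
  mset <- alph_matrix_set()
  for (i in 1:6) {
    m <- if (call$hits$flavour[i] == "narrow") mset$narrow[[i]] else mset$extended[[i]]
    expect_true(matches_at(call$hits$matched[i], m))
  }
})

test_that("the PPP-hallmark arginine and distance violations make the screen negative", {
  r6 <- sub("GDLVGKG", "GDLVDRG", fixture_alph())
  expect_equal(screen_protein("r6", r6)$status, "negative")
  short <- sub(strrep("A", 29), strrep("A", 10), fixture_alph(), fixed = TRUE)
  expect_equal(screen_protein("short", short)$status, "negative")
})

test_that("the extended budget is enforced and counted", {
  # motif 1 as GDXHG matches only the extended matrix
  one_ext <- sub("GDVHG", "GDXHG", fixture_alph())
  out <- screen_protein("e1", one_ext)
  expect_equal(out$status, "alph")
  expect_equal(out$call$extended_count, 1L)
  expect_equal(out$call$hits$flavour[1], "extended")

  two_ext <- sub("LDTG", "LDLG", one_ext)   # motif 6 LDLG: L only in extended set
  out2 <- screen_protein("e2", two_ext)
  expect_equal(out2$status, "alph")
  expect_equal(out2$call$extended_count, 2L)

  three_ext <- sub("HGG", "HLG", two_ext)   # motif 4 position 2 L: extended only
  expect_equal(screen_protein("e3", three_ext)$status, "negative")
  expect_equal(screen_protein("e3", three_ext, extended_budget = 3L)$status, "alph")
  # budget 0 refuses even a single extended motif
  expect_equal(screen_protein("e1", one_ext, extended_budget = 0L)$status, "negative")
})

test_that("ties are broken by fewest extended motifs, then leftmost starts", {
  # a decoy extended-only motif-1 window upstream of the narrow one:
  # the narrow window must win despite being rightmost
  s <- paste0(strrep("A", 4), "GDXHG", strrep("A", 1), fixture_alph())
  out <- screen_protein("tie", s)
  expect_equal(out$status, "alph")
  expect_equal(out$call$hits$flavour[1], "narrow")
  expect_equal(out$call$hits$matched[1], "GDVHG")
  # two equally narrow motif-1 windows: leftmost feasible wins
  s2 <- paste0("GDVHG", strrep("A", 24), fixture_alph())
  out2 <- screen_protein("tie2", s2)
  expect_equal(out2$call$hits$start[1], 1L)
})

test_that("the missing-motif scan flags five-of-six proteins and only those", {
  broken6 <- sub("LDTG", "QQQQ", fixture_alph())
  out <- missing_motif_scan("t", broken6, missing = 6)
  expect_equal(out$status, "missing_one")
  expect_equal(out$missing_motif, 6L)
  expect_equal(out$truncated_terminal, "C")
  # the d56 bound is waived: same result if motif 6 region removed entirely
  trunc <- substring(fixture_alph(), 1, nchar(fixture_alph()) - 30)
  outN <- missing_motif_scan("t", trunc, missing = 6)
  expect_equal(outN$status, "missing_one")

  broken1 <- sub("GDVHG", "QQQQQ", fixture_alph())
  out1 <- missing_motif_scan("t", broken1, missing = 1)
  expect_equal(out1$truncated_terminal, "N")

  # a full ALPH is negative under the scan (the six-motif screen already wins)
  expect_equal(missing_motif_scan("t", fixture_alph(), missing = 3)$status,
               "negative")
  # a random sequence is negative for every waived motif
  set.seed(5)
  rnd <- random_aa_seq(400)
  for (k in 1:6) {
    expect_equal(missing_motif_scan("r", rnd, missing = k)$status, "negative")
  }
  expect_error(missing_motif_scan("t", fixture_alph(), missing = 7), "1..6")
})

test_that("screen equals exhaustive 6-tuple enumeration on mixed short sequences", {
  set.seed(101)
  spec <- compact_spec(30, seed = 101)
  gen <- generate_synthetic_proteome(spec)
  seqs <- c(gen$proteome$sequence,
            replicate(30, random_aa_seq(sample(50:300, 1))),
            # adversarial: fixture with decoy windows salted in
            sub("AAAAA", "AGDVHGA", fixture_alph(), fixed = TRUE))
  for (s in seqs) {
    got <- screen_protein("x", s)
    want <- oracle_screen(s)
    if (is.null(want)) {
      expect_equal(got$status, "negative")
    } else {
      expect_equal(got$status, "alph")
      expect_equal(got$call$hits$start, want$starts)
      expect_equal(got$call$extended_count, want$ext)
    }
  }
})

test_that("widening bounds or budget never turns a positive negative", {
  set.seed(33)
  spec <- compact_spec(15, seed = 33)
  gen <- generate_synthetic_proteome(spec)
  wide <- distance_constraints(bounds = list(`1_2` = c(10, 200),
                                             `2_3` = c(20, 100),
                                             `5_6` = c(10, 60)))
  for (i in seq_len(nrow(gen$proteome))) {
    s <- gen$proteome$sequence[i]
    base <- screen_protein("x", s)
    expect_equal(base$status, "alph")
    expect_equal(screen_protein("x", s, constraints = wide)$status, "alph")
    expect_equal(screen_protein("x", s, extended_budget = 4L)$status, "alph")
  }
})

test_that("both distance conventions are supported and differ by the motif length", {
  out_gap <- screen_protein("f", fixture_alph())
  s2s <- distance_constraints("start_to_start",
                              bounds = list(`1_2` = c(19, 155),
                                            `2_3` = c(32, 87),
                                            `5_6` = c(22, 45)))
  out_s2s <- screen_protein("f", fixture_alph(), constraints = s2s)
  expect_equal(out_s2s$status, "alph")
  # start-to-start = gap + upstream motif length
  expect_equal(unname(out_s2s$call$distances["d12"]),
               unname(out_gap$call$distances["d12"]) + 5L)
  expect_equal(unname(out_s2s$call$distances["d56"]),
               unname(out_gap$call$distances["d56"]) + 5L)
})

test_that("proteome screening preserves order, tallies extended usage and is deterministic", {
  spec <- compact_spec(10, n_decoy_per_class = 2, seed = 9)
  gen <- generate_synthetic_proteome(spec)
  scr <- screen_proteome(gen$proteome)
  expect_equal(scr$summary$n_records, nrow(gen$proteome))
  tab <- outcomes_table(scr)
  expect_identical(tab$protein_id, gen$proteome$record_id)
  called <- tab$protein_id[tab$status == "alph"]
  planted <- gen$truth$record_id[gen$truth$label == "alph"]
  expect_setequal(called, planted)
  # summary fractions re-derivable from the table
  pos <- tab[tab$status == "alph", ]
  expect_equal(scr$summary$frac_motifs_extended,
               sum(pos$extended_count) / (6 * nrow(pos)))
  expect_equal(scr$summary$frac_calls_extended, mean(pos$extended_count > 0))

  # byte-identical TSV on a re-run
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_table_tsv(outcomes_table(screen_proteome(gen$proteome)), f1)
  write_table_tsv(outcomes_table(screen_proteome(gen$proteome)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an empty proteome yields an empty stream and zero-count summary", {
  empty <- data.frame(record_id = character(0), description = character(0),
                      organism_name = character(0), taxon_id = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  scr <- screen_proteome(empty)
  expect_equal(scr$summary$n_records, 0L)
  expect_equal(scr$summary$n_alph, 0L)
  expect_length(scr$outcomes, 0L)
})

test_that("the multi-domain option reports a second candidate domain in notes only", {
  tandem <- paste0(fixture_alph(), strrep("A", 30), fixture_alph())
  out <- screen_protein("tandem", tandem, multi_domain = TRUE)
  expect_equal(out$status, "alph")
  expect_match(out$notes, "additional candidate ALPH domain")
  plain <- screen_protein("tandem", tandem)
  expect_length(plain$notes, 0L)
  # the call itself is identical with and without the option
  expect_equal(plain$call$hits, out$call$hits)
})
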