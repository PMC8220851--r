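narrow <- alph_matrices("narrow")
extended <- alph_matrices("extended")

test_that("printed motif strings match or mismatch the built-in matrices as expected", {
  # canonical yeast-ALPH motif strings, one per motif
  canonical <- c("GDIHG", "GDLVGKG", "GNHD", "HAG", "VFFGH", "LDTG")
  for (k in 1:6) {
    expect_true(matches_at(canonical[k], narrow[[k]]),
                info = paste("motif", k, canonical[k]))
    expect_true(matches_at(canonical[k], extended[[k]]))
  }
  # trypanosome ALPH1 / non-ALPH1 variants of motifs 1 and 6
  expect_true(matches_at("GDVHG", narrow[[1]]))
  expect_true(matches_at("IDTG", narrow[[6]]))
  expect_true(matches_at("LDSG", narrow[[6]]))
  # PPP-family variants of motifs 3 and 4 still inside the allowed sets
  expect_true(matches_at("GNHE", narrow[[3]]))
  expect_true(matches_at("HGG", narrow[[4]]))
  # arginine at motif-1 position 3 is not an allowed residue
  expect_false(matches_at("GDRHG", narrow[[1]]))
})

test_that("arginine at motif-2 position 6 is rejected in every flavour", {
  expect_false(matches_at("GDLVDRG", narrow[[2]]))
  expect_false(matches_at("GDLVDRG", extended[[2]]))
  # even the X wildcards of the extended matrix cannot readmit it
  expect_false(matches_at("GDXXXRG", extended[[2]]))
  # ... unless explicitly overridden
  custom <- motif_matrix(2, c("G", "DN", "LMIFVT", "EIVTLAC", "NSATFGVQIDHMR",
                              "KQNR", "GASHT"), "custom")
  expect_false(matches_at("GDLVDRG", custom))
  expect_true(matches_at("GDLVDRG", custom, allow_r6 = TRUE))
  expect_false("R" %in% narrow[[2]]$positions[[6]])
  expect_false("R" %in% extended[[2]]$positions[[6]])
})

test_that("every narrow set is a subset of the extended set", {
  for (k in 1:6) {
    for (p in seq_len(narrow[[k]]$length)) {
      expect_true(all(narrow[[k]]$positions[[p]] %in% extended[[k]]$positions[[p]]),
                  info = sprintf("motif %d position %d", k, p))
    }
    expect_identical(narrow[[k]]$length, extended[[k]]$length)
  }
  expect_identical(vapply(narrow, `[[`, integer(1), "length"), motif_lengths())
})

test_that("a narrow match implies an extended match", {
  set.seed(11)
  for (rep in 1:200) {
    k <- sample.int(6, 1)
    w <- paste(vapply(narrow[[k]]$positions, sample, character(1), size = 1),
               collapse = "")
    if (matches_at(w, narrow[[k]])) expect_true(matches_at(w, extended[[k]]))
  }
})

test_that("X matches only where the matrix allows the unknown-residue code", {
  expect_false(matches_at("GDXHG", narrow[[1]]))
  expect_true(matches_at("GDXHG", extended[[1]]))
  # lowercase sequences are uppercased on ingest by the scanners
  expect_true(matches_at(toupper("gdxhg"), extended[[1]]))
  # other non-standard codes never match
  for (w in c("GD*HG", "GDBHG", "GDZHG", "GDUHG", "GD-HG")) {
    expect_false(matches_at(w, extended[[1]]), info = w)
  }
})

test_that("matches_at enforces the window-length contract", {
  expect_error(matches_at("GDVH", narrow[[1]]), "length")
  expect_error(matches_at("GDVHGG", narrow[[1]]), "length")
})

test_that("find_occurrences locates all and only matching windows", {
  hits <- find_occurrences("AAGDVHGAA", narrow[[1]])
  expect_equal(hits$start, 3L)   # 1-based; window "GDVHG"
  expect_equal(hits$matched, "GDVHG")
  expect_equal(nrow(find_occurrences("", narrow[[1]])), 0L)
  expect_equal(nrow(find_occurrences("GDV", narrow[[1]])), 0L)
  two <- find_occurrences("GDVHGXXGDVHG", narrow[[1]])
  expect_equal(two$start, c(1L, 8L))
})

test_that("find_occurrences equals a window-by-window brute-force re-check", {
  set.seed(7)
  for (rep in 1:50) {
    s <- random_aa_seq(sample(10:200, 1))
    # salt with planted motifs to get non-trivial hit sets
    if (rep %% 2 == 0) {
      s <- paste0(s, "GDVHG", random_aa_seq(20), "HGG")
    }
    for (k in c(1, 4, 6)) {
      for (m in list(narrow[[k]], extended[[k]])) {
        got <- find_occurrences(s, m)$start
        expect_identical(got, oracle_occurrences(s, m))
        expect_false(anyDuplicated(got) > 0)
        expect_true(!is.unsorted(got))
      }
    }
  }
})

test_that("custom matrix configuration round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_matrix_config(alph_matrix_set(), path)
  rt <- read_matrix_config(path)
  for (k in 1:6) {
    expect_identical(rt$narrow[[k]]$positions, narrow[[k]]$positions)
    expect_identical(rt$extended[[k]]$positions, extended[[k]]$positions)
  }
  # absent config -> built-ins
  builtin <- read_matrix_config(NULL)
  expect_identical(builtin$narrow[[2]]$positions, narrow[[2]]$positions)

  # five motifs only -> schema error naming the flavour/motif problem
  lines <- readLines(path)
  writeLines(lines[!grepl("^motif6", lines)], path)
  expect_error(read_matrix_config(path), "six motifs")

  # wrong length for one motif
  write_matrix_config(alph_matrix_set(), path)
  lines <- readLines(path)
  writeLines(lines[!grepl("^motif3 narrow 4", lines)], path)
  expect_error(read_matrix_config(path), "motif 3")
})

test_that("a custom matrix can widen a single position", {
  path <- withr::local_tempfile(fileext = ".txt")
  ms <- lapply(1:6, function(k) {
    sets <- vapply(alph_matrices("narrow")[[k]]$positions, paste,
                   character(1), collapse = "")
    if (k == 2) sets[3] <- paste0(sets[3], "Y")
    motif_matrix(k, sets, "custom")
  })
  write_matrix_config(ms, path)
  custom <- read_matrix_config(path)
  expect_true(matches_at("GDYVGKG", custom$narrow[[2]]))
  expect_false(matches_at("GDYVGKG", narrow[[2]]))
  # all other positions unchanged relative to narrow
  for (k in c(1, 3:6)) {
    expect_identical(custom$narrow[[k]]$positions, narrow[[k]]$positions)
  }
})
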