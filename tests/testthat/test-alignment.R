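test_that("CIGAR/MD parsing produces exact alignment summaries", {
  # perfect alignment
  st <- parse_alignment(list(query_id = "a", cigar = "300M", md = "300"))
  expect_equal(st$identity, 1)
  expect_equal(st$gap_positions, 0)
  expect_equal(st$left_skip + st$right_skip, 0)
  expect_equal(st$aligned_columns, 300)
  # internal 2-base deletion
  st2 <- parse_alignment(list(query_id = "b", cigar = "150M2D148M",
                              md = "150^AC148"))
  expect_equal(st2$aligned_columns, 300)
  expect_equal(st2$matched, 298)
  expect_equal(st2$gap_positions, 2)
  expect_equal(st2$identity, 298 / 300)
  # soft clips at both ends contribute nothing to aligned length
  st3 <- parse_alignment(list(query_id = "c", cigar = "3S295M2S", md = "295"))
  expect_equal(st3$left_skip, 3)
  expect_equal(st3$right_skip, 2)
  expect_equal(st3$aligned_columns, 295)
  # mismatches live in the MD string
  st4 <- parse_alignment(list(query_id = "d", cigar = "100M",
                              md = "40A30C28"))
  expect_equal(st4$mismatched, 2)
  expect_equal(st4$identity, 98 / 100)
  # inconsistencies are hard errors naming the record
  expect_error(parse_alignment(list(query_id = "bad1", cigar = "100M",
                                    md = "99")), "bad1")
  expect_error(parse_alignment(list(query_id = "bad2", cigar = "50M2D50M",
                                    md = "50^A50")), "bad2")
  expect_error(parse_alignment(list(query_id = "bad3", cigar = "10M5S10M",
                                    md = "20")), "internal soft clip")
})


test_that("the stringency rule accepts and rejects at its exact boundaries", {
  cases <- accept_rule_cases()
  expect_length(cases, 20)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    out <- accept_alignment(cs[[1]])
    expect_equal(out$accept, cs[[2]], info = paste("case", i))
    if (!cs[[2]]) expect_equal(out$reason, cs[[3]], info = paste("case", i))
  }
})

test_that("accept() is monotone: worsening stats never flips reject to
           accept", {
  base <- list(aligned_columns = 300, matched = 297, mismatched = 1,
               gap_positions = 2, left_skip = 2, right_skip = 0,
               identity = 297 / 300)
  worsen <- function(st, what) {
    if (what == "mismatch") { st$matched <- st$matched - 1
      st$mismatched <- st$mismatched + 1 }
    if (what == "gap") { st$matched <- st$matched - 1
      st$gap_positions <- st$gap_positions + 1 }
    if (what == "lskip") st$left_skip <- st$left_skip + 1
    if (what == "rskip") st$right_skip <- st$right_skip + 1
    st$identity <- st$matched / st$aligned_columns
    st
  }
  for (axis in c("mismatch", "gap", "lskip", "rskip")) {
    st <- base
    prev <- accept_alignment(st)$accept
    for (step in 1:8) {
      st <- worsen(st, axis)
      cur <- accept_alignment(st)$accept
      expect_false(!prev && cur,
                   info = paste("monotonicity broken on", axis, "step", step))
      prev <- cur
    }
  }
})

test_that("local alignment matches closed-form scores on constructed
           queries", {
  ref <- tiny_ref(2, 1, seed = 17)
  refseq <- ref$sequence[1]
  L <- 200
  q <- substr(refseq, 21, 20 + L)
  rec <- local_align(q, ref[1, ])
  expect_true(rec$mapped)
  expect_equal(rec$cigar, paste0(L, "M"))
  expect_equal(rec$score, 2 * L)
  expect_equal(rec$ref_start, 21)
  # one internal substitution: one MD mismatch, score 2(L-1) - 6
  qm <- q
  substr(qm, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                  substr(q, 100, 100))[1]
  rec2 <- local_align(qm, ref[1, ])
  st2 <- parse_alignment(rec2)
  expect_equal(st2$mismatched, 1)
  expect_equal(rec2$score, 2 * (L - 1) - 6)
  # random queries against an unrelated reference stay unmapped
  set.seed(31)
  unmapped <- vapply(1:20, function(i)
    local_align(random_seq(300), ref[2, ])$mapped, logical(1))
  expect_false(any(unmapped))
  expect_error(local_align("", ref[1, ]), "empty")
})

test_that("compiled aligner agrees with the brute-force DP oracle and its
           traceback reconstructs the score", {
  set.seed(5)
  for (i in 1:150) {
    q <- random_seq(sample(5:30, 1))
    r <- random_seq(sample(10:60, 1))
    got <- ppmdiet:::.sw_align_cpp(q, r, 2, -6, -5, -3)
    expect_equal(got$score, oracle_sw_score(q, r), info = paste("pair", i))
  }
  # traceback consistency on realistic mutated amplicon queries
  set.seed(6)
  for (i in 1:40) {
    r <- random_seq(250)
    q <- substr(r, 11, 240)
    ch <- strsplit(q, "")[[1]]
    ch[sample(length(ch), 3)] <- sample(c("A", "C", "G", "T"), 3, TRUE)
    if (i %% 2 == 0) ch <- ch[-sample(length(ch), 1)]
    q <- paste(ch, collapse = "")
    a <- ppmdiet:::.sw_align_cpp(q, r, 2, -6, -5, -3)
    rec <- list(query_id = "t", cigar = a$cigar, md = a$md)
    expect_equal(score_from_record(rec), a$score, info = paste("case", i))
  }
})

test_that("best-hit mapping assigns reads deterministically with a full
           ledger", {
  ref <- tiny_ref(3, 2, seed = 23)
  # error-free read from a known species maps to it
  q <- ref$sequence[4]
  merged <- data.frame(id = "r1", seq = q, stringsAsFactors = FALSE)
  out <- map_sample(merged, ref)
  expect_equal(out$assignments$accession, ref$accession[4])
  expect_equal(out$ledger$count, c(0, 0, 1))
  # score tie between two congeners resolves to the smaller accession
  r1 <- random_seq(300)
  p <- 150
  base <- substr(r1, p, p)
  others <- setdiff(c("A", "C", "G", "T"), base)
  r2 <- r1; substr(r2, p, p) <- others[1]
  qt <- r1; substr(qt, p, p) <- others[2]   # equidistant from both
  tie_ref <- data.frame(accession = c("TIE002", "TIE001"),
                        genus = "GenusX",
                        species = c("GenusX sp01", "GenusX sp02"),
                        growth_form = "forb", native = TRUE,
                        sequence = c(r1, r2), stringsAsFactors = FALSE)
  tie <- map_sample(data.frame(id = "t", seq = qt, stringsAsFactors = FALSE),
                    tie_ref)
  expect_equal(tie$assignments$accession, "TIE001")
  expect_identical(tie$assignments$accession,
                   map_sample(data.frame(id = "t", seq = qt,
                                         stringsAsFactors = FALSE),
                              tie_ref)$assignments$accession)
  # a 7-base unalignable 5' tail trips the end-skip rule
  tail7 <- "AAAAAAA"
  ref1 <- ref[1, ]
  first_base <- substr(ref1$sequence, 1, 1)
  if (first_base == "A") tail7 <- "CCCCCCC"
  qtail <- paste0(tail7, ref1$sequence)
  out2 <- map_sample(data.frame(id = "r2", seq = qtail,
                                stringsAsFactors = FALSE), ref)
  expect_equal(out2$ledger$count[out2$ledger$stage == "rejected_by_filter"],
               1)
  expect_equal(out2$decisions$reason, "end_skip")
})

test_that("SAM records round-trip to identical stringency decisions", {
  ref <- tiny_ref(2, 2, seed = 29)
  profile <- c(Genus01 = 0.5, Genus02 = 0.5)
  reads <- generate_sample_reads(profile, ref, 60, error_rate = 0.01,
                                 seed = 41)
  pr <- process_reads(reads$pairs)
  mp <- map_sample(pr$merged, ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(mp$records, ref, sam)
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(mp$records))
  dec1 <- filter_sam_records(mp$records)
  dec2 <- filter_sam_records(back)
  expect_equal(dec2, dec1)
  expect_true(all(dec2$accepted))
  # records lacking MD: recomputed against the reference, or a named error
  lines <- readLines(sam)
  stripped <- sub("\tMD:Z:[^\t]*", "", lines)
  sam2 <- tempfile(fileext = ".sam")
  writeLines(stripped, sam2)
  expect_error(read_sam(sam2), "MD")
  back2 <- read_sam(sam2, ref = ref)
  expect_equal(back2$md, back$md)
})

test_that("stringency filtering passes low-error pipelines and fails
           high-error ones", {
  ref <- tiny_ref(3, 1, seed = 37)
  profile <- stats::setNames(rep(1 / 3, 3), unique(ref$genus))
  lo <- generate_sample_reads(profile, ref, 400, error_rate = 0.005,
                              seed = 43)
  pr <- process_reads(lo$pairs)
  mp <- map_sample(pr$merged, ref)
  expect_gte(mp$ledger$count[3] / nrow(pr$merged), 0.99)
  hi <- generate_sample_reads(profile, ref, 300, error_rate = 0.05, seed = 44)
  pr2 <- process_reads(hi$pairs)
  mp2 <- map_sample(pr2$merged, ref)
  n_all <- nrow(pr2$merged)
  expect_lt(mp2$ledger$count[3], n_all / 2)
})
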