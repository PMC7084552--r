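test_that("read_fasta normalizes case, concatenates wrapped lines, rejects non-IUPAC", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT", ">y desc", "acg", "tma"), fa)
  seqs <- read_fasta(fa)
  expect_equal(seqs$id, c("x", "y"))
  expect_equal(seqs$residues, c("acgt", "acgtma"))
  expect_equal(seqs$length, c(4L, 6L))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">z", "acqt"), bad)
  expect_error(read_fasta(bad), "non-IUPAC.*'q' at position 3")
})

test_that("write_fasta / read_fasta round-trips records, wrapped or not", {
  withr::local_seed(11)
  seqs <- tibble::tibble(
    id = paste0("s", 1:5),
    residues = vapply(sample(20:200, 5), rand_iupac_seq, character(1))
  )
  seqs$length <- nchar(seqs$residues)
  for (w in c(10L, 70L, 500L)) {
    fa <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(seqs, fa, width = w)
    expect_equal(as.data.frame(read_fasta(fa)), as.data.frame(seqs))
  }
})

test_that("expand_symbol follows the IUPAC sets", {
  expect_setequal(expand_symbol("m"), c("a", "c"))
  expect_setequal(expand_symbol("v"), c("a", "c", "g"))
  expect_equal(expand_symbol("a"), "a")
  expect_setequal(expand_symbol("N"), c("a", "c", "g", "t"))
  expect_error(expand_symbol("q"), "not an IUPAC")
  # sets are consistent with symbol multiplicities used for weighting
  expect_equal(sum(vapply(iupac_alphabet(), function(s) length(expand_symbol(s)),
                          integer(1))), 4L + 6L * 2L + 4L * 3L + 4L)
})

test_that("extract_frame uses 1-based inclusive coordinates and composes", {
  withr::local_seed(3)
  s <- rand_iupac_seq(16569, p_ambig = 0)
  frame <- extract_frame(s, 5713, 9713)
  expect_equal(nchar(frame), 4001L)
  expect_equal(extract_frame(s, 1, nchar(s)), s)
  expect_error(extract_frame(s, 9713, 5713), "start_np")
  expect_error(extract_frame("acgt", 2, 9), "exceeds length")
  # composition: frame of a frame == frame with composed coordinates
  expect_equal(extract_frame(extract_frame(s, 101, 1100), 51, 150),
               extract_frame(s, 151, 250))
  # tibble input keeps shape
  tb <- tibble::tibble(id = "x", residues = s, length = nchar(s))
  expect_equal(extract_frame(tb, 5713, 9713)$length, 4001L)
})

test_that("classify_against_reference calls mutation classes correctly", {
  self <- classify_against_reference("acgt", "acgt")
  expect_equal(nrow(self$homoplasmic), 0L)
  expect_equal(nrow(self$heteroplasmic), 0L)
  expect_equal(self$no_call_count, 0L)

  homo <- classify_against_reference("acgt", "aagt")
  expect_equal(as.data.frame(homo$homoplasmic),
               data.frame(np = 2L, ref = "a", alt = "c"))

  rep <- classify_against_reference("amgn", "acgt")
  expect_equal(as.data.frame(rep$heteroplasmic),
               data.frame(np = 2L, ref = "c", code = "m"))
  expect_equal(rep$no_call_count, 1L)
  expect_equal(rep$base_counts, c(a = 1L, c = 0L, g = 1L, t = 0L))
  expect_equal(nrow(rep$homoplasmic), 0L)

  expect_error(classify_against_reference("acg", "acgt"), "length")
  expect_error(classify_against_reference("acgt", "amgt"), "determinate")
})

test_that("classification partitions every position (property)", {
  withr::local_seed(21)
  for (rep_i in 1:25) {
    n <- sample(10:300, 1)
    ref <- rand_iupac_seq(n, p_ambig = 0)
    seq <- rand_iupac_seq(n, p_ambig = stats::runif(1, 0, 0.4))
    rp <- classify_against_reference(seq, ref)
    sc <- strsplit(seq, "")[[1]]; rc <- strsplit(ref, "")[[1]]
    matches <- sum(sc == rc)
    expect_equal(nrow(rp$homoplasmic) + nrow(rp$heteroplasmic) +
                   rp$no_call_count + matches, n)
    # base counts + no-calls + heteroplasmic symbols tally the whole length
    expect_equal(sum(rp$base_counts) + rp$no_call_count +
                   nrow(rp$heteroplasmic), n)
    # position lists are strictly increasing and disjoint
    expect_true(!is.unsorted(rp$homoplasmic$np, strictly = TRUE))
    expect_true(!is.unsorted(rp$heteroplasmic$np, strictly = TRUE))
    expect_length(intersect(rp$homoplasmic$np, rp$heteroplasmic$np), 0L)
  }
})

test_that("tidy() and glance() summarize a report consistently", {
  rp <- classify_against_reference("amgn", "acgt")
  td <- tidy(rp)
  expect_equal(td$np, 2L)
  expect_equal(td$class, "heteroplasmic")
  gl <- glance(rp)
  expect_equal(gl$heteroplasmic, 1L)
  expect_equal(gl$no_call, 1L)
  expect_equal(gl$a + gl$c + gl$g + gl$t + gl$heteroplasmic + gl$no_call,
               gl$length)
})

test_that("variant tables materialize subject sequences onto a reference", {
  ref <- "acgtacgt"
  v <- tibble::tibble(np = c(2L, 5L, 8L), symbol = c("m", "n", "A"))
  out <- apply_variants(ref, v)
  expect_equal(out, "amgtncga")
  expect_error(apply_variants(ref, tibble::tibble(np = 9, symbol = "a")),
               "out of range")
  expect_error(apply_variants(ref, tibble::tibble(np = c(2, 2), symbol = c("a", "c"))),
               "duplicate")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(v, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_variant_table(tsv)$symbol, c("m", "n", "a"))
})
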