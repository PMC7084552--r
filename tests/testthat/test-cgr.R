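test_that("position_map follows the corner convention", {
  cfg1 <- cgr_config(L = 1)
  pm <- position_map(c("c", "g", "a", "t"), cfg1)
  # default corners: c->(0,0) g->(0,1) a->(1,0) t->(1,1), reported 1-based
  expect_equal(pm$row, c(1L, 1L, 2L, 2L))
  expect_equal(pm$col, c(1L, 2L, 1L, 2L))

  # first symbol selects the coarsest quadrant: 'ca' -> row bits (0,1), col (0,0)
  pm2 <- position_map("ca", cgr_config(L = 2))
  expect_equal(c(pm2$row, pm2$col), c(0L + 1L + 1L, 0L + 0L + 1L))

  # with symbol_order = "last" the final symbol is coarsest
  pm3 <- position_map("ca", cgr_config(L = 2, symbol_order = "last"))
  expect_equal(c(pm3$row, pm3$col), c(2L + 0L + 1L, 0L + 0L + 1L))

  expect_error(position_map("m", cfg1), "determinate")
  expect_error(position_map("ac", cfg1), "length L")
})

test_that("position_map is a bijection onto the 2^L x 2^L cells", {
  for (L in 1:6) {
    cfg <- cgr_config(L = L)
    kmers <- do.call(paste0, expand.grid(rep(list(c("a", "c", "g", "t")), L)))
    pm <- position_map(kmers, cfg)
    cells <- paste(pm$row, pm$col)
    expect_equal(length(unique(cells)), 4^L)
    expect_true(all(pm$row >= 1 & pm$row <= 2^L))
    expect_true(all(pm$col >= 1 & pm$col <= 2^L))
  }
})

test_that("build_cgr counts overlapping windows", {
  m1 <- build_cgr("acgt", cgr_config(L = 1))
  expect_true(all(m1$entries == 1))
  expect_equal(m1$total_mass, 4)

  m2 <- build_cgr("aaaa", cgr_config(L = 2))
  expect_equal(sum(m2$entries != 0), 1L)
  expect_equal(max(m2$entries), 3)
  expect_equal(m2$total_mass, 3)

  # L = 1 CGR is base counting
  withr::local_seed(5)
  s <- rand_iupac_seq(500, p_ambig = 0)
  m <- build_cgr(s, cgr_config(L = 1))
  rp <- classify_against_reference(s, s)
  pm <- position_map(c("a", "c", "g", "t"), cgr_config(L = 1))
  for (i in 1:4) {
    expect_equal(m$entries[pm$row[i], pm$col[i]],
                 unname(rp$base_counts[pm$kmer[i]]))
  }

  expect_error(build_cgr("amgt", cgr_config(L = 2)), "build_cgr_weighted")
  expect_error(build_cgr("ac", cgr_config(L = 3)), "shorter")
})

test_that("expand_substring enumerates weighted determinate strings", {
  e1 <- expand_substring("tamcg")
  expect_equal(e1$strings, c("taacg", "taccg"))
  expect_equal(e1$weight, 1 / 2)

  e2 <- expand_substring("tavcgm")
  expect_equal(e2$strings, c("taacga", "taccga", "tagcga",
                             "taacgc", "taccgc", "tagcgc"))
  expect_equal(e2$weight, 1 / 6)

  e3 <- expand_substring("nn")
  expect_equal(e3$n, 16L)
  expect_equal(e3$weight, 1 / 16)
  expect_equal(sort(e3$strings),
               sort(do.call(paste0, expand.grid(c("a", "c", "g", "t"),
                                                c("a", "c", "g", "t")))))

  e4 <- expand_substring("acg")
  expect_equal(e4$strings, "acg")
  expect_equal(e4$weight, 1)
  # N * w = 1 exactly for every symbol combination
  for (s in c("mm", "vn", "bdh", "na")) {
    e <- expand_substring(s)
    expect_identical(e$n * e$weight, 1)
    expect_true(all(nchar(e$strings) == nchar(s)))
    expect_true(all(strsplit(paste(e$strings, collapse = ""), "")[[1]] %in%
                      c("a", "c", "g", "t")))
  }
})

test_that("build_cgr_weighted spreads fractional weights and conserves mass", {
  mw <- build_cgr_weighted("am", cgr_config(L = 1))
  pm <- position_map(c("a", "c"), cgr_config(L = 1))
  expect_equal(mw$entries[pm$row[1], pm$col[1]], 1.5)
  expect_equal(mw$entries[pm$row[2], pm$col[2]], 0.5)
  expect_equal(mw$total_mass, 2)

  mn <- build_cgr_weighted("nnnn", cgr_config(L = 1))
  expect_true(all(mn$entries == 1))
  expect_equal(mn$total_mass, 4)
})

test_that("weighted builder equals plain builder on determinate input", {
  withr::local_seed(9)
  for (L in c(1L, 3L, 5L)) {
    s <- rand_iupac_seq(400, p_ambig = 0)
    expect_identical(build_cgr_weighted(s, cgr_config(L = L))$entries,
                     build_cgr(s, cgr_config(L = L))$entries)
  }
})

test_that("weighted builder agrees with window-by-window oracle", {
  withr::local_seed(13)
  for (rep_i in 1:8) {
    L <- sample(1:4, 1)
    s <- rand_iupac_seq(sample(20:80, 1), p_ambig = 0.3)
    cfg <- cgr_config(L = L, symbol_order = sample(c("first", "last"), 1))
    expect_equal(build_cgr_weighted(s, cfg)$entries, naive_cgr(s, cfg),
                 tolerance = 1e-12)
  }
})

test_that("mass conservation holds for ambiguous input; n_policy = 'drop' drops n windows", {
  withr::local_seed(17)
  for (rep_i in 1:20) {
    n <- sample(10:200, 1)
    L <- sample(1:5, 1)
    if (n <= L) next
    s <- rand_iupac_seq(n, p_ambig = stats::runif(1, 0, 0.5))
    m <- build_cgr_weighted(s, cgr_config(L = L))
    expect_equal(m$total_mass, n - L + 1, tolerance = 1e-9)
  }
  # dropping n windows removes exactly the windows that contain an 'n'
  s <- "acgtnacgt"
  md <- build_cgr_weighted(s, cgr_config(L = 2, n_policy = "drop"))
  expect_equal(md$total_mass, 8 - 2)  # windows 4-5 ('tn') and 5-6 ('na') dropped
})

test_that("long uniform-random sequences give near-uniform CGR entries", {
  withr::local_seed(23)
  cv <- vapply(c(4000L, 64000L), function(n) {
    m <- build_cgr(rand_iupac_seq(n, 0), cgr_config(L = 2))
    stats::sd(m$entries) / mean(m$entries)
  }, numeric(1))
  expect_lt(cv[2], cv[1])   # coefficient of variation shrinks with length
  expect_lt(cv[2], 0.05)
})

test_that("as_tibble and TSV serialization preserve the matrix", {
  m <- build_cgr("acgtacgtt", cgr_config(L = 2))
  tb <- as_tibble(m)
  expect_equal(nrow(tb), 16L)
  expect_equal(sum(tb$mass), m$total_mass)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cgr_tsv(m, tsv)
  back <- as.matrix(utils::read.table(tsv, sep = "\t"))
  dimnames(back) <- NULL
  expect_equal(back, m$entries)
})
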