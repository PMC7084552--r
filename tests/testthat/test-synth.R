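test_that("random_reference is seed-deterministic with the requested composition", {
  expect_identical(random_reference(300, seed = 4), random_reference(300, seed = 4))
  expect_false(identical(random_reference(300, seed = 4),
                         random_reference(300, seed = 5)))
  expect_equal(random_reference(50, c(a = 1, c = 0, g = 0, t = 0), seed = 1),
               strrep("a", 50))
  # base fractions approach the target composition at genome scale
  comp <- c(a = 0.309, c = 0.313, g = 0.131, t = 0.247)
  s <- random_reference(16569, comp, seed = 2)
  counts <- table(strsplit(s, "")[[1]])[names(comp)]
  expect_true(all(abs(counts / 16569 - comp) < 0.01))
  expect_error(random_reference(10, c(a = 0.9, c = 0.2, g = 0, t = 0), seed = 1),
               "composition")
})

test_that("injected variants are recovered exactly by the classifier", {
  ref <- random_reference(16569, seed = 10)
  iv <- inject_variants(ref, 18, 12, 1009, seed = 11)
  rp <- classify_against_reference(iv$sequence, ref)
  expect_equal(nrow(rp$homoplasmic), 18L)
  expect_equal(nrow(rp$heteroplasmic), 12L)
  expect_equal(rp$no_call_count, 1009L)
  truth <- iv$truth
  expect_equal(rp$homoplasmic$np, truth$np[truth$class == "homoplasmic"])
  expect_equal(rp$heteroplasmic$np, truth$np[truth$class == "heteroplasmic"])
  expect_equal(rp$heteroplasmic$code, truth$symbol[truth$class == "heteroplasmic"])
  # heteroplasmic codes are 2-fold and contain the reference base
  for (i in which(truth$class == "heteroplasmic")) {
    bases <- expand_symbol(truth$symbol[i])
    expect_length(bases, 2L)
    expect_true(truth$ref[i] %in% bases)
  }
})

test_that("inject_variants handles edge cases", {
  ref <- random_reference(100, seed = 1)
  expect_identical(inject_variants(ref, 0, 0, 0, seed = 1)$sequence, ref)
  expect_error(inject_variants(ref, 60, 30, 30, seed = 1), "exceed")
  # hotspot concentrates all positions inside the window
  iv <- inject_variants(ref, 5, 5, 5, seed = 3, hotspot = c(40, 60))
  expect_true(all(iv$truth$np >= 40 & iv$truth$np <= 60))
  # 3-fold heteroplasmic codes when requested
  iv3 <- inject_variants(ref, 0, 10, 0, seed = 4, hetero_fold = 3)
  expect_true(all(lengths(lapply(iv3$truth$symbol, expand_symbol)) == 3L))
})

test_that("synthetic cohorts are reproducible and carry group-specific burdens", {
  spec <- cohort_spec(n_per_group = 6, sequence_length = 1000,
                      nocall_a = c(60, 20), nocall_b = c(58, 15), seed = 21)
  c1 <- synthetic_cohort(spec)
  c2 <- synthetic_cohort(spec)
  expect_identical(c1$subjects, c2$subjects)   # bit-identical given the seed
  expect_identical(c1$reference, c2$reference)
  expect_equal(nrow(c1$subjects), 12L)
  expect_equal(as.vector(table(c1$subjects$group)), c(6L, 6L))
  # every subject round-trips through the classifier
  for (i in seq_len(nrow(c1$subjects))) {
    rp <- classify_against_reference(c1$subjects$residues[i], c1$reference)
    expect_equal(nrow(rp$homoplasmic), c1$subjects$n_homo[i])
    expect_equal(nrow(rp$heteroplasmic), c1$subjects$n_hetero[i])
    expect_equal(rp$no_call_count, c1$subjects$n_nocall[i])
  }
})

test_that("cohort burden draws track the spec means at genome scale", {
  ch <- synthetic_cohort(cohort_spec(n_per_group = 15, seed = 33))
  sub <- ch$subjects
  for (g in c("case", "control")) {
    burd <- ch$subjects[sub$group == g, ]
    tgt <- if (g == "case") c(18, 12, 1009) else c(21, 10, 980)
    sds <- if (g == "case") c(8, 13, 765) else c(8, 6, 390)
    obs <- c(mean(burd$n_homo), mean(burd$n_hetero), mean(burd$n_nocall))
    # within 2 standard errors of the generating means (truncation at zero
    # biases the small-burden classes slightly upward)
    expect_true(all(abs(obs - tgt) <= pmax(2 * sds / sqrt(15), 3)))
  }
})

test_that("hotspot extra burden lands only in case subjects inside the frame", {
  ch <- synthetic_cohort(cohort_spec(
    n_per_group = 3, sequence_length = 2000, nocall_a = c(20, 5),
    nocall_b = c(20, 5), hotspot = c(500, 1500), hotspot_extra_hetero = 40,
    seed = 8))
  truth <- ch$truth
  for (id in unique(truth$subject_id)) {
    tt <- truth[truth$subject_id == id, ]
    rp <- classify_against_reference(
      ch$subjects$residues[ch$subjects$subject_id == id], ch$reference)
    expect_equal(rp$heteroplasmic$np, tt$np[tt$class == "heteroplasmic"])
  }
  n_het <- tapply(truth$class == "heteroplasmic", truth$subject_id, sum)
  base_het <- ch$subjects$n_hetero
  names(base_het) <- ch$subjects$subject_id
  extra <- n_het - base_het[names(n_het)]
  expect_true(all(extra[grep("^case", names(extra))] == 40))
  expect_true(all(extra[grep("^control", names(extra))] == 0))
})

test_that("write_cohort emits FASTA + manifest + truth that reload cleanly", {
  ch <- synthetic_cohort(cohort_spec(n_per_group = 2, sequence_length = 400,
                                     nocall_a = c(10, 3), nocall_b = c(10, 3),
                                     seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir)
  fa <- read_fasta(paths$fasta)
  expect_equal(fa$id, c("reference", ch$subjects$subject_id))
  expect_equal(fa$residues[-1], ch$subjects$residues)
  man <- read_cohort_manifest(paths$manifest, fasta_path = paths$fasta)
  expect_equal(man$residues, ch$subjects$residues)
})
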