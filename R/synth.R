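# Seeded synthetic data with the statistical structure the pipeline
# assumes: a determinate reference-like sequence, per-subject substitution
# of homoplasmic bases, 2-fold heteroplasmic IUPAC codes containing the
# reference base, and 'n' no-calls, at burdens drawn from per-group
# truncated normals. Default burdens follow the mtDNA resequencing profile
# of the study population: cases 18 +/- 8 homoplasmies, 12 +/- 13
# heteroplasmies, 1009 +/- 765 no-calls; controls 21 +/- 8, 10 +/- 6,
# 980 +/- 390. Positions are uniform unless a hotspot frame concentrates
# part of the burden, emulating a region-restricted mutation excess.

# Base composition of the human mitochondrial reference (fractions of the
# printed a/c/g/t tallies 5117/5175/2163/4089).
MT_COMPOSITION <- c(a = 5117, c = 5175, g = 2163, t = 4089) / 16544

# 2-fold IUPAC codes containing each base.
TWOFOLD_WITH <- list(a = c("m", "r", "w"), c = c("m", "s", "y"),
                     g = c("r", "s", "k"), t = c("w", "y", "k"))
THREEFOLD_WITH <- list(a = c("v", "h", "d"), c = c("v", "h", "b"),
                       g = c("v", "d", "b"), t = c("h", "d", "b"))

#' Generate a random determinate reference sequence
#'
#' @param length Sequence length (default 16569, the human mitochondrial
#'   genome size).
#' @param composition Named probabilities over a/c/g/t (default: the human
#'   mitochondrial base composition).
#' @param seed Integer seed; the sequence is reproducible given the seed.
#' @return A lowercase residue string.
#' @export
#' @examples
#' substr(random_reference(50, seed = 1), 1, 10)
random_reference <- function(length = 16569L, composition = MT_COMPOSITION,
                             seed = 1L) {
  stopifnot(length >= 1L)
  if (!setequal(names(composition), c("a", "c", "g", "t")) ||
      any(composition < 0) || abs(sum(composition) - 1) > 1e-8) {
    stop("composition must be probabilities over a, c, g, t summing to 1",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    paste(sample(names(composition), length, replace = TRUE,
                 prob = composition), collapse = "")
  })
}

#' Inject homoplasmic, heteroplasmic and no-call variants into a reference
#'
#' Distinct positions are drawn without replacement: homoplasmic sites get a
#' determinate base different from the reference, heteroplasmic sites a
#' 2-fold (or, with `hetero_fold = 3`, 3-fold) IUPAC code containing the
#' reference base (a mixed ref/alt call), and no-call sites `n`.
#'
#' @param ref Reference residue string (determinate).
#' @param n_homo,n_hetero,n_nocall Numbers of sites per class.
#' @param seed Integer seed.
#' @param hotspot Optional `c(start_np, end_np)` frame; positions for the
#'   `hotspot_fraction` of each burden are drawn inside it.
#' @param hotspot_fraction Fraction of each burden placed inside `hotspot`
#'   (default 1 when a hotspot is given).
#' @param hetero_fold 2 (default) or 3: multiplicity of heteroplasmic codes.
#' @return A list with `sequence` (mutated residue string) and `truth`, a
#'   tibble (np, ref, symbol, class) sorted by position.
#' @export
#' @examples
#' ref <- random_reference(200, seed = 1)
#' iv <- inject_variants(ref, 3, 2, 5, seed = 2)
#' iv$truth
inject_variants <- function(ref, n_homo, n_hetero, n_nocall, seed = 1L,
                            hotspot = NULL, hotspot_fraction = 1,
                            hetero_fold = 2L) {
  ref <- validate_residues(ref, id = "reference")
  len <- nchar(ref)
  n_homo <- as.integer(n_homo); n_hetero <- as.integer(n_hetero)
  n_nocall <- as.integer(n_nocall)
  stopifnot(n_homo >= 0L, n_hetero >= 0L, n_nocall >= 0L,
            hetero_fold %in% c(2L, 3L))
  total <- n_homo + n_hetero + n_nocall
  if (total > len) stop("variant counts exceed sequence length", call. = FALSE)
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("a", "c", "g", "t"))) {
    stop("reference must be determinate", call. = FALSE)
  }

  withr::with_seed(seed, {
    pool_in <- seq_len(len)
    if (!is.null(hotspot)) {
      stopifnot(length(hotspot) == 2L, hotspot[1] >= 1L, hotspot[2] <= len,
                hotspot[1] <= hotspot[2])
      inside <- seq.int(hotspot[1], hotspot[2])
      n_in <- round(hotspot_fraction * total)
      if (n_in > length(inside)) stop("hotspot too small for burden", call. = FALSE)
      pos_in <- sample(inside, n_in)
      pos_out <- sample(setdiff(seq_len(len), inside), total - n_in)
      pos <- sample(c(pos_in, pos_out))   # shuffle before class assignment
    } else {
      pos <- sample(pool_in, total)
    }
    homo_pos <- sort(pos[seq_len(n_homo)])
    het_pos <- sort(pos[n_homo + seq_len(n_hetero)])
    nc_pos <- sort(pos[n_homo + n_hetero + seq_len(n_nocall)])

    homo_alt <- vapply(homo_pos, function(p) {
      sample(setdiff(c("a", "c", "g", "t"), chars[p]), 1L)
    }, character(1))
    code_table <- if (hetero_fold == 2L) TWOFOLD_WITH else THREEFOLD_WITH
    het_code <- vapply(het_pos, function(p) {
      sample(code_table[[chars[p]]], 1L)
    }, character(1))

    truth <- dplyr::arrange(dplyr::bind_rows(
      tibble::tibble(np = homo_pos, ref = chars[homo_pos], symbol = homo_alt,
                     class = "homoplasmic"),
      tibble::tibble(np = het_pos, ref = chars[het_pos], symbol = het_code,
                     class = "heteroplasmic"),
      tibble::tibble(np = nc_pos, ref = chars[nc_pos], symbol = "n",
                     class = "no_call")
    ), .data$np)

    mutated <- chars
    mutated[truth$np] <- truth$symbol
    list(sequence = paste(mutated, collapse = ""), truth = truth)
  })
}

#' Specification of a two-group synthetic cohort
#'
#' Burden parameters are `c(mean, sd)` of a normal truncated at zero and
#' rounded to integers. Defaults reproduce the case/control mutation-burden
#' profile of mitochondrial resequencing in elderly subjects.
#'
#' @param n_per_group Subjects per group.
#' @param sequence_length Reference length (default 16569).
#' @param composition Base composition of the reference.
#' @param homoplasmy_a,heteroplasmy_a,nocall_a `c(mean, sd)` burdens for
#'   group `"case"`.
#' @param homoplasmy_b,heteroplasmy_b,nocall_b `c(mean, sd)` burdens for
#'   group `"control"`.
#' @param hotspot Optional `c(start_np, end_np)` frame for extra case-only
#'   burden.
#' @param hotspot_extra_hetero Extra heteroplasmic sites placed inside
#'   `hotspot` for each case subject (creates a region-restricted group
#'   difference; default 0).
#' @param hetero_fold Heteroplasmic code multiplicity (2 or 3).
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15L, sequence_length = 16569L,
                        composition = MT_COMPOSITION,
                        homoplasmy_a = c(18, 8), heteroplasmy_a = c(12, 13),
                        nocall_a = c(1009, 765),
                        homoplasmy_b = c(21, 8), heteroplasmy_b = c(10, 6),
                        nocall_b = c(980, 390),
                        hotspot = NULL, hotspot_extra_hetero = 0L,
                        hetero_fold = 2L, seed = 1L) {
  structure(list(
    n_per_group = as.integer(n_per_group),
    sequence_length = as.integer(sequence_length), composition = composition,
    burdens = list(
      case = list(homoplasmy = homoplasmy_a, heteroplasmy = heteroplasmy_a,
                  nocall = nocall_a),
      control = list(homoplasmy = homoplasmy_b, heteroplasmy = heteroplasmy_b,
                     nocall = nocall_b)
    ),
    hotspot = hotspot, hotspot_extra_hetero = as.integer(hotspot_extra_hetero),
    hetero_fold = as.integer(hetero_fold), seed = as.integer(seed)
  ), class = "cohort_spec")
}

draw_burden <- function(n, mean_sd, cap) {
  pmin(cap, pmax(0L, as.integer(round(stats::rnorm(n, mean_sd[1], mean_sd[2])))))
}

#' Generate a synthetic two-group cohort of IUPAC sequences
#'
#' One shared reference is drawn, then each subject receives homoplasmic,
#' heteroplasmic and no-call variants at burdens drawn from the group's
#' truncated normals. Fully deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `reference` (residue string),
#'   `subjects` (tibble: subject_id, group, n_homo, n_hetero, n_nocall,
#'   residues), and `truth` (per-variant tibble across subjects).
#' @export
#' @examples
#' ch <- synthetic_cohort(cohort_spec(n_per_group = 2, sequence_length = 300))
#' ch$subjects[, 1:5]
synthetic_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ref <- random_reference(spec$sequence_length, spec$composition,
                          seed = spec$seed)
  n <- spec$n_per_group
  groups <- rep(c("case", "control"), each = n)
  ids <- sprintf("%s_%02d", groups, c(seq_len(n), seq_len(n)))

  cap <- spec$sequence_length
  burdens <- withr::with_seed(spec$seed + 1L, {
    tibble::tibble(
      subject_id = ids, group = groups,
      n_homo = c(draw_burden(n, spec$burdens$case$homoplasmy, cap),
                 draw_burden(n, spec$burdens$control$homoplasmy, cap)),
      n_hetero = c(draw_burden(n, spec$burdens$case$heteroplasmy, cap),
                   draw_burden(n, spec$burdens$control$heteroplasmy, cap)),
      n_nocall = c(draw_burden(n, spec$burdens$case$nocall, cap),
                   draw_burden(n, spec$burdens$control$nocall, cap))
    )
  })
  # keep per-subject totals feasible
  over <- with(burdens, n_homo + n_hetero + n_nocall) > cap
  if (any(over)) stop("drawn burdens exceed sequence length", call. = FALSE)

  seqs <- character(nrow(burdens))
  truths <- vector("list", nrow(burdens))
  for (i in seq_len(nrow(burdens))) {
    base_iv <- inject_variants(
      ref, burdens$n_homo[i], burdens$n_hetero[i], burdens$n_nocall[i],
      seed = spec$seed + 100L + i, hetero_fold = spec$hetero_fold
    )
    seq_i <- base_iv$sequence
    truth_i <- base_iv$truth
    if (!is.null(spec$hotspot) && spec$hotspot_extra_hetero > 0L &&
        burdens$group[i] == "case") {
      free <- setdiff(seq.int(spec$hotspot[1], spec$hotspot[2]), truth_i$np)
      extra_pos <- withr::with_seed(spec$seed + 5000L + i,
                                    sort(sample(free, spec$hotspot_extra_hetero)))
      rc <- strsplit(ref, "", fixed = TRUE)[[1]][extra_pos]
      code_table <- if (spec$hetero_fold == 2L) TWOFOLD_WITH else THREEFOLD_WITH
      codes <- withr::with_seed(spec$seed + 6000L + i, vapply(rc, function(b) {
        sample(code_table[[b]], 1L)
      }, character(1), USE.NAMES = FALSE))
      sc <- strsplit(seq_i, "", fixed = TRUE)[[1]]
      sc[extra_pos] <- codes
      seq_i <- paste(sc, collapse = "")
      truth_i <- dplyr::arrange(dplyr::bind_rows(
        truth_i, tibble::tibble(np = extra_pos, ref = rc, symbol = codes,
                                class = "heteroplasmic")
      ), .data$np)
    }
    seqs[i] <- seq_i
    truths[[i]] <- dplyr::mutate(truth_i, subject_id = burdens$subject_id[i],
                                 .before = 1L)
  }
  structure(list(
    reference = ref,
    subjects = dplyr::mutate(burdens, residues = seqs),
    truth = dplyr::bind_rows(truths)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$subjects), " subjects, reference ",
      nchar(x$reference), " np\n", sep = "")
  print(dplyr::count(x$subjects, .data$group))
  invisible(x)
}

#' Write a synthetic cohort to FASTA + manifest + truth files
#'
#' @param cohort A [synthetic_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "cohort.fasta")
  write_fasta(tibble::tibble(id = c("reference", cohort$subjects$subject_id),
                             residues = c(cohort$reference,
                                          cohort$subjects$residues)), fasta)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$subjects[, c("subject_id", "group")], manifest,
                   row.names = FALSE)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth, dataframe = "rows")
  invisible(list(fasta = fasta, manifest = manifest, truth = truth))
}
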