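# End-to-end pipeline: (optional frame extraction) -> weighted CGR ->
# sigmoid regularization -> gliding-box lacunarity curve -> hyperbola fit,
# then cohort-level comparison, outlier exclusion and the randomized-split
# control.

#' Pipeline configuration
#'
#' Defaults are the coefficient set used for mitochondrial profiling:
#' `L = 5` (32 x 32 CGR), sigmoid `k = 7`, `sigma = 0.7`, `b_min = 3`, and
#' `b_max` half the matrix order; `b_min = 5` and `L = 6` are the documented
#' alternates.
#'
#' @param L CGR substring length.
#' @param k,sigma Sigmoid regularization parameters.
#' @param b_min,b_max Gliding-box size range; `b_max = NULL` means half the
#'   matrix order.
#' @param frame Optional `c(start_np, end_np)` coordinate frame analyzed
#'   instead of the whole sequence (e.g. `c(5713, 9713)`).
#' @param corners,symbol_order,n_policy Passed to [cgr_config()].
#' @param normalize Passed to [sigmoid_transform()].
#' @param rel_sse_max Non-hyperbolic threshold for [assess_hyperbolic()].
#' @param fence_multiplier Alpha-outlier Tukey fence multiplier.
#' @param tail,direction,test Passed to [compare_groups()].
#' @param n_repeats Randomized-split repeats (default 20).
#' @param seed Seed for the randomized-split control.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(L = 5L, k = 7, sigma = 0.7, b_min = 3L,
                            b_max = NULL, frame = NULL,
                            corners = c(c = "00", g = "01", a = "10", t = "11"),
                            symbol_order = "first", n_policy = "expand",
                            normalize = FALSE, rel_sse_max = 0.2,
                            fence_multiplier = 1.5, tail = "one",
                            direction = "greater", test = "auto",
                            n_repeats = 20L, seed = 1L) {
  cfg <- list(cgr = cgr_config(L = L, corners = corners,
                               symbol_order = symbol_order, n_policy = n_policy),
              k = k, sigma = sigma, b_min = as.integer(b_min),
              b_max = if (is.null(b_max)) NULL else as.integer(b_max),
              frame = frame, normalize = normalize, rel_sse_max = rel_sse_max,
              fence_multiplier = fence_multiplier, tail = tail,
              direction = direction, test = test,
              n_repeats = as.integer(n_repeats), seed = as.integer(seed))
  stopifnot(cfg$k > 0, cfg$sigma > 0, cfg$b_min >= 1L)
  if (!is.null(frame)) stopifnot(length(frame) == 2L, frame[1] <= frame[2])
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> L=", x$cgr$L, " k=", x$k, " sigma=", x$sigma,
      " b_min=", x$b_min, " b_max=",
      if (is.null(x$b_max)) paste0("order/2 (", 2^(x$cgr$L - 1), ")") else x$b_max,
      if (!is.null(x$frame)) paste0(" frame=", x$frame[1], "-", x$frame[2]) else "",
      "\n", sep = "")
  invisible(x)
}

#' Analyze a single sequence end to end
#'
#' Runs (optional) frame extraction, weighted CGR construction, sigmoid
#' regularization, the gliding-box lacunarity curve and the hyperbola fit.
#'
#' @param seq Residue string or one-row sequence tibble.
#' @param config A [pipeline_config()].
#' @param id Subject label.
#' @return A list of class `subject_result`: `id`, `cgr` (the `cgr_matrix`),
#'   `curve` (the `lacunarity_curve`), `fit` (the `hyperbola_fit`).
#' @export
#' @examples
#' res <- analyze_sequence(random_reference(2000, seed = 1),
#'                         pipeline_config(), id = "demo")
#' glance(res$fit)
analyze_sequence <- function(seq, config = pipeline_config(), id = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.data.frame(seq)) {
    if (is.null(id)) id <- seq$id[[1]]
    seq <- seq$residues[[1]]
  }
  if (is.null(id)) id <- "sequence"
  if (!is.null(config$frame)) {
    seq <- extract_frame(seq, config$frame[1], config$frame[2])
  }
  cgr <- build_cgr_weighted(seq, config$cgr, id = id)
  curve <- lacunarity_curve(cgr, b_min = config$b_min, b_max = config$b_max,
                            k = config$k, sigma = config$sigma,
                            normalize = config$normalize, source_id = id)
  fit <- fit_hyperbola(curve, rel_sse_max = config$rel_sse_max)
  structure(list(id = id, cgr = cgr, curve = curve, fit = fit),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat("<subject_result> ", x$id, "\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' @method glance subject_result
#' @export
glance.subject_result <- function(x, ...) {
  dplyr::mutate(glance(x$fit), id = x$id, .before = 1L)
}

#' Analyze a two-group cohort of sequences
#'
#' Runs [analyze_sequence()] per subject, flags alpha outliers and
#' non-hyperbolic fits with [exclude_alpha_outliers()], compares `beta` (and
#' `alpha`) between groups on the retained subjects, and runs the
#' randomized-split control on `beta`.
#'
#' @param subjects A data frame with columns `subject_id`, `group`, and
#'   `residues` (IUPAC residue strings), e.g. `synthetic_cohort()$subjects`
#'   or a manifest joined to [read_fasta()] output.
#' @param config A [pipeline_config()].
#' @return A list of class `cohort_analysis`: `results` (per-subject tibble
#'   with fit parameters and exclusion flags), `comparison_beta`,
#'   `comparison_alpha` (class `group_comparison`), `split_test` (class
#'   `randomized_split`), `n_excluded`, and `config`.
#' @export
analyze_cohort <- function(subjects, config = pipeline_config()) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "group", "residues") %in% names(subjects)))
  if (nrow(subjects) == 0L) stop("empty cohort", call. = FALSE)
  if (length(unique(subjects$group)) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    res <- tryCatch(
      analyze_sequence(subjects$residues[i], config,
                       id = subjects$subject_id[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(id = subjects$subject_id[i], alpha = NA_real_,
                     beta = NA_real_, gamma = NA_real_, sse = NA_real_,
                     rel_sse = NA_real_, n = NA_integer_, converged = FALSE,
                     hyperbolic = FALSE, error = conditionMessage(res))
    } else {
      dplyr::mutate(glance(res$fit), id = subjects$subject_id[i],
                    .before = 1L, error = NA_character_)
    }
  })
  results <- dplyr::bind_rows(rows)
  results <- dplyr::mutate(results, group = subjects$group, .after = "id")
  results <- exclude_alpha_outliers(results,
                                    fence_multiplier = config$fence_multiplier)
  kept <- results[!results$excluded, ]
  if (any(table(kept$group) < 3L)) {
    stop("fewer than 3 retained subjects in a group after exclusions",
         call. = FALSE)
  }
  comparison_beta <- compare_groups(kept, "beta", "group", tail = config$tail,
                                    direction = config$direction,
                                    test = config$test)
  comparison_alpha <- compare_groups(kept, "alpha", "group", tail = "two",
                                     test = config$test)
  split_test <- randomized_split_test(kept, "beta", "group",
                                      n_repeats = config$n_repeats,
                                      seed = config$seed, tail = config$tail,
                                      direction = config$direction,
                                      test = config$test)
  structure(list(results = results, comparison_beta = comparison_beta,
                 comparison_alpha = comparison_alpha, split_test = split_test,
                 n_excluded = sum(results$excluded), config = config),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> ", nrow(x$results), " subjects, ", x$n_excluded,
      " excluded\n  beta: ", x$comparison_beta$test, " ",
      x$comparison_beta$tail, "-tailed p = ",
      signif(x$comparison_beta$p_value, 3), "\n  randomized split: ",
      round(100 * x$split_test$frac_significant), "% significant\n", sep = "")
  invisible(x)
}

#' @method tidy cohort_analysis
#' @export
tidy.cohort_analysis <- function(x, ...) x$results

#' @method glance cohort_analysis
#' @export
glance.cohort_analysis <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$results), n_excluded = x$n_excluded,
    beta_test = x$comparison_beta$test, beta_p = x$comparison_beta$p_value,
    alpha_p = x$comparison_alpha$p_value,
    split_frac_significant = x$split_test$frac_significant
  )
}

#' Read a cohort manifest and attach sequences from FASTA
#'
#' @param manifest_path CSV with columns `subject_id`, `group`, and either a
#'   `fasta` column of per-subject file paths or nothing (in which case
#'   `fasta_path` must name a multi-record FASTA whose record ids match
#'   `subject_id`).
#' @param fasta_path Optional multi-record FASTA for all subjects.
#' @return Subjects tibble suitable for [analyze_cohort()]. Subjects whose
#'   file is missing are reported with a warning and dropped rather than
#'   aborting the batch.
#' @export
read_cohort_manifest <- function(manifest_path, fasta_path = NULL) {
  stopifnot(file.exists(manifest_path))
  man <- tibble::as_tibble(utils::read.csv(manifest_path,
                                           stringsAsFactors = FALSE))
  if (!all(c("subject_id", "group") %in% names(man))) {
    stop("manifest needs columns 'subject_id' and 'group'", call. = FALSE)
  }
  if (nrow(man) == 0L) stop("empty manifest", call. = FALSE)
  if (!is.null(fasta_path)) {
    fa <- read_fasta(fasta_path)
    man$residues <- fa$residues[match(man$subject_id, fa$id)]
  } else if ("fasta" %in% names(man)) {
    man$residues <- vapply(seq_len(nrow(man)), function(i) {
      if (!file.exists(man$fasta[i])) return(NA_character_)
      read_fasta(man$fasta[i])$residues[[1]]
    }, character(1))
  } else {
    stop("manifest needs a 'fasta' column or a fasta_path", call. = FALSE)
  }
  missing <- is.na(man$residues)
  if (any(missing)) {
    warning(sum(missing), " subject(s) without sequences dropped: ",
            paste(utils::head(man$subject_id[missing], 5), collapse = ", "),
            call. = FALSE)
    man <- man[!missing, ]
  }
  man
}

#' Grid calibration of the CGR/lacunarity conventions against target values
#'
#' The box-size ceiling `b_max`, the tensor orientation (`symbol_order`) and
#' raw-count normalization before the sigmoid are conventions that published
#' parameter values pin down only implicitly. Given a reference sequence and
#' target (alpha, beta) pairs for the whole sequence and/or a frame, this
#' runs the pipeline over the grid and reports each configuration's
#' deviation, so the matching convention can be frozen as the default.
#'
#' @param seq Reference residue string (e.g. the rCRS).
#' @param targets A data frame with columns `scope` ("whole" or "frame"),
#'   `alpha`, `beta`.
#' @param frame Frame coordinates used for `scope == "frame"` rows.
#' @param b_max_grid,symbol_order_grid,normalize_grid Grid axes.
#' @param config Base [pipeline_config()] supplying all other settings.
#' @return A tibble with one row per configuration and scope: fitted
#'   `alpha`/`beta`, targets, and relative deviations.
#' @export
calibrate_cgr_convention <- function(seq, targets, frame = c(5713L, 9713L),
                                     b_max_grid = 8:32,
                                     symbol_order_grid = c("first", "last"),
                                     normalize_grid = c(FALSE, TRUE),
                                     config = pipeline_config()) {
  stopifnot(is.data.frame(targets),
            all(c("scope", "alpha", "beta") %in% names(targets)))
  grid <- expand.grid(b_max = b_max_grid, symbol_order = symbol_order_grid,
                      normalize = normalize_grid, scope = unique(targets$scope),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- pipeline_config(
      L = config$cgr$L, k = config$k, sigma = config$sigma,
      b_min = config$b_min, b_max = g$b_max,
      frame = if (g$scope == "frame") frame else NULL,
      symbol_order = g$symbol_order, normalize = g$normalize,
      n_policy = config$cgr$n_policy
    )
    fit <- analyze_sequence(seq, cfg, id = paste0("calib_", i))$fit
    tg <- targets[targets$scope == g$scope, ][1, ]
    tibble::tibble(scope = g$scope, b_max = g$b_max,
                   symbol_order = g$symbol_order, normalize = g$normalize,
                   alpha = fit$alpha, beta = fit$beta,
                   target_alpha = tg$alpha, target_beta = tg$beta,
                   alpha_rel_dev = abs(fit$alpha - tg$alpha) / tg$alpha,
                   beta_rel_dev = abs(fit$beta - tg$beta) / tg$beta)
  })
  dplyr::bind_rows(rows)
}
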