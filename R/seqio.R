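# Sequence I/O and reference comparison. Sequences live in tibbles with one
# row per record: columns id, residues (lowercase IUPAC string), length.
# Coordinates are 1-based inclusive GenBank "np" positions; sequences are
# treated as linear strings (no circular wrap).

#' Read IUPAC nucleotide sequences from a FASTA file
#'
#' Records may be line-wrapped; residues are case-normalized to lowercase and
#' validated against the 15-letter IUPAC alphabet (see [iupac_alphabet()]).
#'
#' @param path Path to a FASTA file (plain text, one or more records).
#' @return A tibble with one row per record and columns `id` (header word),
#'   `residues` (lowercase sequence string) and `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "ACG", "TMA"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  residues <- vapply(seq_along(set), function(i) {
    validate_residues(as.character(set[[i]]), id = ids[i])
  }, character(1))
  tibble::tibble(id = ids, residues = residues, length = nchar(residues))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `residues`.
#' @param path Output file path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  lines <- unlist(lapply(seq_len(nrow(seqs)), function(i) {
    res <- seqs$residues[i]
    starts <- seq(1L, nchar(res), by = width)
    c(paste0(">", seqs$id[i]), substring(res, starts, pmin(starts + width - 1L, nchar(res))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Extract an inclusive coordinate frame from sequences
#'
#' Coordinates follow the 1-based inclusive GenBank nucleotide-position
#' convention, so `extract_frame(x, 5713, 9713)` returns frames of length
#' 9713 - 5713 + 1 = 4001.
#'
#' @param x A sequence tibble (as from [read_fasta()]) or a single residue
#'   string.
#' @param start_np,end_np 1-based inclusive positions, `start_np <= end_np`.
#' @return Same shape as `x`, with residues restricted to the frame.
#' @export
extract_frame <- function(x, start_np, end_np) {
  stopifnot(length(start_np) == 1L, length(end_np) == 1L)
  start_np <- as.integer(start_np); end_np <- as.integer(end_np)
  if (is.na(start_np) || is.na(end_np) || start_np < 1L || start_np > end_np) {
    stop("invalid frame: need 1 <= start_np <= end_np", call. = FALSE)
  }
  cut_one <- function(res, id) {
    if (end_np > nchar(res)) {
      stop("frame end ", end_np, " exceeds length ", nchar(res),
           " of sequence '", id, "'", call. = FALSE)
    }
    substr(res, start_np, end_np)
  }
  if (is.character(x) && length(x) == 1L) return(cut_one(x, "sequence"))
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  out <- x
  out$residues <- vapply(seq_len(nrow(x)), function(i) cut_one(x$residues[i], x$id[i]),
                         character(1))
  out$length <- nchar(out$residues)
  out
}

#' Classify a subject sequence against a determinate reference
#'
#' Position-by-position comparison of an IUPAC call sequence with a
#' determinate reference of equal length. Positions where the subject call
#' is determinate and differs from the reference are homoplasmic mutations;
#' positions carrying a 2- or 3-fold ambiguity code are heteroplasmic;
#' positions called `n` are no-calls. A reference position that is itself
#' `n` (a placeholder) is tolerated and skipped for mutation calling.
#'
#' @param seq Subject residue string (or one-row sequence tibble).
#' @param ref Reference residue string (or one-row sequence tibble) of the
#'   same length, determinate apart from tolerated `n` placeholders.
#' @param id Label used in the report (defaults to the tibble id if given).
#' @return An object of class `seq_report`: a list with `id`, `length`,
#'   `base_counts` (named count of determinate a/c/g/t calls),
#'   `no_call_count`, and tibbles `homoplasmic` (np, ref, alt) and
#'   `heteroplasmic` (np, ref, code).
#' @export
#' @examples
#' rep <- classify_against_reference("amgn", "acgt")
#' rep$heteroplasmic
#' tidy(rep)
classify_against_reference <- function(seq, ref, id = NULL) {
  pick <- function(x, what) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L, "residues" %in% names(x))
      x$residues[[1]]
    } else {
      stopifnot(is.character(x), length(x) == 1L)
      x
    }
  }
  if (is.null(id)) id <- if (is.data.frame(seq)) seq$id[[1]] else "sequence"
  s <- validate_residues(pick(seq), id = id)
  r <- validate_residues(pick(ref), id = "reference")
  if (nchar(s) != nchar(r)) {
    stop("sequence length ", nchar(s), " differs from reference length ",
         nchar(r), call. = FALSE)
  }
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  rc <- strsplit(r, "", fixed = TRUE)[[1]]
  if (any(!rc %in% c("a", "c", "g", "t", "n"))) {
    stop("reference must be determinate (ambiguity codes found)", call. = FALSE)
  }
  mult <- unname(iupac_multiplicity()[sc])
  determinate <- mult == 1L
  no_call <- sc == "n"
  hetero <- !determinate & !no_call                # 2- and 3-fold codes
  ref_known <- rc != "n"
  homo <- determinate & ref_known & sc != rc

  base_counts <- vapply(c("a", "c", "g", "t"),
                        function(b) sum(sc == b), integer(1))
  new_seq_report(
    id = id, length = length(sc), base_counts = base_counts,
    no_call_count = sum(no_call),
    homoplasmic = tibble::tibble(np = which(homo), ref = rc[homo], alt = sc[homo]),
    heteroplasmic = tibble::tibble(np = which(hetero & ref_known),
                                   ref = rc[hetero & ref_known],
                                   code = sc[hetero & ref_known])
  )
}

new_seq_report <- function(id, length, base_counts, no_call_count,
                           homoplasmic, heteroplasmic) {
  structure(list(id = id, length = length, base_counts = base_counts,
                 no_call_count = no_call_count, homoplasmic = homoplasmic,
                 heteroplasmic = heteroplasmic),
            class = "seq_report")
}

#' @export
print.seq_report <- function(x, ...) {
  cat("<seq_report> ", x$id, " (", x$length, " np)\n", sep = "")
  cat("  bases: ", paste(names(x$base_counts), x$base_counts, sep = "=",
                         collapse = " "), "\n", sep = "")
  cat("  homoplasmic: ", nrow(x$homoplasmic),
      "  heteroplasmic: ", nrow(x$heteroplasmic),
      "  no-call: ", x$no_call_count, "\n", sep = "")
  invisible(x)
}

#' Tidy a sequence report into one row per mutation
#'
#' @param x A `seq_report`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `np`, `class` (homoplasmic /
#'   heteroplasmic), `ref`, `call`, ordered by position.
#' @method tidy seq_report
#' @export
tidy.seq_report <- function(x, ...) {
  out <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$homoplasmic, call = "alt"), class = "homoplasmic"),
    dplyr::mutate(dplyr::rename(x$heteroplasmic, call = "code"), class = "heteroplasmic")
  )
  if (nrow(out) == 0L) {
    return(tibble::tibble(id = character(), np = integer(), class = character(),
                          ref = character(), call = character()))
  }
  dplyr::arrange(dplyr::mutate(out, id = x$id)[, c("id", "np", "class", "ref", "call")], .data$np)
}

#' One-row summary of a sequence report
#'
#' @param x A `seq_report`.
#' @param ... Unused.
#' @return One-row tibble with base counts and mutation burdens.
#' @method glance seq_report
#' @export
glance.seq_report <- function(x, ...) {
  tibble::tibble(id = x$id, length = x$length,
                 a = x$base_counts[["a"]], c = x$base_counts[["c"]],
                 g = x$base_counts[["g"]], t = x$base_counts[["t"]],
                 homoplasmic = nrow(x$homoplasmic),
                 heteroplasmic = nrow(x$heteroplasmic),
                 no_call = x$no_call_count)
}

#' Read a variant table (np, symbol)
#'
#' @param path TSV file with columns `np` (1-based position) and `symbol`
#'   (IUPAC call at that position).
#' @return Tibble with integer `np` and lowercase `symbol`.
#' @export
read_variant_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("np", "symbol") %in% names(df))) {
    stop("variant table needs columns 'np' and 'symbol'", call. = FALSE)
  }
  tibble::tibble(np = as.integer(df$np), symbol = tolower(as.character(df$symbol)))
}

#' Materialize a subject sequence from a reference and a variant table
#'
#' @param ref Reference residue string.
#' @param variants Data frame with columns `np` and `symbol`.
#' @return Residue string with the variants substituted.
#' @export
apply_variants <- function(ref, variants) {
  ref <- validate_residues(ref, id = "reference")
  stopifnot(is.data.frame(variants), all(c("np", "symbol") %in% names(variants)))
  np <- as.integer(variants$np)
  sym <- tolower(as.character(variants$symbol))
  if (any(np < 1L | np > nchar(ref))) stop("variant np out of range", call. = FALSE)
  if (anyDuplicated(np)) stop("duplicate variant positions", call. = FALSE)
  if (any(!sym %in% iupac_alphabet())) stop("non-IUPAC variant symbol", call. = FALSE)
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  chars[np] <- sym
  paste(chars, collapse = "")
}
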