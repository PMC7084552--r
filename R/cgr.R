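# Chaos Game Representation (CGR). An L-mer over {a,c,g,t} is mapped to one
# cell of a 2^L x 2^L matrix: each symbol contributes one row bit and one
# column bit through the corner assignment of the order-2 generator matrix,
# and the matrix of order 2^L is the L-fold tensor power of that generator.
# Ambiguity codes are handled by expanding each window into its determinate
# L-mers, each deposited with fractional weight 1/N.

#' CGR configuration
#'
#' @param L Substring length (1 to 12). The CGR matrix has order `2^L`.
#' @param corners Named character vector assigning each base to a cell of the
#'   2x2 generator, as two bits "rc" (row bit, column bit). Default is the
#'   Jeffrey-style layout c->"00", g->"01", a->"10", t->"11".
#' @param symbol_order Which end of the L-mer selects the coarsest quadrant:
#'   `"first"` (default; tensor product read left to right) or `"last"`
#'   (classical midpoint iteration).
#' @param n_policy How windows containing the no-call symbol `n` are treated
#'   by [build_cgr_weighted()]: `"expand"` (default; `n` is a 4-fold
#'   undetermined symbol) or `"drop"` (windows containing `n` contribute
#'   nothing).
#' @return An object of class `cgr_config`.
#' @export
#' @examples
#' cgr_config(L = 5)
cgr_config <- function(L = 5L,
                       corners = c(c = "00", g = "01", a = "10", t = "11"),
                       symbol_order = c("first", "last"),
                       n_policy = c("expand", "drop")) {
  L <- as.integer(L)
  stopifnot(length(L) == 1L, L >= 1L, L <= 12L)
  symbol_order <- match.arg(symbol_order)
  n_policy <- match.arg(n_policy)
  if (!setequal(names(corners), c("a", "c", "g", "t")) ||
      !setequal(unname(corners), c("00", "01", "10", "11"))) {
    stop("corners must be a bijection of a,c,g,t onto cells 00,01,10,11",
         call. = FALSE)
  }
  rbit <- cbit <- stats::setNames(rep(NA_real_, 15L), iupac_alphabet())
  for (b in c("a", "c", "g", "t")) {
    bits <- strsplit(corners[[b]], "")[[1]]
    rbit[b] <- as.numeric(bits[1]); cbit[b] <- as.numeric(bits[2])
  }
  structure(list(L = L, corners = corners[c("a", "c", "g", "t")],
                 symbol_order = symbol_order, n_policy = n_policy,
                 rbit = rbit, cbit = cbit),
            class = "cgr_config")
}

#' @export
print.cgr_config <- function(x, ...) {
  cat("<cgr_config> L=", x$L, " (order ", 2^x$L, "), symbol_order=",
      x$symbol_order, ", n_policy=", x$n_policy, "\n  corners: ",
      paste(names(x$corners), x$corners, sep = "->", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Bit significance per window position (1..L). "first": the first symbol
# carries the most significant bit (coarsest quadrant).
bit_weights <- function(config) {
  if (config$symbol_order == "first") 2^((config$L - 1L):0) else 2^(0:(config$L - 1L))
}

#' Map determinate L-mers to CGR matrix cells
#'
#' The bijection between the `4^L` determinate L-mers and the `2^L x 2^L`
#' cells: each symbol contributes its corner's row bit and column bit, in
#' the significance order set by `symbol_order`.
#'
#' @param kmers Character vector of determinate L-mers (lowercase a/c/g/t).
#' @param config A [cgr_config()] whose `L` matches `nchar(kmers)`.
#' @return A tibble with columns `kmer`, `row`, `col` (1-based indices).
#' @export
#' @examples
#' position_map(c("a", "t"), cgr_config(L = 1))
position_map <- function(kmers, config = cgr_config()) {
  stopifnot(is.character(kmers), length(kmers) >= 1L)
  kmers <- tolower(kmers)
  if (any(nchar(kmers) != config$L)) {
    stop("all k-mers must have length L = ", config$L, call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(kmers, "", fixed = TRUE), use.names = FALSE),
                  ncol = config$L, byrow = TRUE)
  if (any(!chars %in% c("a", "c", "g", "t"))) {
    stop("k-mers must be determinate (a/c/g/t); expand ambiguity codes first",
         call. = FALSE)
  }
  sig <- bit_weights(config)
  rbits <- matrix(config$rbit[chars], nrow = nrow(chars))
  cbits <- matrix(config$cbit[chars], nrow = nrow(chars))
  tibble::tibble(kmer = kmers,
                 row = as.integer(rbits %*% sig) + 1L,
                 col = as.integer(cbits %*% sig) + 1L)
}

#' Expand a window with ambiguity codes into weighted determinate L-mers
#'
#' A window containing undetermined symbols is replaced by the N determinate
#' strings obtained by resolving each symbol in turn (earlier positions vary
#' fastest), each carrying weight w = 1/N. For the window `tamcg` this gives
#' `taacg` and `taccg` with w = 1/2; for `tavcgm`, six strings with w = 1/6.
#'
#' @param s A window string over the IUPAC alphabet.
#' @return A list of class `kmer_expansion` with `source`, `strings`, `n`,
#'   and `weight` (= 1/n).
#' @export
#' @examples
#' expand_substring("tamcg")
expand_substring <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- validate_residues(s, id = "window")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  opts <- IUPAC_MAP[chars]
  n <- prod(lengths(opts))
  grid <- do.call(expand.grid, c(unname(opts),
                                 list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  strings <- do.call(paste0, grid)
  structure(list(source = s, strings = strings, n = as.integer(n), weight = 1 / n),
            class = "kmer_expansion")
}

#' @export
print.kmer_expansion <- function(x, ...) {
  cat("<kmer_expansion> '", x$source, "' -> ", x$n, " string(s), w = 1/",
      x$n, "\n  ", paste(x$strings, collapse = " "), "\n", sep = "")
  invisible(x)
}

new_cgr_matrix <- function(entries, config, source_id) {
  structure(list(entries = entries, L = config$L, config = config,
                 source_id = source_id, total_mass = sum(entries)),
            class = "cgr_matrix")
}

# Shared fast path: deposit all fully determinate windows with tabulate();
# returns the partially filled matrix plus the start indices of windows that
# still contain undetermined symbols.
cgr_core <- function(residues, config, id) {
  residues <- validate_residues(residues, id = id)
  L <- config$L
  n <- nchar(residues)
  if (n < L) {
    stop("sequence '", id, "' is shorter (", n, ") than L = ", L, call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  order_ <- 2^L
  sig <- bit_weights(config)
  n_win <- n - L + 1L

  amb <- iupac_multiplicity()[chars] > 1L
  cs <- c(0L, cumsum(amb))
  amb_in_win <- cs[seq_len(n_win) + L] - cs[seq_len(n_win)]
  det_start <- which(amb_in_win == 0L)
  amb_start <- which(amb_in_win > 0L)

  entries <- matrix(0, order_, order_)
  if (length(det_start)) {
    rows <- cols <- numeric(length(det_start))
    rb <- config$rbit; cb <- config$cbit
    for (j in seq_len(L)) {
      cj <- chars[det_start + j - 1L]
      rows <- rows + rb[cj] * sig[j]
      cols <- cols + cb[cj] * sig[j]
    }
    lin <- as.integer(rows + cols * order_ + 1)   # column-major, 1-based
    entries[] <- tabulate(lin, nbins = order_ * order_)
  }
  list(entries = entries, chars = chars, amb_start = amb_start, n_win = n_win)
}

#' Build the CGR matrix of a determinate sequence
#'
#' Every overlapping window of length `L` (unit step, no circular wrap)
#' increments its cell by one, so the total mass is `length - L + 1`.
#'
#' @param seq Residue string or one-row sequence tibble (determinate only;
#'   use [build_cgr_weighted()] for sequences with ambiguity codes).
#' @param config A [cgr_config()].
#' @param id Provenance label.
#' @return An object of class `cgr_matrix`: list with `entries`
#'   (`2^L x 2^L` matrix), `L`, `config`, `source_id`, `total_mass`.
#' @export
#' @examples
#' m <- build_cgr("acgtacgt", cgr_config(L = 2))
#' m$total_mass
build_cgr <- function(seq, config = cgr_config(), id = NULL) {
  if (is.data.frame(seq)) {
    if (is.null(id)) id <- seq$id[[1]]
    seq <- seq$residues[[1]]
  }
  if (is.null(id)) id <- "sequence"
  core <- cgr_core(seq, config, id)
  if (length(core$amb_start)) {
    stop("sequence '", id, "' contains undetermined symbols at ",
         length(core$amb_start), " window(s); use build_cgr_weighted()",
         call. = FALSE)
  }
  new_cgr_matrix(core$entries, config, id)
}

#' Build the CGR matrix of a sequence with undetermined symbols
#'
#' Windows made of determinate bases increment their cell by one; a window
#' containing ambiguity codes or no-calls is expanded into its N determinate
#' L-mers (see [expand_substring()]) and each generated L-mer's cell receives
#' weight 1/N, so every window still deposits total mass 1 and the matrix
#' mass equals `length - L + 1`. With `n_policy = "drop"` windows containing
#' `n` are skipped instead. On determinate input the result equals
#' [build_cgr()] exactly.
#'
#' @inheritParams build_cgr
#' @return A `cgr_matrix`.
#' @export
#' @examples
#' m <- build_cgr_weighted("am", cgr_config(L = 1))
#' m$entries
build_cgr_weighted <- function(seq, config = cgr_config(), id = NULL) {
  if (is.data.frame(seq)) {
    if (is.null(id)) id <- seq$id[[1]]
    seq <- seq$residues[[1]]
  }
  if (is.null(id)) id <- "sequence"
  core <- cgr_core(seq, config, id)
  entries <- core$entries
  L <- config$L
  order_ <- 2^L
  sig <- bit_weights(config)
  rb <- config$rbit; cb <- config$cbit

  starts <- core$amb_start
  if (config$n_policy == "drop" && length(starts)) {
    has_n <- vapply(starts, function(i) {
      any(core$chars[i:(i + L - 1L)] == "n")
    }, logical(1))
    starts <- starts[!has_n]
  }
  if (length(starts)) {
    lin_all <- vector("list", length(starts))
    w_all <- numeric(length(starts))
    for (k in seq_along(starts)) {
      i <- starts[k]
      opts <- IUPAC_MAP[core$chars[i:(i + L - 1L)]]
      N <- prod(lengths(opts))
      grid <- as.matrix(do.call(expand.grid,
                                c(unname(opts),
                                  list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))))
      rows <- matrix(rb[grid], nrow = N) %*% sig
      cols <- matrix(cb[grid], nrow = N) %*% sig
      lin_all[[k]] <- as.integer(rows + cols * order_ + 1)
      w_all[k] <- 1 / N
    }
    w_vec <- rep.int(w_all, lengths(lin_all))
    dep <- rowsum(w_vec, unlist(lin_all))
    idx <- as.integer(rownames(dep))
    entries[idx] <- entries[idx] + dep[, 1L]
  }
  new_cgr_matrix(entries, config, id)
}

#' @export
print.cgr_matrix <- function(x, ...) {
  cat("<cgr_matrix> ", x$source_id, ": order ", 2^x$L, " (L=", x$L,
      "), total mass ", format(x$total_mass), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble cgr_matrix
#' @export
as_tibble.cgr_matrix <- function(x, ...) {
  order_ <- 2^x$L
  tibble::tibble(row = rep(seq_len(order_), times = order_),
                 col = rep(seq_len(order_), each = order_),
                 mass = as.vector(x$entries))
}

#' Plot a CGR matrix as a gray-scale image
#'
#' @param object A `cgr_matrix`.
#' @param ... Unused.
#' @return A ggplot object (dark cells = high L-mer frequency).
#' @method autoplot cgr_matrix
#' @export
autoplot.cgr_matrix <- function(object, ...) {
  df <- as_tibble.cgr_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$source_id,
                  subtitle = paste0("CGR, L = ", object$L),
                  x = NULL, y = NULL, fill = "mass") +
    ggplot2::theme_minimal()
}

#' Write a CGR matrix as dense TSV
#'
#' @param x A `cgr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgr_tsv <- function(x, path) {
  stopifnot(inherits(x, "cgr_matrix"))
  utils::write.table(x$entries, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
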