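digit_vector <- function(residues, policy = "strict") {
  strtoi(strsplit(encode_seq(residues, policy = policy), "")[[1]], base = 10L)
}

#' Chemical similarity of two aligned residue blocks
#'
#' Percentage of aligned positions whose residues belong to the same chemical
#' group: `(m / L) * 100` where `m` counts positionwise group matches and `L`
#' is the common block length. The comparison is strictly ungapped and
#' symmetric, and equals 100 exactly when the two blocks have identical
#' digit-string encodings.
#'
#' @param block_a,block_b Residue strings of equal, positive length.
#'   Vectorized over pairs (vectors are recycled to a common length).
#' @return Numeric vector of percentages in `[0, 100]` (exact rationals, not
#'   rounded).
#' @examples
#' aligned_percent("DRSMYI", "EKTCWV") # 100: every position same group
#' aligned_percent("QRSMYI", "DRSMYI") # 83.33...: 5 of 6 positions
#' @export
aligned_percent <- function(block_a, block_b) {
  stopifnot(is.character(block_a), is.character(block_b))
  n <- max(length(block_a), length(block_b))
  block_a <- rep_len(block_a, n)
  block_b <- rep_len(block_b, n)
  if (any(!nchar(block_a)) || any(nchar(block_a) != nchar(block_b))) {
    rlang::abort("Blocks must be non-empty and of equal length.",
                 class = "chemotif_domain_error")
  }
  da <- encode_seq(block_a)
  db <- encode_seq(block_b)
  vapply(seq_len(n), function(i) {
    a <- strsplit(da[i], "")[[1]]
    b <- strsplit(db[i], "")[[1]]
    100 * sum(a == b) / length(a)
  }, numeric(1))
}

#' Raw amino-acid identity of two aligned blocks
#'
#' Ungapped percentage of positions with the *identical* residue, the
#' conventional counterpart of [aligned_percent()]: chemically conserved
#' blocks often show far lower raw identity than chemical similarity.
#'
#' @inheritParams aligned_percent
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' residue_identity("QIRCNAVI", "QLRCNGVL") # 62.5
#' @export
residue_identity <- function(block_a, block_b) {
  stopifnot(is.character(block_a), is.character(block_b))
  n <- max(length(block_a), length(block_b))
  block_a <- toupper(rep_len(block_a, n))
  block_b <- toupper(rep_len(block_b, n))
  if (any(!nchar(block_a)) || any(nchar(block_a) != nchar(block_b))) {
    rlang::abort("Blocks must be non-empty and of equal length.",
                 class = "chemotif_domain_error")
  }
  vapply(seq_len(n), function(i) {
    a <- strsplit(block_a[i], "")[[1]]
    b <- strsplit(block_b[i], "")[[1]]
    100 * sum(a == b) / length(a)
  }, numeric(1))
}

#' Best chemical match of a block against a full sequence
#'
#' Slides a window of the block's length `L` along the target one position at
#' a time, scoring each window by the number `m` of positions whose residues
#' share a chemical group with the block, and reports the best percentage
#' `(m / L) * 100` together with *every* window position achieving it.
#'
#' @param block A residue string (the query block).
#' @param target A residue string, or a one-row slice of a sequence table.
#' @param target_id Label for the target in the report.
#' @return A `chem_scan` object: fields `query_block`, `target_id`, `L`,
#'   `best_percent`, `hits` (tibble of `position`, `residue_block`,
#'   `matches`) and `percents`, the full per-window similarity profile. See
#'   [tidy.chem_scan()] and [autoplot.chem_scan()].
#' @examples
#' scan_best("DR", "RDRE")
#' @export
scan_best <- function(block, target, target_id = "target") {
  if (is.data.frame(target)) {
    check_seq_table(target)
    stopifnot(nrow(target) == 1L)
    target_id <- target$seq_id
    target <- target$residues
  }
  stopifnot(is.character(block), length(block) == 1L,
            is.character(target), length(target) == 1L)
  L <- nchar(block)
  n <- nchar(target)
  if (L < 1L || L > n) {
    rlang::abort("Block length must be positive and not exceed the target length.",
                 class = "chemotif_domain_error")
  }
  bd <- digit_vector(block)
  td <- digit_vector(target, policy = "mask")
  starts <- seq_len(n - L + 1L)
  m <- vapply(starts, function(p) sum(bd == td[p:(p + L - 1L)]), integer(1))
  best <- max(m)
  pos <- starts[m == best]
  structure(list(
    query_block = block,
    target_id = target_id,
    L = L,
    best_percent = 100 * best / L,
    hits = tibble::tibble(
      position = pos,
      residue_block = substring(target, pos, pos + L - 1L),
      matches = rep(best, length(pos))
    ),
    percents = 100 * m / L
  ), class = "chem_scan")
}

#' @export
print.chem_scan <- function(x, ...) {
  cat(sprintf("<chem_scan> block '%s' (L = %d) vs %s\n",
              x$query_block, x$L, x$target_id))
  cat(sprintf("  best chemical similarity: %.2f%% at %d position(s): %s\n",
              x$best_percent, nrow(x$hits),
              paste(utils::head(x$hits$position, 8), collapse = ", ")))
  invisible(x)
}

#' Tidy a block-scan result into its hit table
#'
#' @param x A `chem_scan` object.
#' @param ... Unused.
#' @return A tibble with one row per best-scoring window: `query_block`,
#'   `target_id`, `position`, `residue_block`, `matches`, `percent`.
#' @export
tidy.chem_scan <- function(x, ...) {
  x$hits |>
    dplyr::mutate(query_block = x$query_block, target_id = x$target_id,
                  .before = 1) |>
    dplyr::mutate(percent = x$best_percent)
}

#' One-row summary of a block-scan result
#'
#' @param x A `chem_scan` object.
#' @param ... Unused.
#' @return A one-row tibble: `query_block`, `target_id`, `L`,
#'   `best_percent`, `n_hits`, `n_windows`.
#' @export
glance.chem_scan <- function(x, ...) {
  tibble::tibble(query_block = x$query_block, target_id = x$target_id,
                 L = x$L, best_percent = x$best_percent,
                 n_hits = nrow(x$hits), n_windows = length(x$percents))
}

#' Similarity profile of a block scan along the target
#'
#' @param object A `chem_scan` object.
#' @param ... Unused.
#' @return A ggplot of per-window chemical similarity with the best-scoring
#'   positions marked.
#' @export
autoplot.chem_scan <- function(object, ...) {
  prof <- tibble::tibble(position = seq_along(object$percents),
                         percent = object$percents)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$percent)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(prof, .data$percent == object$best_percent),
                        colour = "firebrick") +
    ggplot2::labs(x = "window start (aa)", y = "chemical similarity (%)",
                  title = sprintf("'%s' vs %s (best %.2f%%)",
                                  object$query_block, object$target_id,
                                  object$best_percent)) +
    ggplot2::theme_minimal()
}

#' Best-match report of query blocks against a sequence set
#'
#' Scans every block against every sequence with [scan_best()] and tabulates
#' the best chemical-similarity percentage per pair, with the first
#' best-scoring position rendered `"position-residues"`. A block longer than
#' a target is reported as a failed pair (`NA` percent with a note), not an
#' error.
#'
#' @param data A sequence table (`seq_id`, `residues`).
#' @param blocks Residue blocks: a character vector (optionally named), or a
#'   data frame with columns `block_id` and `block`.
#' @return A tibble with one row per (block, sequence) pair: `block_id`,
#'   `block`, `seq_id`, `best_percent`, `n_hits`, `position`,
#'   `residue_block`, `rendered`, `note`.
#' @examples
#' tibble::tibble(seq_id = "t", residues = "RDRE") |>
#'   scan_blocks("DR")
#' @export
scan_blocks <- function(data, blocks) {
  check_seq_table(data)
  if (is.data.frame(blocks)) {
    stopifnot(all(c("block_id", "block") %in% names(blocks)))
    btbl <- tibble::as_tibble(blocks[c("block_id", "block")])
  } else {
    stopifnot(is.character(blocks))
    ids <- names(blocks)
    if (is.null(ids)) ids <- paste0("block", seq_along(blocks))
    btbl <- tibble::tibble(block_id = ids, block = unname(blocks))
  }
  tidyr::expand_grid(btbl, seq_id = data$seq_id) |>
    dplyr::left_join(data[c("seq_id", "residues")], by = "seq_id") |>
    purrr::pmap_dfr(function(block_id, block, seq_id, residues) {
      base <- tibble::tibble(block_id = block_id, block = block,
                             seq_id = seq_id)
      if (nchar(block) > nchar(residues)) {
        return(dplyr::mutate(base, best_percent = NA_real_,
                             n_hits = 0L, position = NA_integer_,
                             residue_block = NA_character_,
                             rendered = NA_character_,
                             note = "block longer than target"))
      }
      s <- scan_best(block, residues, target_id = seq_id)
      dplyr::mutate(base,
                    best_percent = s$best_percent,
                    n_hits = nrow(s$hits),
                    position = s$hits$position[1],
                    residue_block = s$hits$residue_block[1],
                    rendered = paste0(s$hits$position[1], "-",
                                      s$hits$residue_block[1]),
                    note = NA_character_)
    })
}
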