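# all L-mers of a digit string that do not span a mask break ('0')
kmer_set <- function(digits, L) {
  n <- nchar(digits)
  if (L < 1L || L > n) return(character(0))
  k <- substring(digits, 1:(n - L + 1L), L:n)
  unique(k[!stringr::str_detect(k, "0")])
}

# intersection of per-sequence L-mer sets
common_kmers <- function(digit_strings, L) {
  sets <- lapply(digit_strings, kmer_set, L = L)
  Reduce(intersect, sets)
}

has_distinct_digits <- function(patterns) {
  vapply(strsplit(patterns, ""), function(d) !anyDuplicated(d), logical(1))
}

#' All chemical-group patterns of length L without repetition
#'
#' Enumerates every digit string of length `L` over `'1'`--`'8'` whose digits
#' are pairwise distinct, in lexicographic order. There are
#' `8!/(8-L)!` of them; by pigeonhole none exist for `L > 8`.
#'
#' @param L Pattern length, 1--8.
#' @return Character vector of digit strings.
#' @examples
#' length(norepeat_patterns(2)) # 56
#' @export
norepeat_patterns <- function(L) {
  if (length(L) != 1L || is.na(L) || L != as.integer(L) || L < 1L || L > 8L) {
    rlang::abort(
      "`L` must be a single integer in 1..8 (no repetition-free pattern can be longer than 8).",
      class = "chemotif_domain_error")
  }
  pats <- as.character(1:8)
  if (L > 1L) {
    for (len in 2:L) {
      pats <- unlist(lapply(pats, function(p) {
        used <- strsplit(p, "")[[1]]
        paste0(p, setdiff(as.character(1:8), used))
      }))
    }
  }
  sort(pats)
}

new_chem_patterns <- function(L, mode, patterns, hits) {
  structure(list(L = L, mode = mode,
                 patterns = sort(patterns), hits = hits),
            class = "chem_patterns")
}

empty_hits <- function() {
  tibble::tibble(pattern = character(), seq_id = character(),
                 position = integer(), residue_block = character())
}

#' Chemical-group patterns common to every sequence of a set
#'
#' Finds every digit pattern of length `L` that occurs as a contiguous
#' substring of the encoding of *every* sequence in `data`, together with all
#' (1-based, possibly overlapping) hit positions. `mode = "norepeat"`
#' restricts to patterns whose group digits are pairwise distinct
#' (`L <= 8`); `mode = "repeat"` allows any digits.
#'
#' The result is defined as the intersection of the per-sequence L-mer sets
#' filtered by the mode's constraint, whatever the search strategy.
#' `method = "intersect"` computes that intersection directly;
#' `method = "grow"` reproduces the published search strategies —
#' enumerate-and-test over all repetition-free patterns for `norepeat`, and
#' seeded tetramer growth with pruning for `repeat` — and always returns the
#' same set.
#'
#' @param data A sequence table (`seq_id`, `residues`, optional `digits`).
#' @param L Pattern length (`>= 2` per the published procedure; `L = 1` is
#'   also accepted). An `L` longer than the shortest sequence yields an empty
#'   result, not an error.
#' @param mode `"norepeat"` or `"repeat"`.
#' @param method Search strategy, `"intersect"` (default) or `"grow"`.
#' @return A `chem_patterns` object: fields `L`, `mode`, `patterns` (sorted
#'   digit strings) and `hits`, a tibble with one row per occurrence
#'   (`pattern`, `seq_id`, `position`, `residue_block`), ordered by pattern,
#'   then input sequence order, then position. See [tidy.chem_patterns()].
#' @examples
#' tibble::tibble(seq_id = c("a", "b"), residues = c("DRS", "ADRS")) |>
#'   common_patterns(L = 3)
#' @export
common_patterns <- function(data, L, mode = c("norepeat", "repeat"),
                            method = c("intersect", "grow")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (length(L) != 1L || is.na(L) || L != as.integer(L) || L < 1L) {
    rlang::abort("`L` must be a single positive integer.",
                 class = "chemotif_domain_error")
  }
  L <- as.integer(L)
  if (mode == "norepeat" && L > 8L) {
    rlang::abort("No repetition-free pattern can be longer than 8 groups.",
                 class = "chemotif_domain_error")
  }
  data <- ensure_digits(data)
  if (!nrow(data)) {
    rlang::abort("`data` must contain at least one sequence.",
                 class = "chemotif_domain_error")
  }

  pats <- switch(method,
    intersect = {
      found <- common_kmers(data$digits, L)
      if (mode == "norepeat") found[has_distinct_digits(found)] else found
    },
    grow = if (mode == "norepeat") {
      cand <- norepeat_patterns(L)
      present_all <- rep(TRUE, length(cand))
      for (dig in data$digits) {
        present_all <- present_all & cand %in% kmer_set(dig, L)
      }
      cand[present_all]
    } else {
      grow_repeat_patterns(data$digits, L)
    }
  )
  build_pattern_result(data, L, mode, pats)
}

# Seeded tetramer growth for repeat-mode patterns: survivors of the 4-mer
# search are concatenated in tetramer-sized rounds (the terminal tetramer of
# any common k-mer is itself common, so common tetramers are a sufficient
# extension set), a remainder of r positions is added one digit at a time,
# and candidates absent from any sequence are pruned after every round.
grow_repeat_patterns <- function(digit_strings, L) {
  if (L < 4L) {
    return(common_kmers(digit_strings, L))
  }
  tetra <- common_kmers(digit_strings, 4L)
  if (!length(tetra)) return(character(0))
  q <- L %/% 4L
  r <- L %% 4L
  cand <- tetra
  len <- 4L
  if (q > 1L) {
    for (round in seq_len(q - 1L)) {
      cand <- as.vector(outer(cand, tetra, paste0))
      len <- len + 4L
      cand <- intersect(cand, common_kmers(digit_strings, len))
      if (!length(cand)) return(character(0))
    }
  }
  for (step in seq_len(r)) {
    cand <- as.vector(outer(cand, as.character(1:8), paste0))
    len <- len + 1L
    cand <- intersect(cand, common_kmers(digit_strings, len))
    if (!length(cand)) return(character(0))
  }
  cand
}

# assemble a chem_patterns object with every hit of every selected pattern
build_pattern_result <- function(data, L, mode, pats) {
  pats <- sort(pats)
  hits <- if (length(pats)) {
    purrr::map_dfr(pats, function(p) {
      locate_pattern(data, p) |> dplyr::mutate(pattern = p, .before = 1)
    })
  } else {
    empty_hits()
  }
  new_chem_patterns(L, mode, pats, hits)
}

#' Locate all occurrences of a digit pattern in each sequence
#'
#' Scans each sequence's digit-string encoding for `pattern` and reports
#' every 1-based start position, overlapping occurrences included, with the
#' amino-acid block found there.
#'
#' @inheritParams common_patterns
#' @param pattern A non-empty digit string over `'1'`--`'8'`.
#' @return A tibble with columns `seq_id`, `position`, `residue_block`,
#'   ordered by input sequence order then position. Sequences without a match
#'   contribute no rows.
#' @examples
#' tibble::tibble(seq_id = "s", residues = "ADRSDRS") |>
#'   locate_pattern("127")
#' @export
locate_pattern <- function(data, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nchar(pattern) ||
      !grepl("^[1-8]+$", pattern)) {
    rlang::abort("`pattern` must be a non-empty digit string over '1'-'8'.",
                 class = "chemotif_domain_error")
  }
  data <- ensure_digits(data)
  Lp <- nchar(pattern)
  purrr::map2_dfr(data$seq_id, seq_len(nrow(data)), function(id, i) {
    dig <- data$digits[i]
    # lookahead keeps overlapping occurrences
    pos <- gregexpr(sprintf("(?=%s)", pattern), dig, perl = TRUE)[[1]]
    pos <- as.integer(pos[pos > 0L])
    if (!length(pos)) return(empty_hits()[, -1])
    tibble::tibble(
      seq_id = id,
      position = pos,
      residue_block = substring(data$residues[i], pos, pos + Lp - 1L)
    )
  })
}

#' Longest chemical-group pattern common to all sequences
#'
#' Searches for the largest length `L_max` at which at least one pattern is
#' shared by every sequence, and returns the full common set at that length.
#' Because the length-`L` prefix of any common length-`(L+1)` pattern is
#' itself common, the search grows candidates one digit at a time from
#' `L = 1` and stops as soon as extension fails, which guarantees all longer
#' lengths are empty. `mode = "norepeat"` caps the search at `L = 8`.
#'
#' @inheritParams common_patterns
#' @return A `chem_patterns` object at `L = L_max`; when not even a single
#'   group is shared the result has `L = 0` and no patterns.
#' @examples
#' tibble::tibble(seq_id = "s", residues = "DRSMYI") |>
#'   maximal_common_patterns() # the sequence's own encoding, L = 6
#' @export
maximal_common_patterns <- function(data, mode = c("norepeat", "repeat")) {
  mode <- match.arg(mode)
  data <- ensure_digits(data)
  if (!nrow(data)) {
    rlang::abort("`data` must contain at least one sequence.",
                 class = "chemotif_domain_error")
  }
  cap <- min(nchar(data$digits))
  if (mode == "norepeat") cap <- min(cap, 8L)

  filter_mode <- function(p) if (mode == "norepeat") p[has_distinct_digits(p)] else p
  best <- character(0)
  best_L <- 0L
  cand <- filter_mode(common_kmers(data$digits, 1L))
  L <- 1L
  while (length(cand) && L <= cap) {
    best <- cand
    best_L <- L
    if (L == cap) break
    ext <- as.vector(outer(cand, as.character(1:8), paste0))
    ext <- filter_mode(ext)
    cand <- intersect(ext, common_kmers(data$digits, L + 1L))
    L <- L + 1L
  }
  build_pattern_result(data, best_L, mode, best)
}

#' Partition common patterns into all-shared and subgroup-specific sets
#'
#' Splits the sequence set into two subgroups (for example non-muscle vs
#' muscle myosins) and classifies every length-`L` pattern that is common to
#' at least one subgroup: `common` patterns occur in every sequence of both
#' subgroups, `a_only` patterns are common to every member of subgroup A but
#' not to every member of subgroup B, and symmetrically for `b_only`. The
#' three sets are pairwise disjoint by construction.
#'
#' @inheritParams common_patterns
#' @param ids_a,ids_b Character vectors of `seq_id`s forming a partition of
#'   `data$seq_id` (disjoint, union = all ids).
#' @return A tibble with columns `pattern`, `L`, `mode` and `set`
#'   (`"common"`, `"a_only"` or `"b_only"`), patterns sorted within set.
#' @export
classify_patterns <- function(data, ids_a, ids_b, L,
                              mode = c("norepeat", "repeat")) {
  mode <- match.arg(mode)
  data <- ensure_digits(data)
  ids_a <- as.character(ids_a)
  ids_b <- as.character(ids_b)
  if (length(intersect(ids_a, ids_b)) ||
      !setequal(c(ids_a, ids_b), data$seq_id) ||
      !length(ids_a) || !length(ids_b)) {
    rlang::abort("`ids_a` and `ids_b` must be disjoint, non-empty, and together cover every seq_id.",
                 class = "chemotif_domain_error")
  }
  pats_of <- function(ids) {
    common_patterns(data[data$seq_id %in% ids, , drop = FALSE], L, mode)$patterns
  }
  pa <- pats_of(ids_a)
  pb <- pats_of(ids_b)
  dplyr::bind_rows(
    tibble::tibble(pattern = sort(intersect(pa, pb)), set = "common"),
    tibble::tibble(pattern = sort(setdiff(pa, pb)), set = "a_only"),
    tibble::tibble(pattern = sort(setdiff(pb, pa)), set = "b_only")
  ) |>
    dplyr::mutate(L = L, mode = mode, .after = "pattern")
}

#' @export
print.chem_patterns <- function(x, ...) {
  cat(sprintf("<chem_patterns> %d pattern(s) of length %d (mode: %s)\n",
              length(x$patterns), x$L, x$mode))
  if (length(x$patterns)) {
    show <- utils::head(x$patterns, 10)
    cat("  ", paste(show, collapse = " "),
        if (length(x$patterns) > 10) "..." else "", "\n")
    cat(sprintf("  %d hit(s) across %d sequence(s)\n",
                nrow(x$hits), dplyr::n_distinct(x$hits$seq_id)))
  }
  invisible(x)
}

#' Tidy a common-pattern result into its hit table
#'
#' @param x A `chem_patterns` object.
#' @param ... Unused.
#' @return A tibble with one row per occurrence: `pattern`, `L`, `mode`,
#'   `seq_id`, `position`, `residue_block`.
#' @export
tidy.chem_patterns <- function(x, ...) {
  x$hits |> dplyr::mutate(L = x$L, mode = x$mode, .after = "pattern")
}

#' One-row summary of a common-pattern result
#'
#' @param x A `chem_patterns` object.
#' @param ... Unused.
#' @return A one-row tibble: `L`, `mode`, `n_patterns`, `n_hits`,
#'   `n_sequences`.
#' @export
glance.chem_patterns <- function(x, ...) {
  tibble::tibble(L = x$L, mode = x$mode,
                 n_patterns = length(x$patterns),
                 n_hits = nrow(x$hits),
                 n_sequences = dplyr::n_distinct(x$hits$seq_id))
}

#' Map of common-pattern hit positions across sequences
#'
#' @param object A `chem_patterns` object.
#' @param ... Unused.
#' @return A ggplot showing, for each sequence, where each common pattern
#'   occurs along the chain.
#' @export
autoplot.chem_patterns <- function(object, ...) {
  hits <- object$hits
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$position, y = .data$seq_id,
                                     colour = .data$pattern)) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "position (aa)", y = NULL, colour = "pattern",
                  title = sprintf("Common chemical patterns (L = %d, %s)",
                                  object$L, object$mode)) +
    ggplot2::theme_minimal()
}
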