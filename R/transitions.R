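#' 8x8 chemical-group transition matrix of one sequence
#'
#' Reads the encoded sequence left to right and counts every adjacent ordered
#' pair: cell (i, j) is the number of positions where a group-i residue is
#' immediately followed by a group-j residue. The cell total equals
#' `length - 1` (0 for empty or single-residue sequences).
#'
#' @param x A single residue string, or a digit string if `encoded = TRUE`.
#' @param encoded Is `x` already a digit string over `'0'`--`'8'`? Defaults to
#'   auto-detection (residue strings never consist solely of digits).
#' @param policy Passed to [encode_seq()] when `x` needs encoding.
#' @return An 8x8 integer matrix with dimnames `G1`..`G8`. Masked positions
#'   (digit `'0'`) start or end no counted pair.
#' @examples
#' transition_matrix("DRSMYI")
#' @export
transition_matrix <- function(x, encoded = grepl("^[0-8]*$", x),
                              policy = "strict") {
  stopifnot(is.character(x), length(x) == 1L)
  dig <- if (encoded) x else encode_seq(x, policy = policy)
  v <- strtoi(strsplit(dig, "")[[1]], base = 10L)
  lab <- paste0("G", 1:8)
  m <- matrix(0L, 8, 8, dimnames = list(from = lab, to = lab))
  if (length(v) >= 2L) {
    a <- v[-length(v)]
    b <- v[-1L]
    keep <- a > 0L & b > 0L # pairs never span a mask break
    tab <- table(factor(a[keep], levels = 1:8), factor(b[keep], levels = 1:8))
    m[] <- as.integer(tab)
  }
  m
}

#' Transition counts for a table of sequences, in long form
#'
#' @param data A sequence table (columns `seq_id`, `residues`; a `digits`
#'   column is used if present, otherwise sequences are encoded first).
#' @return A tibble with columns `seq_id`, `from`, `to` (group ids 1--8) and
#'   `n`, one row per cell of each sequence's transition matrix (64 rows per
#'   sequence, zeros included).
#' @examples
#' tibble::tibble(seq_id = "s1", residues = "DRSMYI") |>
#'   count_transitions() |>
#'   dplyr::filter(n > 0)
#' @export
count_transitions <- function(data) {
  data <- ensure_digits(data)
  purrr::map2_dfr(data$seq_id, data$digits, function(id, dig) {
    m <- transition_matrix(dig, encoded = TRUE)
    tibble::tibble(
      seq_id = id,
      from = rep(1:8, times = 8),
      to = rep(1:8, each = 8),
      n = as.integer(m)
    )
  })
}

#' Per-group residue and ordered-pair summary (the F table)
#'
#' For each sequence and each chemical group i this computes `total` (#Gi),
#' the number of group-i residues in the sequence, and `nonself` (#Xi), the
#' number of ordered pairs that start at a group-i residue excluding the self
#' pair (i, i). `nonself` equals the transition-matrix row sum minus the
#' diagonal cell; `total` differs from the row sum by one when the final
#' residue belongs to group i, since the last residue starts no pair.
#'
#' @inheritParams count_transitions
#' @return A tibble with columns `seq_id`, `group` (1--8), `total`, `nonself`;
#'   8 rows per sequence.
#' @examples
#' tibble::tibble(seq_id = "s1", residues = "DRSMYI") |> group_summary()
#' @export
group_summary <- function(data) {
  data <- ensure_digits(data)
  purrr::map2_dfr(data$seq_id, data$digits, function(id, dig) {
    v <- strtoi(strsplit(dig, "")[[1]], base = 10L)
    tot <- as.integer(table(factor(v[v > 0L], levels = 1:8)))
    m <- transition_matrix(dig, encoded = TRUE)
    tibble::tibble(
      seq_id = id,
      group = 1:8,
      total = tot,
      nonself = as.integer(rowSums(m) - diag(m))
    )
  })
}

#' Render the F table one row per sequence, cells "#G-#X"
#'
#' Wide rendering of [group_summary()]: columns `G1`..`G8`, each cell the
#' hyphenated `total-nonself` pair.
#'
#' @inheritParams count_transitions
#' @return A tibble with a `seq_id` column and character columns `G1`..`G8`.
#' @export
summary_table <- function(data) {
  group_summary(data) |>
    dplyr::mutate(cell = paste0(.data$total, "-", .data$nonself),
                  group = paste0("G", .data$group)) |>
    dplyr::select("seq_id", "group", "cell") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
}

#' Chemical groups that discriminate two sides of a sequence-set bipartition
#'
#' Given a per-group summary and a bipartition of the sequence ids, a group is
#' "hitting" (discriminating) when both its `total` (#G) value range and its
#' `nonself` (#X) value range are disjoint between the two sides, so the
#' group's transition behaviour alone separates the branches. Intervals are
#' closed; touching endpoints count as overlapping. Hits are ranked by
#' descending separation, where each metric's gap (distance between the two
#' intervals) is normalized by the midpoint of their union span and the
#' larger of the two normalized gaps is the group's separation; ties break by
#' group id.
#'
#' @param summary A long summary tibble from [group_summary()].
#' @param left,right Disjoint, non-empty character vectors of `seq_id`s, all
#'   present in `summary`.
#' @return A tibble of hitting groups with columns `group`, the left/right
#'   `[min, max]` interval bounds for both metrics (`a_*` = total, `b_*` =
#'   nonself), `gap_a`, `gap_b` and `separation`, ranked best first. Zero rows
#'   when no group discriminates.
#' @examples
#' tbl <- tibble::tibble(seq_id = c("x", "y"),
#'                       residues = c("DDDRS", "DRSRS")) |> group_summary()
#' discriminating_groups(tbl, left = "x", right = "y")
#' @export
discriminating_groups <- function(summary, left, right) {
  stopifnot(is.data.frame(summary),
            all(c("seq_id", "group", "total", "nonself") %in% names(summary)))
  left <- as.character(left)
  right <- as.character(right)
  if (!length(left) || !length(right)) {
    rlang::abort("`left` and `right` must be non-empty.",
                 class = "chemotif_domain_error")
  }
  if (length(intersect(left, right))) {
    rlang::abort("`left` and `right` must be disjoint.",
                 class = "chemotif_domain_error")
  }
  unknown <- setdiff(c(left, right), summary$seq_id)
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown seq_id(s): %s.",
                         paste(unknown, collapse = ", ")),
                 class = "chemotif_domain_error")
  }

  side_range <- function(ids, metric) {
    summary |>
      dplyr::filter(.data$seq_id %in% ids) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(min = min(.data[[metric]]),
                       max = max(.data[[metric]]), .groups = "drop")
  }
  # closed-interval distance; 0 when the intervals touch or overlap
  gap_of <- function(lmin, lmax, rmin, rmax) pmax(0, rmin - lmax, lmin - rmax)
  norm_gap <- function(lmin, lmax, rmin, rmax) {
    mid <- (pmin(lmin, rmin) + pmax(lmax, rmax)) / 2
    gap <- gap_of(lmin, lmax, rmin, rmax)
    ifelse(mid > 0, gap / mid, ifelse(gap > 0, Inf, 0))
  }

  res <- tibble::tibble(group = 1:8)
  for (metric in c("a", "b")) {
    col <- if (metric == "a") "total" else "nonself"
    l <- side_range(left, col)
    r <- side_range(right, col)
    res[[paste0(metric, "_left_min")]] <- l$min
    res[[paste0(metric, "_left_max")]] <- l$max
    res[[paste0(metric, "_right_min")]] <- r$min
    res[[paste0(metric, "_right_max")]] <- r$max
    res[[paste0("gap_", metric)]] <- gap_of(l$min, l$max, r$min, r$max)
    res[[paste0("norm_gap_", metric)]] <- norm_gap(l$min, l$max, r$min, r$max)
  }
  res |>
    dplyr::filter(.data$gap_a > 0, .data$gap_b > 0) |>
    dplyr::mutate(separation = pmax(.data$norm_gap_a, .data$norm_gap_b)) |>
    dplyr::arrange(dplyr::desc(.data$separation), .data$group) |>
    dplyr::select(-"norm_gap_a", -"norm_gap_b")
}

#' Heatmap of pooled chemical-group transition counts
#'
#' @inheritParams count_transitions
#' @return A ggplot: 8x8 tile map of transition counts summed over all
#'   sequences in `data`.
#' @export
plot_transitions <- function(data) {
  pooled <- count_transitions(data) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(pooled, ggplot2::aes(x = factor(.data$to),
                                       y = factor(.data$from),
                                       fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(as.character(1:8))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "to group", y = "from group", fill = "pairs",
                  title = "Chemical-group transition counts") +
    ggplot2::theme_minimal()
}
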