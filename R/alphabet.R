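#' The eight chemical groups of the standard amino acids
#'
#' The reduced alphabet partitions the 20 standard amino acids into eight
#' classes by side-chain chemistry. Each residue is replaced by the digit
#' (1--8) of the group that owns it, so a protein becomes a string over
#' `'1'`--`'8'` and two residues are "chemically identical" when they share a
#' digit (e.g. S and T, or Y and F).
#'
#' @return A tibble with one row per group and columns `group` (integer 1--8),
#'   `name` (group name) and `residues` (list-column of 1-letter codes).
#' @examples
#' chemical_groups()
#' @export
chemical_groups <- function() {
  tibble::tibble(
    group = 1:8,
    name = c("acidic", "basic", "aromatic", "aliphatic", "cyclic",
             "sulfur-containing", "hydroxyl-containing", "acidic amide"),
    residues = list(
      c("D", "E"),
      c("R", "H", "K"),
      c("Y", "F", "W"),
      c("I", "L", "V", "A", "G"),
      "P",
      c("M", "C"),
      c("S", "T"),
      c("Q", "N")
    )
  )
}

# residue -> group lookup, built once at load
.chem_map <- local({
  tab <- c(D = 1L, E = 1L,
           R = 2L, H = 2L, K = 2L,
           Y = 3L, F = 3L, W = 3L,
           I = 4L, L = 4L, V = 4L, A = 4L, G = 4L,
           P = 5L,
           M = 6L, C = 6L,
           S = 7L, T = 7L,
           Q = 8L, N = 8L)
  tab
})

#' Residues belonging to a chemical group
#'
#' @param group Integer group id, 1--8.
#' @return Character vector of 1-letter residue codes.
#' @examples
#' group_members(6) # M, C
#' @export
group_members <- function(group) {
  if (length(group) != 1L || is.na(group) || group < 1 || group > 8 ||
      group != as.integer(group)) {
    rlang::abort("`group` must be a single integer between 1 and 8.",
                 class = "chemotif_domain_error")
  }
  chemical_groups()$residues[[as.integer(group)]]
}

#' Chemical group of a single residue
#'
#' @param residue A single 1-letter amino-acid code (case-insensitive).
#' @return Integer group id 1--8.
#' @examples
#' encode_residue("D") # 1 (acidic)
#' encode_residue("P") # 5 (cyclic)
#' @export
encode_residue <- function(residue) {
  if (length(residue) != 1L || !is.character(residue) || nchar(residue) != 1L) {
    rlang::abort("`residue` must be a single 1-letter code.",
                 class = "chemotif_domain_error")
  }
  g <- .chem_map[toupper(residue)]
  if (is.na(g)) {
    rlang::abort(
      sprintf("Invalid residue '%s': not one of the 20 standard amino acids.",
              residue),
      class = "chemotif_invalid_residue"
    )
  }
  unname(g)
}

#' Encode residue strings as chemical-group digit strings
#'
#' Each residue of each input string is replaced by the digit of its chemical
#' group, giving a digit string of equal length over `'1'`--`'8'`. Lowercase
#' input is uppercased before lookup. Under `policy = "strict"` (the default)
#' any non-standard character (B, J, O, U, X, Z, `-`, `*`, ...) is an error;
#' under `policy = "mask"` such characters become the break digit `'0'`,
#' which no pattern or similarity window can ever match.
#'
#' @param residues Character vector of residue strings.
#' @param policy `"strict"` or `"mask"`.
#' @return Character vector of digit strings, same length as `residues`.
#' @examples
#' encode_seq("FPKATD")              # "352471"
#' encode_seq(c("DRSMYI", "EKTCWV")) # both "127634"
#' @export
encode_seq <- function(residues, policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  stopifnot(is.character(residues))
  up <- toupper(residues)
  std <- paste(names(.chem_map), collapse = "")
  dig <- paste(.chem_map, collapse = "")
  bad <- stringr::str_locate(up, sprintf("[^%s]", std))[, "start"]
  if (policy == "strict" && any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    rlang::abort(
      sprintf("Invalid residue '%s' at position %d of sequence %d.",
              substr(up[i], bad[i], bad[i]), bad[i], i),
      class = "chemotif_invalid_residue"
    )
  }
  out <- chartr(std, dig, up)
  if (policy == "mask") {
    out <- stringr::str_replace_all(out, sprintf("[^%s]", dig), "0")
  }
  out
}

#' Add a digit-string encoding column to a sequence table
#'
#' Data-frame-first wrapper around [encode_seq()]: takes a table of sequences
#' (such as the one returned by [read_fasta()] or [simulate_sequences()]) and
#' appends a `digits` column.
#'
#' @param data A data frame with at least columns `seq_id` and `residues`.
#' @param policy Passed to [encode_seq()].
#' @return A tibble: `data` with a `digits` character column appended.
#' @examples
#' tibble::tibble(seq_id = "s1", residues = "DRSMYI") |> encode_sequences()
#' @export
encode_sequences <- function(data, policy = c("strict", "mask")) {
  check_seq_table(data)
  tibble::as_tibble(data) |>
    dplyr::mutate(digits = encode_seq(.data$residues, policy = policy))
}

# shared validation for sequence tables
check_seq_table <- function(data, need_digits = FALSE) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame of sequences.",
                 class = "chemotif_domain_error")
  }
  need <- c("seq_id", "residues", if (need_digits) "digits")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    rlang::abort(sprintf("`data` is missing column(s): %s.",
                         paste(miss, collapse = ", ")),
                 class = "chemotif_domain_error")
  }
  if (anyDuplicated(data$seq_id)) {
    rlang::abort("`seq_id` values must be unique.",
                 class = "chemotif_domain_error")
  }
  invisible(data)
}

# ensure digits column exists, encoding if necessary
ensure_digits <- function(data, policy = "strict") {
  check_seq_table(data)
  if (!"digits" %in% names(data)) {
    data <- encode_sequences(data, policy = policy)
  }
  data
}
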