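# Independent brute-force oracles, deliberately written with plain loops so
# they share no code path with the package internals.

# all length-L substrings of one digit string, via an explicit loop
oracle_lmers <- function(digits, L) {
  n <- nchar(digits)
  out <- character(0)
  if (n >= L) {
    for (p in 1:(n - L + 1)) {
      out <- c(out, substr(digits, p, p + L - 1))
    }
  }
  unique(out)
}

# digit patterns of length L present in every digit string, optionally
# restricted to repetition-free patterns
oracle_common <- function(digit_strings, L, norepeat = FALSE) {
  sets <- lapply(digit_strings, oracle_lmers, L = L)
  common <- sets[[1]]
  for (s in sets[-1]) common <- common[common %in% s]
  if (norepeat) {
    keep <- logical(length(common))
    for (i in seq_along(common)) {
      d <- strsplit(common[i], "")[[1]]
      keep[i] <- length(unique(d)) == length(d)
    }
    common <- common[keep]
  }
  sort(common)
}

# adjacent ordered-pair count by direct loop
oracle_pair_total <- function(digits) {
  n <- nchar(digits)
  total <- 0L
  if (n >= 2) for (p in 1:(n - 1)) total <- total + 1L
  total
}

# positionwise group-match count of two equal-length digit strings
oracle_matches <- function(da, db) {
  a <- strsplit(da, "")[[1]]
  b <- strsplit(db, "")[[1]]
  m <- 0L
  for (i in seq_along(a)) if (a[i] == b[i]) m <- m + 1L
  m
}

RESIDUES20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) {
  paste(sample(RESIDUES20, len, replace = TRUE), collapse = "")
}

random_seq_table <- function(n, len_range) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  tibble::tibble(
    seq_id = sprintf("r%02d", seq_len(n)),
    residues = vapply(lens, random_protein, character(1))
  )
}

# swap every residue of a block for a random residue of the same group
resample_within_groups <- function(block) {
  groups <- chemical_groups()$residues
  chars <- strsplit(toupper(block), "")[[1]]
  out <- vapply(chars, function(r) {
    mem <- groups[[encode_residue(r)]]
    if (length(mem) == 1) mem else sample(mem, 1)
  }, character(1))
  paste(out, collapse = "")
}
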