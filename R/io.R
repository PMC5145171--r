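#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]: multi-record files, wrapped lines
#' and CRLF endings are handled; sequences are uppercased. The record id is
#' the first whitespace-delimited token of the header, the rest is kept as
#' `description`.
#'
#' @param path Path to a FASTA file.
#' @param policy Residue policy: `"strict"` rejects any record containing a
#'   non-standard character (B, J, O, U, X, Z, gaps, `*`) with the record and
#'   offset named; `"mask"` defers masking to [encode_sequences()].
#' @return A tibble with columns `seq_id`, `description`, `residues`.
#' @export
read_fasta <- function(path, policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
                 class = "chemotif_io_error")
  }
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) {
    rlang::abort(sprintf("No FASTA records in %s.", path),
                 class = "chemotif_io_error")
  }
  headers <- names(set)
  ids <- stringr::str_extract(headers, "^\\S+")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rlang::abort(sprintf("Duplicate FASTA id(s): %s.",
                         paste(dup, collapse = ", ")),
                 class = "chemotif_io_error")
  }
  out <- tibble::tibble(
    seq_id = ids,
    description = stringr::str_trim(stringr::str_remove(headers, "^\\S+")),
    residues = unname(toupper(as.character(set)))
  )
  if (policy == "strict") {
    std <- paste(sort(unlist(chemical_groups()$residues)), collapse = "")
    bad <- stringr::str_locate(out$residues, sprintf("[^%s]", std))[, "start"]
    if (any(!is.na(bad))) {
      i <- which(!is.na(bad))[1L]
      rlang::abort(
        sprintf("Record '%s': invalid residue '%s' at offset %d.",
                out$seq_id[i], substr(out$residues[i], bad[i], bad[i]), bad[i]),
        class = "chemotif_invalid_residue")
    }
  }
  out
}

#' Write a sequence table to FASTA
#'
#' @param data A sequence table (`seq_id`, `residues`, optional
#'   `description`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  check_seq_table(data)
  set <- Biostrings::AAStringSet(data$residues)
  names(set) <- if ("description" %in% names(data) &&
                    any(nzchar(data$description))) {
    stringr::str_trim(paste(data$seq_id, data$description))
  } else {
    data$seq_id
  }
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Simulate protein-like sequences with planted chemical-group motifs
#'
#' Generates a reproducible set of random amino-acid sequences and plants
#' digit patterns into them at non-overlapping positions. Each planted
#' occurrence realizes its pattern by sampling, independently per position,
#' one residue from the corresponding group's members — so the chemical
#' pattern is exact while the residues vary across occurrences, emulating
#' within-group conservation such as S/T or Y/F swaps. Defaults emulate a
#' small protein family: 8 sequences of 300--400 residues with a uniform
#' background over the 20 standard residues.
#'
#' @param n_sequences Number of sequences.
#' @param length_range Length range `c(min, max)`, sampled uniformly.
#' @param planted A character vector of digit patterns over `'1'`--`'8'`
#'   (each planted once per sequence), or a data frame with columns `pattern`
#'   and `count` (occurrences per sequence). `NULL` plants nothing.
#' @param background Per-residue sampling weights: a named numeric vector
#'   over the 20 standard codes (need not sum to 1). `NULL` = uniform.
#' @param seed Integer seed; the output is fully determined by it.
#' @return A list with `sequences`, a tibble (`seq_id`, `residues`), and
#'   `manifest`, a tibble of ground-truth plants (`seq_id`, `pattern`,
#'   `position`).
#' @examples
#' fx <- simulate_sequences(3, c(50, 60), planted = "352471", seed = 1)
#' fx$manifest
#' @export
simulate_sequences <- function(n_sequences = 8,
                               length_range = c(300, 400),
                               planted = NULL,
                               background = NULL,
                               seed = 1L) {
  stopifnot(n_sequences >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (is.character(planted)) {
    planted <- tibble::tibble(pattern = planted, count = 1L)
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("pattern", "count") %in% names(planted)),
              all(grepl("^[1-8]+$", planted$pattern)), all(planted$count >= 1))
    if (any(nchar(planted$pattern) > length_range[1])) {
      rlang::abort("Planted pattern longer than the minimum sequence length.",
                   class = "chemotif_domain_error")
    }
  }
  residues20 <- sort(unlist(chemical_groups()$residues))
  if (is.null(background)) {
    background <- stats::setNames(rep(1, 20), residues20)
  }
  stopifnot(all(residues20 %in% names(background)))
  w <- background[residues20]
  members <- chemical_groups()$residues

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  lens <- sample(length_range[1]:length_range[2], n_sequences, replace = TRUE)
  seqs <- character(n_sequences)
  manifest <- list()
  for (i in seq_len(n_sequences)) {
    chars <- sample(residues20, lens[i], replace = TRUE, prob = w)
    if (!is.null(planted)) {
      taken <- integer(0) # occupied positions, so plants never overlap
      for (j in seq_len(nrow(planted))) {
        pat <- strtoi(strsplit(planted$pattern[j], "")[[1]], base = 10L)
        Lp <- length(pat)
        for (k in seq_len(planted$count[j])) {
          free <- setdiff(seq_len(lens[i] - Lp + 1L),
                          unlist(lapply(taken, function(t) (t - Lp + 1L):t)))
          free <- free[vapply(free, function(p)
            !any((p:(p + Lp - 1L)) %in% taken), logical(1))]
          if (!length(free)) {
            rlang::abort("Could not place all planted patterns without overlap; use longer sequences or fewer plants.",
                         class = "chemotif_domain_error")
          }
          p <- if (length(free) == 1L) free else sample(free, 1L)
          block <- vapply(pat, function(g) {
            mem <- members[[g]]
            if (length(mem) == 1L) mem else sample(mem, 1L)
          }, character(1))
          chars[p:(p + Lp - 1L)] <- block
          taken <- c(taken, p:(p + Lp - 1L))
          manifest[[length(manifest) + 1L]] <-
            tibble::tibble(seq_id = sprintf("syn%02d", i),
                           pattern = planted$pattern[j],
                           position = as.integer(p))
        }
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  list(
    sequences = tibble::tibble(seq_id = sprintf("syn%02d", seq_len(n_sequences)),
                               residues = seqs),
    manifest = if (length(manifest)) {
      dplyr::arrange(dplyr::bind_rows(manifest), .data$seq_id, .data$position)
    } else {
      tibble::tibble(seq_id = character(), pattern = character(),
                     position = integer())
    }
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a result table to TSV or JSON
#'
#' @param x A data frame (any of the package's tidy outputs).
#' @param path Output path; `""` writes TSV to stdout.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  if (format == "tsv") {
    readr::write_tsv(x, path)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
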