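#' Read a FASTQ file into a read table
#'
#' Thin wrapper around [Biostrings::readQualityScaledDNAStringSet()]
#' (gzip-transparent) that returns reads in the plain tabular form the rest of
#' the package consumes. The inline sample index is taken to be the first
#' `index_length` bases of each read; the remainder of the read (containing
#' flanking constant regions and the barcode) stays in `sequence`.
#'
#' @param path Path to a FASTQ (or FASTQ.gz) file.
#' @param index_length Number of leading bases forming the inline index.
#' @param quality_encoding Quality score encoding; only `"phred"` (Sanger,
#'   offset 33) is supported. Anything else is a configuration error.
#' @return A tibble with columns `read_id`, `inline_index`, `sequence` and
#'   `quality` (integer-list column of per-base Phred scores for the
#'   post-index region).
#' @export
read_fastq_reads <- function(path, index_length = 0L, quality_encoding = "phred") {
  if (!identical(quality_encoding, "phred")) {
    stop("unknown quality encoding: ", quality_encoding, call. = FALSE)
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTQ requires the Biostrings package", call. = FALSE)
  }
  reads <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")),
    error = function(e) {
      stop("malformed FASTQ input in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  bad <- which(Biostrings::width(reads) !=
                 Biostrings::width(Biostrings::quality(reads)))
  if (length(bad)) {
    stop("malformed FASTQ record at offset ", bad[1],
         ": sequence and quality lengths differ", call. = FALSE)
  }
  seqs <- unname(as.character(reads))
  quals <- tryCatch(
    as.list(as(Biostrings::quality(reads), "IntegerList")),
    error = function(e) {
      # truncated quality lines are nul-padded by the parser and surface here
      stop("malformed FASTQ input in '", path,
           "': quality line shorter than its sequence", call. = FALSE)
    }
  )
  n <- length(seqs)
  idx_len <- as.integer(index_length)
  tibble::tibble(
    read_id = if (is.null(names(reads))) as.character(seq_len(n)) else names(reads),
    inline_index = substr(seqs, 1L, idx_len),
    sequence = substr(seqs, idx_len + 1L, nchar(seqs)),
    quality = lapply(quals, function(q) q[seq.int(idx_len + 1L, length.out = length(q) - idx_len)])
  )
}

#' Construct a read table in memory
#'
#' Convenience constructor used by tests and the synthetic generator; enforces
#' the same invariants as [read_fastq_reads()].
#'
#' @param sequence Character vector of read sequences (post-index region).
#' @param quality List of integer vectors of per-base Phred scores, or a single
#'   number recycled over all bases of every read.
#' @param inline_index Character vector (recycled) of inline index sequences.
#' @return A read-table tibble.
#' @export
read_table <- function(sequence, quality, inline_index = "") {
  if (!is.list(quality)) {
    quality <- lapply(nchar(sequence), function(n) rep.int(as.integer(quality), n))
  }
  if (any(nchar(sequence) != lengths(quality))) {
    stop("sequence and quality must have equal length per read", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", sequence))) {
    stop("sequence alphabet must be {A,C,G,T,N}", call. = FALSE)
  }
  tibble::tibble(
    read_id = as.character(seq_along(sequence)),
    inline_index = rep_len(inline_index, length(sequence)),
    sequence = sequence,
    quality = quality
  )
}

#' Filter reads on inline index and barcode-region quality
#'
#' A read survives iff its inline index matches `expected_index` exactly and no
#' more than `max_low_quality_bases` bases of its barcode region fall below
#' `min_quality`. The barcode region is located with `pattern` (see
#' [barcode_pattern()]); reads in which the pattern does not match are judged
#' on the whole post-index sequence, so that unextractable reads are not
#' rescued by a lenient region.
#'
#' @param reads Read table from [read_fastq_reads()] / [read_table()].
#' @param expected_index Inline index that must match exactly ("" if unused).
#' @param pattern A [barcode_pattern()] locating the barcode region, or `NULL`
#'   to apply the quality rule to the whole read.
#' @param min_quality Minimum acceptable per-base Phred score (default 20).
#' @param max_low_quality_bases Number of sub-threshold bases tolerated in the
#'   region (default 0).
#' @return The surviving rows of `reads`, order preserved, with the tally of
#'   dropped reads in `attr(, "dropped")` (named: `index`, `quality`).
#' @export
filter_reads <- function(reads, expected_index = "", pattern = NULL,
                         min_quality = 20, max_low_quality_bases = 0) {
  idx_ok <- reads$inline_index == expected_index
  region <- barcode_region(reads$sequence, pattern)
  low <- mapply(function(q, from, to) {
    if (is.na(from)) sum(q < min_quality) else sum(q[from:to] < min_quality)
  }, reads$quality, region$start, region$end)
  qual_ok <- low <= max_low_quality_bases
  keep <- idx_ok & qual_ok
  out <- reads[keep, , drop = FALSE]
  attr(out, "dropped") <- c(index = sum(!idx_ok),
                            quality = sum(idx_ok & !qual_ok))
  out
}

#' Declare the flank-anchored barcode pattern
#'
#' Barcodes are located between two constant flanking sequences. Flanks are
#' matched exactly; `flank_width` optionally trims each flank to its
#' barcode-proximal bases so that sequencing errors far from the barcode do not
#' cost reads.
#'
#' @param left,right Constant flanking sequences (left/right of the barcode).
#' @param min_length,max_length Admissible barcode lengths.
#' @param flank_width Number of barcode-proximal bases of each flank required
#'   to match (`Inf` = whole flank).
#' @return An object of class `barcode_pattern`.
#' @export
barcode_pattern <- function(left, right, min_length = 8L, max_length = 12L,
                            flank_width = Inf) {
  stopifnot(min_length >= 1, max_length >= min_length)
  if (is.finite(flank_width)) {
    left <- substr(left, max(1L, nchar(left) - flank_width + 1L), nchar(left))
    right <- substr(right, 1L, min(nchar(right), flank_width))
  }
  structure(
    list(left = left, right = right,
         min_length = as.integer(min_length),
         max_length = as.integer(max_length),
         regex = paste0(left, "([ACGTN]{", min_length, ",", max_length, "})", right)),
    class = "barcode_pattern"
  )
}

# Locate the barcode region (start/end, 1-based, in the post-index sequence).
barcode_region <- function(sequence, pattern) {
  if (is.null(pattern)) {
    return(list(start = rep(1L, length(sequence)), end = nchar(sequence)))
  }
  m <- regexpr(pattern$regex, sequence, perl = TRUE)
  hit <- m != -1L
  start <- ifelse(hit, m + nchar(pattern$left), NA_integer_)
  width <- attr(m, "match.length") - nchar(pattern$left) - nchar(pattern$right)
  list(start = as.integer(start),
       end = as.integer(ifelse(hit, start + width - 1L, NA_integer_)))
}

#' Extract barcodes from reads
#'
#' Returns the barcode substring for every read in which both flanks of
#' `pattern` match; non-matching reads yield `NA` and are tallied rather than
#' raising an error.
#'
#' @param reads Read table (or a character vector of sequences).
#' @param pattern A [barcode_pattern()].
#' @return Character vector of barcodes (`NA` = no match) with the no-match
#'   tally in `attr(, "unmatched")`.
#' @export
extract_barcode <- function(reads, pattern) {
  sequence <- if (is.data.frame(reads)) reads$sequence else reads
  region <- barcode_region(sequence, pattern)
  out <- ifelse(is.na(region$start), NA_character_,
                substr(sequence, region$start, region$end))
  attr(out, "unmatched") <- sum(is.na(out))
  out
}

# All strings obtained by deleting one position from x (plus x itself).
deletion_neighborhood <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(x)
  dels <- vapply(seq_len(n), function(i) {
    paste0(substr(x, 1L, i - 1L), substr(x, i + 1L, n))
  }, character(1))
  unique(c(x, dels))
}

# Index mapping every neighborhood member of every known barcode to its owner.
# Members shared by several known barcodes map to NA (intrinsically ambiguous).
build_deletion_index <- function(known) {
  keys <- lapply(known, deletion_neighborhood)
  idx <- tibble::tibble(
    key = unlist(keys, use.names = FALSE),
    barcode = rep(known, lengths(keys))
  )
  idx <- dplyr::summarise(
    dplyr::group_by(idx, .data$key),
    barcode = if (dplyr::n_distinct(.data$barcode) == 1L) .data$barcode[1] else NA_character_,
    n_owners = dplyr::n_distinct(.data$barcode),
    .groups = "drop"
  )
  idx
}

#' Correct raw barcodes against a known set (single-bp-deletion neighborhoods)
#'
#' A raw barcode is assigned to a known barcode iff the single-bp-deletion
#' neighborhood of the raw string (every string obtained by deleting one
#' position, plus the string itself) intersects the deletion neighborhood of
#' exactly one known barcode. This corrects any single substitution, insertion
#' or deletion. Intersections with zero or two or more known barcodes, and raw
#' lengths outside L-1..L+1 (L = known barcode length), are `unassigned`. A raw
#' string that *is* a known barcode is always assigned to itself.
#'
#' @param raw Character vector of raw (extracted) barcodes; `NA` allowed.
#' @param known Character vector of known barcodes, all the same length.
#' @return Character vector of corrected barcodes (`NA` = unassigned) with an
#'   `attr(, "tally")` named integer vector over categories
#'   `assigned`, `no_flank` (input `NA`), `bad_length`, `ambiguous`,
#'   `no_neighbor`.
#' @export
correct_barcode <- function(raw, known) {
  L <- unique(nchar(known))
  if (length(L) != 1L) stop("known barcodes must share one length", call. = FALSE)
  if (anyDuplicated(known)) stop("known barcodes must be unique", call. = FALSE)
  idx <- build_deletion_index(known)

  out <- rep(NA_character_, length(raw))
  category <- rep("no_neighbor", length(raw))
  category[is.na(raw)] <- "no_flank"

  len <- nchar(raw)
  exact <- !is.na(raw) & raw %in% known
  out[exact] <- raw[exact]
  category[exact] <- "assigned"

  todo <- which(!is.na(raw) & !exact)
  badlen <- todo[abs(len[todo] - L) > 1L]
  category[badlen] <- "bad_length"
  todo <- setdiff(todo, badlen)

  if (length(todo)) {
    nbh <- lapply(raw[todo], deletion_neighborhood)
    keys <- tibble::tibble(
      i = rep(todo, lengths(nbh)),
      key = unlist(nbh, use.names = FALSE)
    )
    keys <- dplyr::inner_join(keys, idx, by = "key")
    hits <- dplyr::summarise(
      dplyr::group_by(keys, .data$i),
      ambiguous = any(.data$n_owners > 1L) || dplyr::n_distinct(.data$barcode) > 1L,
      barcode = .data$barcode[1],
      .groups = "drop"
    )
    ok <- hits[!hits$ambiguous & !is.na(hits$barcode), ]
    out[ok$i] <- ok$barcode
    category[ok$i] <- "assigned"
    amb <- hits$i[hits$ambiguous]
    category[amb] <- "ambiguous"
  }

  attr(out, "tally") <- c(
    assigned = sum(category == "assigned"),
    no_flank = sum(category == "no_flank"),
    bad_length = sum(category == "bad_length"),
    ambiguous = sum(category == "ambiguous"),
    no_neighbor = sum(category == "no_neighbor")
  )
  out
}

#' Tally corrected barcode assignments into lineage count tables
#'
#' @param assignments Tibble with columns `barcode` (corrected; `NA` =
#'   unassigned) and `timepoint` (integer, must be among `timepoints`).
#' @param map Barcode map tibble with columns `barcode`, `library_id`,
#'   `clone_id`, `mutation_id`, `neutral`.
#' @param timepoints Integer vector of declared assay timepoints (columns of
#'   the output); an assignment at an undeclared timepoint is a hard error.
#' @return A named list, one element per (library, clone) assay, each a tibble
#'   of per-barcode counts with columns `barcode`, `mutation_id`, `neutral` and
#'   one `t<j>` column per timepoint. The fraction of unassigned reads is in
#'   `attr(, "unassigned_fraction")`.
#' @export
tally_counts <- function(assignments, map, timepoints) {
  timepoints <- sort(as.integer(timepoints))
  bad_t <- setdiff(unique(assignments$timepoint), timepoints)
  if (length(bad_t)) {
    stop("assignment at undeclared timepoint(s): ", paste(bad_t, collapse = ", "),
         call. = FALSE)
  }
  assigned <- assignments[!is.na(assignments$barcode), , drop = FALSE]
  unknown <- setdiff(unique(assigned$barcode), map$barcode)
  if (length(unknown)) {
    stop("assigned barcode not present in the map: ", unknown[1], call. = FALSE)
  }
  tcols <- paste0("t", timepoints)
  # exact multiplicities over the full declared grid
  grid <- tidyr::crossing(barcode = map$barcode, timepoint = timepoints)
  tallied <- dplyr::count(assigned, .data$barcode, .data$timepoint)
  counts <- dplyr::left_join(grid, tallied, by = c("barcode", "timepoint"))
  counts$n[is.na(counts$n)] <- 0L
  wide <- tidyr::pivot_wider(counts, names_from = "timepoint",
                             values_from = "n", names_prefix = "t")
  wide <- dplyr::left_join(wide, map, by = "barcode")
  out <- lapply(split(wide, paste(wide$library_id, wide$clone_id, sep = "/")),
                function(d) {
                  tibble::as_tibble(d[, c("barcode", "library_id", "clone_id",
                                          "mutation_id", "neutral", tcols)])
                })
  attr(out, "unassigned_fraction") <-
    if (nrow(assignments)) mean(is.na(assignments$barcode)) else 0
  out
}

#' Validate a barcode map
#'
#' Checks the invariants of the barcode-to-lineage map: unique barcodes, a
#' single (library, clone, mutation) key per barcode, and at least one neutral
#' reference mutation per clone (required downstream to zero the fitness
#' scale).
#'
#' @param map Tibble with columns `barcode`, `library_id`, `clone_id`,
#'   `mutation_id`, `neutral`.
#' @return `map`, invisibly, after validation.
#' @export
validate_barcode_map <- function(map) {
  need <- c("barcode", "library_id", "clone_id", "mutation_id", "neutral")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols)) {
    stop("barcode map lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map$barcode)) stop("barcodes must be unique", call. = FALSE)
  per_clone <- dplyr::summarise(dplyr::group_by(map, .data$clone_id),
                                any_neutral = any(.data$neutral), .groups = "drop")
  if (!all(per_clone$any_neutral)) {
    stop("every clone needs at least one neutral reference mutation",
         call. = FALSE)
  }
  invisible(map)
}
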