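#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that keys records by
#' the first whitespace-delimited token of each header, upper-cases the
#' sequences and strips terminal stop characters (`*`). Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] named by record id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("FASTA parse error: ", path, " is empty", call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1],
         ": expected a '>' header before sequence data", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  seqs <- Biostrings::AAStringSet(gsub("^\\*+|\\*+$", "", as.character(seqs)))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  seqs
}

#' Extract an immunogen region by 1-based inclusive coordinates
#'
#' @param sequence A character string, [Biostrings::AAString] or one-element
#'   [Biostrings::AAStringSet].
#' @param start,end Residue coordinates, 1-based inclusive.
#' @return The subsequence as a character string of length `end - start + 1`.
#' @export
extract_region <- function(sequence, start, end) {
  s <- as.character(sequence)[1]
  len <- nchar(s)
  if (!is_count(start, 1) || !is_count(end, 1) || start > end || end > len) {
    stop("region ", start, "-", end, " out of range for sequence of length ",
         len, call. = FALSE)
  }
  substr(s, start, end)
}

aa_alphabet <- function() rownames(blosum62_matrix())

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' Semi-global alignment of an immunogen region to an orthologue
#'
#' Aligns the region globally while leaving the orthologue's ends free
#' (i.e. the region is matched against its best-scoring stretch of the
#' orthologue), under BLOSUM62 with affine gap penalties (open 11, extend
#' 1). This mirrors how a short immunogen peptide is compared against a
#' full-length orthologue sequence.
#'
#' @param region_seq The immunogen region (character / AAString).
#' @param orthologue_seq The full-length orthologue sequence.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @param substitution_matrix Scoring matrix (default BLOSUM62).
#' @return An `epitope_alignment` list: `pattern` and `subject` (gapped
#'   aligned strings), `score`, `subject_start`, `subject_end`.
#' @export
align_region <- function(region_seq, orthologue_seq,
                         gap_opening = 11, gap_extension = 1,
                         substitution_matrix = NULL) {
  p <- toupper(as.character(region_seq)[1])
  s <- toupper(as.character(orthologue_seq)[1])
  if (nchar(p) == 0 || nchar(s) == 0) stop("sequences must be nonempty", call. = FALSE)
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  ok <- rownames(substitution_matrix)
  bad <- setdiff(unique(strsplit(paste0(p, s), "")[[1]]), ok)
  if (length(bad)) {
    stop("non-amino-acid characters in input: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  align_once <- function(subject) Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(subject),
    type = "global-local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pa <- align_once(s)
  # deterministic tie-break: among equal-scoring placements prefer the
  # leftmost, by re-aligning against shrinking subject prefixes while the
  # score is preserved
  repeat {
    end <- Biostrings::end(Biostrings::subject(pa))
    if (end <= 1) break
    cand <- align_once(substr(s, 1, end - 1))
    if (Biostrings::score(cand) >= Biostrings::score(pa)) pa <- cand else break
  }
  structure(
    list(
      pattern = as.character(Biostrings::alignedPattern(pa)),
      subject = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa),
      subject_start = Biostrings::start(Biostrings::subject(pa)),
      subject_end = Biostrings::end(Biostrings::subject(pa))
    ),
    class = "epitope_alignment"
  )
}

#' Percent identity of a pairwise alignment
#'
#' Matches are columns with identical residues; the denominator is all
#' alignment columns including gap columns (one fixed, documented
#' convention -- published identity figures sometimes use other
#' denominators, e.g. region length minus one, and may differ by one
#' rounding step). The percentage is kept at full precision; the print
#' method rounds to one decimal.
#'
#' @param alignment An `epitope_alignment`, or a length-2 character vector
#'   of equal-length gapped aligned strings.
#' @return An `identity_result` list: `aligned_columns`, `matches`,
#'   `percent_identity`, `alignment` (the two gapped strings).
#' @export
percent_identity <- function(alignment) {
  if (inherits(alignment, "epitope_alignment")) {
    a <- alignment$pattern; b <- alignment$subject
  } else {
    stopifnot(is.character(alignment), length(alignment) == 2)
    a <- alignment[1]; b <- alignment[2]
  }
  if (nchar(a) == 0 || nchar(a) != nchar(b)) {
    stop("alignment must be two nonempty equal-length gapped strings", call. = FALSE)
  }
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  structure(
    list(aligned_columns = length(ca), matches = matches,
         percent_identity = 100 * matches / length(ca),
         alignment = c(a, b)),
    class = "identity_result"
  )
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("<identity_result> %.1f%% (%d/%d aligned columns)\n",
              round(x$percent_identity, 1), x$matches, x$aligned_columns))
  invisible(x)
}

#' Immunogen-vs-orthologue identity table
#'
#' For each immunogen region (a row of `regions`), extracts the region from
#' its source sequence, aligns it to the target orthologue and records the
#' percent identity. `start`/`end` may be `NA` when the whole source record
#' is the immunogen.
#'
#' @param regions Data frame with columns `antibody`, `source_id`, `start`,
#'   `end`, `target_id` (coordinates 1-based inclusive).
#' @param sequences Named sequences ([Biostrings::AAStringSet] or named
#'   character vector) containing every `source_id` and `target_id`.
#' @return Data frame with one row per region: the region description plus
#'   `aligned_columns`, `matches`, `percent_identity`.
#' @export
identity_table <- function(regions, sequences) {
  need <- c("antibody", "source_id", "start", "end", "target_id")
  stopifnot(all(need %in% names(regions)))
  seqs <- as.character(sequences)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    for (id in c(r$source_id, r$target_id)) {
      if (!id %in% names(seqs)) stop("sequence '", id, "' not supplied", call. = FALSE)
    }
    region <- if (is.na(r$start) || is.na(r$end)) seqs[[r$source_id]] else
      extract_region(seqs[[r$source_id]], r$start, r$end)
    res <- percent_identity(align_region(region, seqs[[r$target_id]]))
    cbind(r, data.frame(aligned_columns = res$aligned_columns,
                        matches = res$matches,
                        percent_identity = res$percent_identity))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
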