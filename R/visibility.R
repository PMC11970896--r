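# Immune-visibility metric.
#
# The absolute visibility of a sequence is the number of its 8-, 9- and
# 10-mers called presented by a predictor; overlapping windows are counted
# separately, and a k-mer presented by several MHC-I alleles still counts
# once (the predictor interface is allele-pooled). Relative visibility is the
# design's visibility divided by the template's.

#' Enumerate peptide windows of a sequence
#'
#' All contiguous 8-, 9- and 10-residue windows, left to right, in 0-based
#' half-open coordinates. An 11-residue sequence holds four 8-mers, three
#' 9-mers and two 10-mers.
#'
#' @param sequence Amino-acid string (may contain `'X'`).
#' @param lengths Window lengths; subset of `c(8, 9, 10)`.
#' @return Data frame with columns `start` (0-based), `length`, `peptide`.
#' @examples
#' nrow(enumerate_kmers("GANIWGANNNV"))  # 9
#' @export
enumerate_kmers <- function(sequence, lengths = c(8L, 9L, 10L)) {
  stopifnot(length(sequence) == 1L)
  lengths <- sort(as.integer(lengths))
  n <- nchar(sequence)
  starts <- integer(0); lens <- integer(0)
  for (L in lengths) {
    k <- n - L + 1L
    if (k > 0L) {
      starts <- c(starts, seq_len(k) - 1L)
      lens <- c(lens, rep.int(L, k))
    }
  }
  pep <- if (length(starts)) substring(sequence, starts + 1L, starts + lens)
         else character(0)
  data.frame(start = starts, length = lens, peptide = pep,
             stringsAsFactors = FALSE)
}

#' Absolute immune visibility of a sequence
#'
#' Enumerates every 8-10-mer window, calls the predictor once per window, and
#' counts the presented windows. Windows containing `'X'` are "unclear": they
#' never contribute to visibility but their count is reported so callers can
#' flag low-confidence sequences.
#'
#' @param sequence Amino-acid string.
#' @param predictor A presentation predictor (see [predict_presented()]).
#' @param lengths Window lengths (default 8-10).
#' @return A `visibility_report`: list with `sequence`, `kmer_calls` (data
#'   frame `start`/`length`/`peptide`/`presented`), `absolute_visibility`,
#'   `unclear_count`, `predictor_name`.
#' @export
absolute_visibility <- function(sequence, predictor, lengths = c(8L, 9L, 10L)) {
  kmers <- enumerate_kmers(sequence, lengths)
  calls <- if (nrow(kmers)) predict_presented(predictor, kmers$peptide) else logical(0)
  kmers$presented <- calls
  structure(list(
    sequence = sequence,
    kmer_calls = kmers,
    absolute_visibility = sum(calls, na.rm = TRUE),
    unclear_count = sum(is.na(calls)),
    predictor_name = predictor_name(predictor)
  ), class = "visibility_report")
}

#' @export
print.visibility_report <- function(x, ...) {
  cat("Immune-visibility report (", x$predictor_name, ")\n", sep = "")
  cat("  sequence length:    ", nchar(x$sequence), "\n", sep = "")
  cat("  k-mers assessed:    ", nrow(x$kmer_calls), "\n", sep = "")
  cat("  absolute visibility:", x$absolute_visibility, "\n")
  if (x$unclear_count > 0)
    cat("  unclear k-mers:     ", x$unclear_count, "\n")
  invisible(x)
}

#' Relative immune visibility
#'
#' The design's absolute visibility divided by the template's. A design with
#' visibility 9 against a template with visibility 36 scores 0.25. A template
#' visibility of 0 makes the ratio undefined and returns `NA` (not zero, not
#' an error).
#'
#' @param design_visibility Non-negative design visibility count.
#' @param template_visibility Non-negative template visibility count.
#' @return A real number, or `NA_real_` when the template visibility is 0.
#' @examples
#' relative_visibility(9, 36)  # 0.25
#' @export
relative_visibility <- function(design_visibility, template_visibility) {
  if (isTRUE(any(design_visibility < 0)) || isTRUE(any(template_visibility < 0)))
    stop("visibility counts must be >= 0")
  ifelse(!is.na(template_visibility) & template_visibility == 0, NA_real_,
         design_visibility / template_visibility)
}

#' Per-residue epitope annotation
#'
#' Categorizes each residue as `anchor` (second or last position of at least
#' one presented k-mer), `epitope` (inside a presented k-mer but not an
#' anchor), `unclear` (inside an 'X'-containing k-mer and in no presented
#' k-mer), or `none`. Precedence: anchor > epitope > unclear > none.
#'
#' @inheritParams absolute_visibility
#' @return Character vector of per-residue categories.
#' @export
annotate_residues <- function(sequence, predictor, lengths = c(8L, 9L, 10L)) {
  n <- nchar(sequence)
  cat_lvl <- rep("none", n)
  rep_ <- absolute_visibility(sequence, predictor, lengths)
  calls <- rep_$kmer_calls
  for (i in seq_len(nrow(calls))) {
    s <- calls$start[i]; L <- calls$length[i]
    pos <- (s + 1L):(s + L)                      # 1-based residue indices
    if (isTRUE(calls$presented[i])) {
      inner <- setdiff(pos, c(s + 2L, s + L))
      cat_lvl[inner][cat_lvl[inner] == "none" | cat_lvl[inner] == "unclear"] <- "epitope"
      cat_lvl[c(s + 2L, s + L)] <- "anchor"
    } else if (is.na(calls$presented[i])) {
      cat_lvl[pos][cat_lvl[pos] == "none"] <- "unclear"
    }
  }
  # epitope must win over unclear even when the unclear k-mer came later
  cat_lvl
}
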