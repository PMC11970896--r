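#' @keywords internal
"_PACKAGE"

#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in the fixed row order used by all PWM
#' matrices in this package (alphabetical one-letter codes), and the same
#' alphabet extended by `"X"` (unknown residue), the 21st token of the
#' sequence model vocabulary.
#'
#' @return Character vector of one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
aa_alphabet_x <- function() c(aa_alphabet(), "X")

#' Background amino-acid composition of natural proteins
#'
#' Average residue frequencies in naturally occurring proteins
#' (Robinson & Robinson-style background), in [aa_alphabet()] order.
#' Used by the synthetic-data module to draw native-like template sequences.
#'
#' @return Named numeric vector summing to 1.
#' @export
aa_background <- function() {
  f <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
         G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
         M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
         S = 0.0661, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)
  f / sum(f)
}

peptide_lengths_supported <- c(8L, 9L, 10L)

#' Validate peptide strings
#'
#' A valid peptide is 8-10 residues long and uses the 20 canonical one-letter
#' codes, optionally containing `"X"` for an unknown residue.
#'
#' @param peptides Character vector.
#' @param allow_x Admit `"X"` characters (default `TRUE`).
#' @return Logical vector, one entry per peptide.
#' @export
is_valid_peptide <- function(peptides, allow_x = TRUE) {
  alph <- if (allow_x) aa_alphabet_x() else aa_alphabet()
  ok_len <- nchar(peptides) %in% peptide_lengths_supported
  ok_chr <- vapply(strsplit(peptides, ""), function(ch) all(ch %in% alph),
                   logical(1))
  ok_len & ok_chr
}

has_unknown_residue <- function(peptides) grepl("X", peptides, fixed = TRUE)

#' Sample uniform random peptides
#'
#' Draws `n` peptides with lengths chosen uniformly from `lengths` and
#' residues i.i.d. uniform over the 20 canonical amino acids. This emulates
#' the random 8-10-mer pool used to build and calibrate the presentation
#' classifier.
#'
#' @param n Number of peptides (>= 0).
#' @param lengths Peptide lengths to draw from; subset of `c(8, 9, 10)`.
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of `n` peptides.
#' @examples
#' sample_random_peptides(5, seed = 1)
#' @export
sample_random_peptides <- function(n, lengths = c(8L, 9L, 10L), seed = NULL) {
  if (length(lengths) == 0L) stop("`lengths` must be nonempty")
  lengths <- as.integer(lengths)
  if (!all(lengths %in% peptide_lengths_supported))
    stop("peptide lengths must be within {8, 9, 10}")
  if (n < 0) stop("`n` must be >= 0")
  if (n == 0) return(character(0))
  if (!is.null(seed)) set.seed(seed)
  aa <- aa_alphabet()
  len <- lengths[sample.int(length(lengths), n, replace = TRUE)]
  # draw one flat residue vector then split by peptide
  res <- sample(aa, sum(len), replace = TRUE)
  idx <- rep.int(seq_len(n), len)
  vapply(split(res, idx), paste, character(1), collapse = "")
}

#' Construct a labeled peptide set
#'
#' A labeled peptide set pairs peptides with presented/absent calls from a
#' reference presentation predictor; it is the training and calibration input
#' of [build_pwm()] and [calibrate_pwm()].
#'
#' @param peptide Character vector of peptides.
#' @param presented Logical vector of reference calls (same length).
#' @param source Name of the labeling predictor (metadata).
#' @param alleles Optional character vector of HLA allele names (metadata).
#' @return A `labeled_peptides` data frame with columns `peptide`, `presented`.
#' @export
labeled_peptides <- function(peptide, presented,
                             source = "unknown", alleles = character(0)) {
  if (length(peptide) != length(presented))
    stop("`peptide` and `presented` lengths differ")
  presented <- as.logical(presented)
  if (anyNA(presented)) stop("`presented` must be TRUE/FALSE")
  bad <- !is_valid_peptide(peptide)
  if (any(bad))
    stop("invalid peptides: ", paste(utils::head(peptide[bad], 3), collapse = ", "))
  out <- data.frame(peptide = as.character(peptide), presented = presented,
                    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  attr(out, "alleles") <- alleles
  class(out) <- c("labeled_peptides", "data.frame")
  out
}

#' Read / write labeled peptide sets
#'
#' CSV interchange format with columns `peptide,presented` (0/1).
#'
#' @param path File path.
#' @param x A `labeled_peptides` object.
#' @return `read_labeled_peptides` returns a `labeled_peptides` object.
#' @export
read_labeled_peptides <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "presented") %in% names(df)))
    stop("expected columns `peptide`, `presented` in ", path)
  labeled_peptides(df$peptide, df$presented != 0, source = basename(path))
}

#' @rdname read_labeled_peptides
#' @export
write_labeled_peptides <- function(x, path) {
  df <- data.frame(peptide = x$peptide, presented = as.integer(x$presented))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
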