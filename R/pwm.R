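# PWM-based MHC-I presentation classifier.
#
# One log-probability matrix per peptide length (rows = 20 AAs, columns =
# positions), estimated from reference-predictor-presented peptides, scored by
# summing column entries, and thresholded so that the classifier reproduces the
# reference predictor's presented fraction on a random calibration set.

#' Build a PWM presentation classifier from labeled peptides
#'
#' Estimates, per peptide length, the per-position amino-acid log-probabilities
#' among peptides the reference predictor labels presented:
#' `entry(aa, pos, L) = log((count + pseudocount) / (n_presented + 20 * pseudocount))`.
#' Only presented peptides contribute; peptides containing `'X'` are excluded.
#' The returned classifier is uncalibrated (no thresholds) until passed to
#' [calibrate_pwm()].
#'
#' @param labeled A [labeled_peptides()] set containing at least one presented
#'   peptide of every length in `lengths`.
#' @param pseudocount Count added per amino acid per column before
#'   normalization (default 0.5). `0` is admitted for exact hand-checkable
#'   probabilities but produces `-Inf` entries for unobserved residues.
#' @param lengths Peptide lengths to build matrices for; defaults to the
#'   lengths present in `labeled`.
#' @return A `pwm_classifier` object.
#' @seealso [calibrate_pwm()], [score_peptides()], [predict.pwm_classifier()]
#' @export
build_pwm <- function(labeled, pseudocount = 0.5, lengths = NULL) {
  stopifnot(inherits(labeled, "labeled_peptides") || is.data.frame(labeled))
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  pep <- labeled$peptide
  keep <- !has_unknown_residue(pep)
  pep <- pep[keep]
  presented <- labeled$presented[keep]
  len <- nchar(pep)
  if (is.null(lengths)) lengths <- sort(unique(len))
  lengths <- as.integer(lengths)
  aa <- aa_alphabet()
  mats <- list()
  n_presented <- integer(0)
  for (L in lengths) {
    sel <- presented & len == L
    if (!any(sel))
      stop("no presented peptide of length ", L, " to build a PWM from")
    m <- peptide_matrix(pep[sel], L)          # integer matrix n x L
    counts <- matrix(0, nrow = 20L, ncol = L, dimnames = list(aa, NULL))
    for (j in seq_len(L)) {
      tab <- tabulate(m[, j], nbins = 20L)
      counts[, j] <- tab
    }
    prob <- (counts + pseudocount) / (sum(sel) + 20 * pseudocount)
    mats[[as.character(L)]] <- log(prob)
    n_presented[as.character(L)] <- sum(sel)
  }
  structure(list(
    matrices = mats,
    thresholds = NULL,
    reference_fraction = NULL,
    calibration = NULL,
    pseudocount = pseudocount,
    source = attr(labeled, "source"),
    boundary = ">="
  ), class = "pwm_classifier")
}

# peptides (all of length L) -> n x L integer matrix of alphabet indices
peptide_matrix <- function(peptides, L) {
  if (length(peptides) == 0L) return(matrix(integer(0), 0, L))
  ch <- strsplit(peptides, "")
  m <- matrix(match(unlist(ch), aa_alphabet()), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("peptides contain characters outside the 20-AA alphabet")
  m
}

#' Score peptides under a PWM classifier
#'
#' The score of a peptide is the sum over positions of the PWM
#' log-probability of its residue at that position.
#'
#' @param pwm A `pwm_classifier`.
#' @param peptides Character vector; all peptides must be free of `'X'` and of
#'   a length the classifier holds a matrix for.
#' @return Numeric vector of scores.
#' @export
score_peptides <- function(pwm, peptides) {
  stopifnot(inherits(pwm, "pwm_classifier"))
  if (length(peptides) == 0L) return(numeric(0))
  if (any(has_unknown_residue(peptides)))
    stop("cannot score peptides containing 'X' (unclear peptide)")
  len <- nchar(peptides)
  out <- numeric(length(peptides))
  for (L in unique(len)) {
    mat <- pwm$matrices[[as.character(L)]]
    if (is.null(mat)) stop("no PWM for peptide length ", L)
    idx <- which(len == L)
    m <- peptide_matrix(peptides[idx], L)
    # gather log-probs: entry (i, j) of m indexes row m[i,j], column j
    lp <- matrix(mat[cbind(as.vector(m), rep(seq_len(L), each = nrow(m)))],
                 nrow = nrow(m))
    out[idx] <- rowSums(lp)
  }
  out
}

#' Calibrate PWM thresholds against a reference-labeled random set
#'
#' For each length, the reference fraction `f_L` is the fraction of
#' calibration peptides the reference predictor labeled presented. The
#' threshold is set to the `round(f_L * n_L)`-th highest calibration score, so
#' that the classifier predicts (up to score ties) as many presented peptides
#' in the random set as the reference predictor did. Scores tied with the
#' boundary are admitted (score >= threshold counts as presented), which may
#' overshoot the target count; the achieved count is recorded in the
#' calibration metadata.
#'
#' @param pwm An uncalibrated (or previously calibrated) `pwm_classifier`.
#' @param calibration A [labeled_peptides()] set covering every length in `pwm`.
#' @return The calibrated `pwm_classifier`.
#' @export
calibrate_pwm <- function(pwm, calibration) {
  stopifnot(inherits(pwm, "pwm_classifier"))
  pep <- calibration$peptide
  keep <- !has_unknown_residue(pep)
  pep <- pep[keep]
  presented <- calibration$presented[keep]
  len <- nchar(pep)
  lengths <- as.integer(names(pwm$matrices))
  thresholds <- numeric(0)
  fractions <- numeric(0)
  meta <- list()
  for (L in lengths) {
    sel <- len == L
    n_L <- sum(sel)
    if (n_L == 0L) stop("calibration set holds no peptides of length ", L)
    f_L <- mean(presented[sel])
    scores <- score_peptides(pwm, pep[sel])
    target <- round(f_L * n_L)
    if (target == 0L) {
      t_L <- max(scores) + 1
      warning("reference fraction is 0 for length ", L,
              "; threshold set above the maximum calibration score")
    } else {
      t_L <- sort(scores, decreasing = TRUE)[target]
    }
    achieved <- sum(scores >= t_L)
    thresholds[as.character(L)] <- t_L
    fractions[as.character(L)] <- f_L
    meta[[as.character(L)]] <- list(n = n_L, target_count = target,
                                    achieved_count = achieved)
  }
  pwm$thresholds <- thresholds
  pwm$reference_fraction <- fractions
  pwm$calibration <- meta
  pwm
}

#' Predict presentation with a calibrated PWM classifier
#'
#' A peptide is called presented when its summed log-probability score is
#' greater than or equal to the calibrated threshold for its length. Peptides
#' containing `'X'` are "unclear" and return `NA` (neither presented nor
#' absent); the visibility metric counts them separately.
#'
#' @param object A calibrated `pwm_classifier`.
#' @param peptides Character vector of peptides.
#' @param ... Unused.
#' @return Logical vector (`NA` = unclear).
#' @export
predict.pwm_classifier <- function(object, peptides, ...) {
  if (is.null(object$thresholds))
    stop("PWM classifier is not calibrated; run calibrate_pwm() first")
  out <- rep(NA, length(peptides))
  clear <- !has_unknown_residue(peptides)
  if (any(clear)) {
    scores <- score_peptides(object, peptides[clear])
    thr <- object$thresholds[as.character(nchar(peptides[clear]))]
    out[clear] <- scores >= thr
  }
  out
}

#' @export
print.pwm_classifier <- function(x, ...) {
  lens <- names(x$matrices)
  cat("PWM MHC-I presentation classifier\n")
  cat("  lengths:    ", paste(lens, collapse = ", "), "\n", sep = "")
  cat("  pseudocount:", x$pseudocount, "\n")
  if (is.null(x$thresholds)) {
    cat("  calibration: <uncalibrated>\n")
  } else {
    for (L in lens) {
      cm <- x$calibration[[L]]
      cat(sprintf(
        "  L=%s: threshold %.4f, reference fraction %.4f (n=%d, predicted %d/%d)\n",
        L, x$thresholds[[L]], x$reference_fraction[[L]],
        cm$n, cm$achieved_count, cm$target_count))
    }
  }
  invisible(x)
}

#' Serialize a PWM classifier to JSON
#'
#' The JSON layout stores per-length 20 x L matrices (row order
#' `ACDEFGHIKLMNPQRSTVWY`), thresholds, reference fractions, the pseudocount
#' and provenance. [read_pwm()] restores the classifier; matrix entries and
#' thresholds round-trip at better than 1e-12 relative precision (the stated
#' serialization precision).
#'
#' @param pwm A `pwm_classifier`.
#' @param path Output JSON path.
#' @return `read_pwm` returns the `pwm_classifier`.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm_classifier"))
  obj <- list(
    aa_order = paste(aa_alphabet(), collapse = ""),
    pseudocount = pwm$pseudocount,
    boundary = pwm$boundary,
    source = if (is.null(pwm$source)) "unknown" else pwm$source,
    matrices = lapply(pwm$matrices, function(m) unname(m)),
    thresholds = as.list(pwm$thresholds),
    reference_fraction = as.list(pwm$reference_fraction),
    calibration = pwm$calibration
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- lapply(obj$matrices, function(m) {
    m <- as.matrix(m)
    rownames(m) <- aa_alphabet()
    m
  })
  thr <- if (length(obj$thresholds)) unlist(obj$thresholds) else NULL
  frac <- if (length(obj$reference_fraction)) unlist(obj$reference_fraction) else NULL
  structure(list(
    matrices = mats,
    thresholds = thr,
    reference_fraction = frac,
    calibration = obj$calibration,
    pseudocount = obj$pseudocount,
    source = obj$source,
    boundary = obj$boundary
  ), class = "pwm_classifier")
}
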