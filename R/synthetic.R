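# Synthetic-data module: every input the rest of the package needs, with no
# download. A deterministic motif-based presentation oracle stands in for an
# external neural presentation predictor; toy backbones provide structure
# prompts; native-like template sequences provide recovery references.

#' Deterministic motif-based presentation oracle
#'
#' A stand-in reference presentation predictor that encodes the anchor-residue
#' structure of MHC-I binding motifs: a peptide is called presented iff its
#' second residue lies in `anchor_position_2` and its last residue in
#' `anchor_terminal`. With the default 4-residue anchor sets the expected
#' presented fraction on uniform random peptides is (4/20) * (4/20) = 4%,
#' between the strong-binder (0.5% rank) and weak-binder (2% rank) regimes of
#' neural predictors; shrinking the sets tightens the regime.
#'
#' @param anchor_position_2 Amino acids admitted at peptide position 2
#'   (default hydrophobic `L, M, I, V`).
#' @param anchor_terminal Amino acids admitted at the C-terminal position
#'   (default `V, L, F, Y`).
#' @return A `motif_oracle` predictor usable with [predict_presented()].
#' @export
motif_oracle <- function(anchor_position_2 = c("L", "M", "I", "V"),
                         anchor_terminal = c("V", "L", "F", "Y")) {
  stopifnot(all(anchor_position_2 %in% aa_alphabet()),
            all(anchor_terminal %in% aa_alphabet()))
  structure(list(anchor_position_2 = anchor_position_2,
                 anchor_terminal = anchor_terminal),
            class = "motif_oracle")
}

#' @export
predict_presented.motif_oracle <- function(predictor, peptides) {
  out <- rep(NA, length(peptides))
  clear <- !has_unknown_residue(peptides)
  p2 <- substring(peptides[clear], 2L, 2L)
  pc <- substring(peptides[clear], nchar(peptides[clear]),
                  nchar(peptides[clear]))
  out[clear] <- p2 %in% predictor$anchor_position_2 &
    pc %in% predictor$anchor_terminal
  out
}

#' @export
print.motif_oracle <- function(x, ...) {
  cat("Motif presentation oracle\n")
  cat("  position-2 anchors:", paste(x$anchor_position_2, collapse = ""), "\n")
  cat("  terminal anchors:  ", paste(x$anchor_terminal, collapse = ""), "\n")
  frac <- (length(x$anchor_position_2) / 20) * (length(x$anchor_terminal) / 20)
  cat(sprintf("  expected presented fraction (uniform peptides): %.3f\n", frac))
  invisible(x)
}

#' Generate an oracle-labeled random peptide set
#'
#' Samples uniform random peptides and labels them with a reference
#' presentation predictor, mirroring the construction of the PWM training and
#' calibration pools from a large random peptide sample labeled by a
#' reference predictor.
#'
#' @param oracle A presentation predictor (typically [motif_oracle()]).
#' @param n Number of peptides.
#' @param lengths Peptide lengths; subset of `c(8, 9, 10)`.
#' @param seed Integer seed.
#' @return A [labeled_peptides()] set.
#' @export
generate_labeled_set <- function(oracle, n, lengths = c(8L, 9L, 10L),
                                 seed = NULL) {
  pep <- sample_random_peptides(n, lengths, seed)
  labeled_peptides(pep, if (n > 0) predict_presented(oracle, pep) else logical(0),
                   source = predictor_name(oracle))
}

#' Generate a toy backbone structure
#'
#' Ideal-geometry single-chain backbones (N, CA, C, O per residue) for use as
#' structure prompts: `helix` uses standard alpha-helical rise/twist (1.5 A
#' rise, 100 degrees per residue, CA radius 2.3 A), `strand` an extended
#' zig-zag, and `mixed` alternating helical and extended segments. Optional
#' seeded Gaussian coordinate noise emulates experimental uncertainty.
#'
#' @param length Number of residues (>= 1).
#' @param topology One of `"helix"`, `"strand"`, `"mixed"`.
#' @param noise_sigma Std. dev. (Angstrom) of i.i.d. Gaussian noise added to
#'   every coordinate (default 0).
#' @param seed Integer seed for the noise.
#' @return A `backbone_structure` (see [backbone_structure()]).
#' @export
generate_backbone <- function(length, topology = c("helix", "strand", "mixed"),
                              noise_sigma = 0, seed = NULL) {
  topology <- match.arg(topology)
  if (length < 1) stop("`length` must be >= 1")
  L <- as.integer(length)
  if (!is.null(seed)) set.seed(seed)

  seg <- switch(topology,
    helix = rep("H", L),
    strand = rep("E", L),
    mixed = {
      # alternating 12-residue helices and 6-residue strands
      unlist(lapply(seq_len(ceiling(L / 18)), function(i)
        c(rep("H", 12), rep("E", 6))))[seq_len(L)]
    })

  ca <- matrix(0, L, 3)
  t_h <- 0      # running helical phase
  pos <- c(0, 0, 0)
  dirz <- 1
  for (i in seq_len(L)) {
    if (seg[i] == "H") {
      ca[i, ] <- c(2.3 * cos(t_h), 2.3 * sin(t_h), pos[3])
      t_h <- t_h + 100 * pi / 180
      pos[3] <- pos[3] + 1.5
    } else {
      # extended strand: ~3.4 A rise with lateral zig-zag
      ca[i, ] <- c(2.3 + 1.0 * (i %% 2), 0, pos[3])
      pos[3] <- pos[3] + 3.4 * dirz * 1
    }
  }
  coords <- array(NA_real_, dim = c(L, 4, 3),
                  dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  coords[, "CA", ] <- ca
  # place N toward the previous CA and C toward the next, O off the C
  for (i in seq_len(L)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - c(1, 1, 1) / sqrt(3) * 3.8
    nxt <- if (i < L) ca[i + 1, ] else ca[i, ] + c(1, 1, 1) / sqrt(3) * 3.8
    u_prev <- (prev - ca[i, ]) / sqrt(sum((prev - ca[i, ])^2))
    u_next <- (nxt - ca[i, ]) / sqrt(sum((nxt - ca[i, ])^2))
    coords[i, "N", ] <- ca[i, ] + 1.46 * u_prev
    coords[i, "C", ] <- ca[i, ] + 1.52 * u_next
    # carbonyl O ~1.23 A from C, off the CA->C axis
    perp <- pracma_cross(u_next, u_prev)
    if (sqrt(sum(perp^2)) < 1e-8) perp <- c(0, 0, 1)
    perp <- perp / sqrt(sum(perp^2))
    coords[i, "O", ] <- coords[i, "C", ] + 1.23 * perp
  }
  if (noise_sigma > 0)
    coords <- coords + array(stats::rnorm(L * 4 * 3, sd = noise_sigma),
                             dim = dim(coords))
  backbone_structure(coords, chain = rep("A", L), resno = seq_len(L))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Draw a native-like template sequence
#'
#' Residues are drawn i.i.d. from the natural background composition
#' ([aa_background()]). Used where a composition-realistic but
#' structure-agnostic sequence suffices; [generate_native_sequence()] is the
#' structure-aware generator used for pretraining and recovery references.
#'
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return Amino-acid string.
#' @export
generate_template_sequence <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- aa_background()
  paste(sample(names(f), length, replace = TRUE, prob = f), collapse = "")
}

# secondary-structure-dependent residue propensities (helix formers vs
# beta-branched strand formers), loosely Chou-Fasman shaped
ss_compositions <- function() {
  helix <- c(A = 0.15, L = 0.15, E = 0.10, K = 0.09, Q = 0.07, R = 0.07,
             M = 0.05, I = 0.06, D = 0.05, F = 0.04, S = 0.04, T = 0.03,
             N = 0.03, V = 0.03, W = 0.01, Y = 0.02, H = 0.02, G = 0.015,
             C = 0.01, P = 0.005)
  strand <- c(V = 0.15, I = 0.12, L = 0.09, F = 0.09, Y = 0.08, T = 0.09,
              W = 0.04, C = 0.03, M = 0.03, A = 0.06, S = 0.06, Q = 0.03,
              R = 0.03, K = 0.03, E = 0.03, D = 0.02, N = 0.02, H = 0.02,
              G = 0.02, P = 0.005)
  list(helix = helix[aa_alphabet()] / sum(helix),
       strand = strand[aa_alphabet()] / sum(strand))
}

#' Draw a structure-dependent native sequence for a toy backbone
#'
#' Classifies each residue as helical or extended from its CA geometry
#' (the CA(i)-CA(i+2) distance is ~5.5 A in a helix and ~6.8 A in a strand)
#' and draws the residue from secondary-structure-dependent amino-acid
#' propensities (helix formers A/L/E/K..., beta-branched strand formers
#' V/I/T/F/Y...). This makes the native sequence *predictable from the
#' backbone*, as in real proteins, so that a structure-conditioned model
#' attains above-chance sequence recovery and the visibility/recovery
#' trade-off of preference tuning is measurable. Hydrophobic residues
#' (including the MHC-I anchor-prone L/V/I/M/F/Y) carry substantial mass in
#' both propensity sets, again as in natural sequences.
#'
#' @param structure A [backbone_structure()].
#' @param seed Integer seed.
#' @return Amino-acid string of the structure's length.
#' @export
generate_native_sequence <- function(structure, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comps <- ss_compositions()
  L <- n_residues(structure)
  ca <- matrix(structure$coords[, "CA", ], nrow = L)
  d2 <- rep(NA_real_, L)
  if (L > 2) d2[seq_len(L - 2)] <- sqrt(rowSums((ca[seq_len(L - 2), , drop = FALSE] -
                                                 ca[3:L, , drop = FALSE])^2))
  d2[is.na(d2)] <- d2[max(which(!is.na(d2)), 1)]
  if (all(is.na(d2))) d2 <- rep(5.5, L)
  seg <- ifelse(d2 < 6.0, "helix", "strand")
  res <- vapply(seg, function(s)
    sample(aa_alphabet(), 1L, prob = comps[[s]]), character(1))
  paste(res, collapse = "")
}
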