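# Backbone-structure container and PDB input/output (via bio3d).

#' Backbone structure container
#'
#' Per-residue backbone atom coordinates (N, CA, C, O, in Angstrom), the
#' conditioning prompt of the sequence-design model.
#'
#' @param coords Numeric array `L x 4 x 3`; second dimension named
#'   `N, CA, C, O`.
#' @param chain Character vector of chain identifiers (length `L`).
#' @param resno Integer residue numbers, strictly increasing within a chain.
#' @param sequence Optional native amino-acid sequence (length-`L` string).
#' @return A `backbone_structure` object.
#' @export
backbone_structure <- function(coords, chain = NULL, resno = NULL,
                               sequence = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[2] == 4L, dim(coords)[3] == 3L)
  L <- dim(coords)[1]
  if (!all(is.finite(coords))) stop("backbone coordinates must be finite")
  if (is.null(chain)) chain <- rep("A", L)
  if (is.null(resno)) resno <- seq_len(L)
  for (ch in unique(chain)) {
    r <- resno[chain == ch]
    if (any(diff(r) <= 0))
      stop("residue numbers must be strictly increasing within chain ", ch)
  }
  dimnames(coords) <- list(NULL, c("N", "CA", "C", "O"), NULL)
  structure(list(coords = coords, chain = chain, resno = as.integer(resno),
                 sequence = sequence),
            class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat("Backbone structure: ", dim(x$coords)[1], " residues, ",
      length(unique(x$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

n_residues <- function(structure) dim(structure$coords)[1]

ca_coords <- function(structure) structure$coords[, "CA", , drop = TRUE]

#' Read backbone coordinates from a PDB file
#'
#' Extracts N, CA, C and O atoms per residue (first model, first altloc) with
#' `bio3d::read.pdb`. Residues missing any of the four atoms are dropped.
#'
#' @param path PDB file path.
#' @return A [backbone_structure()].
#' @export
read_backbone_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$elety %in% c("N", "CA", "C", "O") & at$type == "ATOM", ]
  if (!is.null(at$alt)) {
    keep <- is.na(at$alt) | at$alt %in% c("", "A")
    at <- at[keep, ]
  }
  key <- paste(at$chain, at$resno)
  keys <- unique(key)
  rows <- lapply(keys, function(k) at[key == k, ])
  complete <- vapply(rows, function(r) all(c("N", "CA", "C", "O") %in% r$elety),
                     logical(1))
  rows <- rows[complete]
  L <- length(rows)
  if (L == 0L) stop("no complete backbone residues in ", path)
  coords <- array(NA_real_, dim = c(L, 4, 3))
  chain <- character(L); resno <- integer(L); seqv <- character(L)
  for (i in seq_len(L)) {
    r <- rows[[i]]
    for (j in seq_along(c("N", "CA", "C", "O"))) {
      a <- c("N", "CA", "C", "O")[j]
      rr <- r[r$elety == a, ][1, ]
      coords[i, j, ] <- c(rr$x, rr$y, rr$z)
    }
    chain[i] <- r$chain[1]
    resno[i] <- r$resno[1]
    seqv[i] <- bio3d::aa321(r$resid[1])
  }
  seqv[!(seqv %in% aa_alphabet())] <- "X"
  backbone_structure(coords, chain, resno,
                     sequence = paste(seqv, collapse = ""))
}

#' Write a backbone structure to a PDB file
#'
#' @param structure A [backbone_structure()].
#' @param path Output path.
#' @param sequence Optional amino-acid string used for residue names
#'   (defaults to the structure's own sequence, else glycine).
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(structure, path, sequence = NULL) {
  L <- n_residues(structure)
  if (is.null(sequence)) sequence <- structure$sequence
  res1 <- if (is.null(sequence)) rep("G", L) else strsplit(sequence, "")[[1]]
  res3 <- vapply(res1, function(a)
    if (a == "X") "UNK" else bio3d::aa123(a), character(1))
  atoms <- c("N", "CA", "C", "O")
  n_at <- L * 4L
  xyz <- numeric(0)
  for (i in seq_len(L)) for (j in 1:4) xyz <- c(xyz, structure$coords[i, j, ])
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rep("ATOM", n_at),
    resno = rep(structure$resno, each = 4L),
    resid = rep(res3, each = 4L),
    chain = rep(structure$chain, each = 4L),
    eleno = seq_len(n_at),
    elety = rep(atoms, L)
  )
  invisible(path)
}

#' Read / write FASTA sequence files
#'
#' Minimal multi-record FASTA interchange for design inputs and outputs.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  names(out) <- names(recs)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, as.string = TRUE)
  invisible(path)
}
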