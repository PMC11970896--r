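# Design generation, selection and evaluation.

#' Generate candidate designs for a backbone
#'
#' Samples `n` sequences at the given temperature (the design-generation
#' protocol uses 3 candidates at temperature 0.1) and annotates each with its
#' distinct amino-acid count and, when a predictor is supplied, its absolute
#' immune visibility.
#'
#' @param model A `design_model`.
#' @param structure A [backbone_structure()].
#' @param n Number of candidates (default 3).
#' @param temperature Sampling temperature (default 0.1).
#' @param predictor Optional presentation predictor for visibility scoring.
#' @param seed Optional integer seed.
#' @return List of `design_candidate`s: `sequence`, `distinct_aa_count`,
#'   `visibility` (or `NA`), `tm_score` (`NA` until scored),
#'   `predicted_structure` (`NULL` until predicted).
#' @export
generate_candidates <- function(model, structure, n = 3L, temperature = 0.1,
                                predictor = NULL, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_backbone(model, structure)
  lapply(seq_len(n), function(i) {
    sm <- sample_sequence(model, temperature = temperature, encoding = enc)
    cand <- list(
      sequence = sm$sequence,
      distinct_aa_count = length(unique(strsplit(sm$sequence, "")[[1]])),
      visibility = if (is.null(predictor)) NA_integer_ else
        absolute_visibility(sm$sequence, predictor)$absolute_visibility,
      tm_score = NA_real_,
      predicted_structure = NULL)
    class(cand) <- "design_candidate"
    cand
  })
}

#' Filter low-diversity candidates
#'
#' Removes candidate sequences with fewer than 10 distinct amino-acid types
#' (the near-constant-chain failure mode of aggressive checkpoints). The rule
#' is strict: exactly 10 types is retained.
#'
#' @param candidates List of `design_candidate`s.
#' @return The retained candidates (possibly empty; the caller marks the
#'   design failed in that case).
#' @export
filter_low_diversity <- function(candidates) {
  Filter(function(c) c$distinct_aa_count >= 10L, candidates)
}

#' Select the final design among scored candidates
#'
#' If any candidate has a TM-score above 0.9, the least visible of those is
#' chosen; otherwise the candidate with the maximum TM-score. Both
#' comparisons are strict (`> 0.9`); ties are broken by the first candidate
#' in input order. An empty candidate list returns `NULL`.
#'
#' @param candidates List of `design_candidate`s with `tm_score` and
#'   `visibility` filled.
#' @return The selected `design_candidate`, or `NULL`.
#' @export
select_design <- function(candidates) {
  if (length(candidates) == 0L) return(NULL)
  tm <- vapply(candidates, `[[`, numeric(1), "tm_score")
  vis <- vapply(candidates, function(c) as.numeric(c$visibility), numeric(1))
  high <- which(tm > 0.9)
  if (length(high) > 0) {
    candidates[[high[which.min(vis[high])]]]
  } else {
    candidates[[which.max(tm)]]
  }
}

#' Sequence recovery
#'
#' Fraction of positions at which the designed sequence matches the template
#' sequence (symmetric in its arguments).
#'
#' @param design,template Equal-length amino-acid strings.
#' @return Real in `[0, 1]`.
#' @export
sequence_recovery <- function(design, template) {
  if (nchar(design) != nchar(template))
    stop("sequences must have equal length")
  a <- strsplit(design, "")[[1]]
  b <- strsplit(template, "")[[1]]
  mean(a == b)
}

# ---------------------------------------------------------------------------
# TM-score

kabsch_rotation <- function(P, Q) {
  # rotation R minimizing ||P %*% R - Q|| (both n x 3, centered):
  # orthogonal Procrustes solution with a reflection guard
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' TM-score between two backbone structures
#'
#' Built-in backend: assumes positional residue correspondence (fixed-backbone
#' design, equal lengths, no alignment search), superposes by iterative
#' Kabsch fitting (refitting on the residues closer than a distance cutoff
#' until the aligned subset stabilizes) and reports
#' `max over iterations of (1/L_ref) * sum 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 * (L_ref - 15)^(1/3) - 1.8` (floored at 0.5), normalized by the
#' length of `reference`. External backend: parses the TMalign executable's
#' output (score normalized by the reference length); it errors when TMalign
#' is not installed rather than silently returning 0 (0 is reserved for
#' failed structure predictions).
#'
#' @param structure A [backbone_structure()] to score.
#' @param reference The reference/template [backbone_structure()]
#'   (normalization length).
#' @param backend `"builtin"` or `"tmalign"`.
#' @param tmalign_path Path of the TMalign executable for the external
#'   backend.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(structure, reference, backend = c("builtin", "tmalign"),
                     tmalign_path = "TMalign") {
  backend <- match.arg(backend)
  if (backend == "tmalign") return(tm_score_tmalign(structure, reference,
                                                    tmalign_path))
  A <- matrix(structure$coords[, "CA", ], ncol = 3)
  B <- matrix(reference$coords[, "CA", ], ncol = 3)
  if (nrow(A) != nrow(B))
    stop("builtin TM-score backend requires equal-length structures")
  L <- nrow(B)
  d0 <- max(1.24 * (max(L, 16) - 15)^(1 / 3) - 1.8, 0.5)
  subset <- seq_len(L)
  best <- 0
  for (iter in 1:20) {
    Pc <- sweep(A[subset, , drop = FALSE], 2,
                colMeans(A[subset, , drop = FALSE]))
    Qc <- sweep(B[subset, , drop = FALSE], 2,
                colMeans(B[subset, , drop = FALSE]))
    R <- kabsch_rotation(Pc, Qc)
    A_rot <- sweep(A, 2, colMeans(A[subset, , drop = FALSE])) %*% R
    A_fit <- sweep(A_rot, 2, colMeans(B[subset, , drop = FALSE]), "+")
    d <- sqrt(rowSums((A_fit - B)^2))
    best <- max(best, sum(1 / (1 + (d / d0)^2)) / L)
    new_subset <- which(d < max(d0, 4.5))
    if (length(new_subset) < 3L || identical(new_subset, subset)) break
    subset <- new_subset
  }
  best
}

tm_score_tmalign <- function(structure, reference, tmalign_path) {
  if (Sys.which(tmalign_path) == "")
    stop("TMalign executable not found (", tmalign_path, "); ",
         "use backend = \"builtin\" or install TMalign")
  fa <- tempfile(fileext = ".pdb"); fb <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fa, fb)))
  write_backbone_pdb(structure, fa)
  write_backbone_pdb(reference, fb)
  out <- system2(tmalign_path, c(fa, fb), stdout = TRUE)
  ln <- grep("TM-score=.*Chain_2", out, value = TRUE)
  if (length(ln) == 0) ln <- grep("TM-score=", out, value = TRUE)[2]
  as.numeric(sub(".*TM-score= *([0-9.]+).*", "\\1", ln[1]))
}

# ---------------------------------------------------------------------------
# Structure-prediction backends

#' Stub structure-prediction backend
#'
#' Returns the template backbone perturbed with seeded Gaussian coordinate
#' noise, so the TM > 0.9 selection gate and the failure path are exercisable
#' without a folding engine. `fail_rate` makes the backend return `NULL`
#' (prediction failed; the caller assigns TM-score 0) for a random fraction
#' of calls.
#'
#' @param noise_sigma Noise std. dev. per coordinate in Angstrom
#'   (default 0.3, sub-Angstrom like a high-confidence prediction).
#' @param fail_rate Probability of a failed prediction (default 0).
#' @return A backend function `(sequence, template_structure) -> `
#'   [backbone_structure()] or `NULL`.
#' @export
structure_stub_backend <- function(noise_sigma = 0.3, fail_rate = 0) {
  force(noise_sigma); force(fail_rate)
  function(sequence, template_structure) {
    if (fail_rate > 0 && stats::runif(1) < fail_rate) return(NULL)
    co <- template_structure$coords
    co <- co + array(stats::rnorm(length(co), sd = noise_sigma), dim = dim(co))
    backbone_structure(co, template_structure$chain, template_structure$resno,
                       sequence = sequence)
  }
}

#' Design a sequence for a template backbone
#'
#' The full design protocol: sample `n` candidates (temperature 0.1 default),
#' drop low-diversity ones, predict a structure per survivor
#' (failed predictions score TM 0), and apply the selection rule of
#' [select_design()].
#'
#' @inheritParams generate_candidates
#' @param structure_backend A structure-prediction backend (see
#'   [structure_stub_backend()]).
#' @return The selected `design_candidate` (with `tm_score`,
#'   `predicted_structure`), or `NULL` if every candidate was filtered out.
#' @export
design_sequence <- function(model, structure, predictor,
                            structure_backend = structure_stub_backend(),
                            n = 3L, temperature = 0.1, seed = NULL) {
  cands <- generate_candidates(model, structure, n = n,
                               temperature = temperature,
                               predictor = predictor, seed = seed)
  cands <- filter_low_diversity(cands)
  if (length(cands) == 0L) return(NULL)
  cands <- lapply(cands, function(cand) {
    pred <- structure_backend(cand$sequence, structure)
    if (is.null(pred)) {
      cand$tm_score <- 0   # failed structure prediction
    } else {
      cand$predicted_structure <- pred
      cand$tm_score <- tm_score(pred, structure)
    }
    cand
  })
  select_design(cands)
}

#' Evaluate a model checkpoint on a set of backbones
#'
#' Per backbone, either a single sample (`protocol = "single"`, the
#' large-set protocol) or the 3-candidate selection protocol
#' (`protocol = "best_of_3"`). Reports per-structure rows (visibility,
#' relative visibility against the template sequence, sequence recovery, and
#' TM-score under the best-of-3 protocol) plus their arithmetic means.
#' Mean relative visibility is the mean of per-structure ratios.
#'
#' @param model A `design_model` checkpoint.
#' @param structures List of evaluation [backbone_structure()]s.
#' @param sequences Native/template sequences (one per structure).
#' @param predictor Presentation predictor for visibility.
#' @param protocol `"single"` or `"best_of_3"`.
#' @param structure_backend Structure-prediction backend (best-of-3 only).
#' @param temperature Sampling temperature (default 1 for `"single"`,
#'   0.1 for `"best_of_3"`).
#' @param seed Integer seed.
#' @return A `tradeoff_record`: list with `rows` (data frame) and the means
#'   `mean_visibility`, `mean_relative_visibility`, `mean_recovery`,
#'   `mean_tm_score`.
#' @export
evaluate_checkpoint <- function(model, structures, sequences, predictor,
                                protocol = c("single", "best_of_3"),
                                structure_backend = structure_stub_backend(),
                                temperature = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  if (length(structures) == 0L) stop("empty evaluation set")
  stopifnot(length(sequences) == length(structures))
  if (is.null(temperature))
    temperature <- if (protocol == "single") 1.0 else 0.1
  set.seed(seed)
  rows <- list()
  for (i in seq_along(structures)) {
    template_vis <- absolute_visibility(sequences[[i]],
                                        predictor)$absolute_visibility
    if (protocol == "single") {
      enc <- encode_backbone(model, structures[[i]])
      sm <- sample_sequence(model, temperature = temperature, encoding = enc)
      seq_i <- sm$sequence
      tm_i <- NA_real_
      vis_i <- absolute_visibility(seq_i, predictor)$absolute_visibility
    } else {
      sel <- design_sequence(model, structures[[i]], predictor,
                             structure_backend, temperature = temperature)
      if (is.null(sel)) {
        seq_i <- NA_character_; tm_i <- 0; vis_i <- NA_integer_
      } else {
        seq_i <- sel$sequence; tm_i <- sel$tm_score; vis_i <- sel$visibility
      }
    }
    rows[[i]] <- data.frame(
      structure = i,
      visibility = vis_i,
      template_visibility = template_vis,
      relative_visibility = relative_visibility(vis_i, template_vis),
      recovery = if (is.na(seq_i)) NA_real_ else
        sequence_recovery(seq_i, sequences[[i]]),
      tm_score = tm_i)
  }
  rows <- do.call(rbind, rows)
  out <- list(rows = rows,
              protocol = protocol,
              n = nrow(rows),
              mean_visibility = mean(rows$visibility, na.rm = TRUE),
              mean_relative_visibility = mean(rows$relative_visibility,
                                              na.rm = TRUE),
              mean_recovery = mean(rows$recovery, na.rm = TRUE),
              mean_tm_score = mean(rows$tm_score, na.rm = TRUE))
  class(out) <- "tradeoff_record"
  out
}

#' @export
print.tradeoff_record <- function(x, ...) {
  cat("Checkpoint evaluation (", x$protocol, " protocol, n=", x$n, ")\n",
      sep = "")
  cat(sprintf("  mean visibility:          %.2f\n", x$mean_visibility))
  cat(sprintf("  mean relative visibility: %.3f\n", x$mean_relative_visibility))
  cat(sprintf("  mean sequence recovery:   %.3f\n", x$mean_recovery))
  if (!is.nan(x$mean_tm_score) && !all(is.na(x$rows$tm_score)))
    cat(sprintf("  mean TM-score:            %.3f\n", x$mean_tm_score))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Optional external netMHCpan adapter and rank histogram

#' External netMHCpan adapter (optional)
#'
#' Wraps a locally installed netMHCpan executable behind the presentation
#' predictor interface: per peptide, the best percentile rank across the
#' patient's alleles is compared against the rank cutoff (2% includes weak
#' binders; 0.5% restricts to strong binders). Construction fails with a
#' clear message when the executable is absent; this package's workflows
#' default to the PWM classifier and the motif oracle instead.
#'
#' @param alleles HLA allele names passed to netMHCpan.
#' @param rank_cutoff Presented iff best rank below this percentage
#'   (default 2).
#' @param path Executable name or path.
#' @return A `netmhcpan_adapter` predictor.
#' @export
netmhcpan_adapter <- function(alleles, rank_cutoff = 2.0, path = "netMHCpan") {
  if (Sys.which(path) == "")
    stop("netMHCpan executable not found at '", path,
         "'; the external adapter is optional - use the PWM classifier ",
         "or motif oracle instead")
  out <- list(alleles = alleles, rank_cutoff = rank_cutoff, path = path)
  class(out) <- "netmhcpan_adapter"
  out
}

#' @export
predict_presented.netmhcpan_adapter <- function(predictor, peptides) {
  ranks <- netmhcpan_best_ranks(predictor, peptides)
  out <- rep(NA, length(peptides))
  clear <- !has_unknown_residue(peptides)
  out[clear] <- ranks[clear] < predictor$rank_cutoff
  out
}

netmhcpan_best_ranks <- function(adapter, peptides) {
  pf <- tempfile(fileext = ".txt")
  on.exit(unlink(pf))
  writeLines(peptides, pf)
  best <- rep(Inf, length(peptides))
  for (al in adapter$alleles) {
    out <- system2(adapter$path, c("-p", pf, "-a", al), stdout = TRUE)
    dat <- out[grepl("^\\s*\\d+\\s+HLA", out)]
    for (ln in dat) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      pep <- f[3]; rank <- suppressWarnings(as.numeric(f[13]))
      idx <- which(peptides == pep)
      if (length(idx) && is.finite(rank)) best[idx] <- pmin(best[idx], rank)
    }
  }
  best
}

#' Histogram of per-k-mer best presentation ranks
#'
#' Bins the best percentile rank (across alleles) of every 8-10-mer of a
#' sequence into presentation categories; the lowest bin (0-0.5%) holds
#' strong binders and the second (0.5-2%) weak binders. Ranks may come from
#' the external netMHCpan adapter or any other source; the bins partition all
#' k-mers, so the counts sum to the total window count.
#'
#' @param sequence Amino-acid string.
#' @param ranks Numeric vector of best ranks (percent), one per k-mer of
#'   [enumerate_kmers()] in that order; alternatively a
#'   [netmhcpan_adapter()] via `adapter` to compute them.
#' @param adapter Optional `netmhcpan_adapter`.
#' @param breaks Rank bin edges in percent (default
#'   `c(0, 0.5, 2, 10, 50, 100)`).
#' @return Named integer vector of counts per bin.
#' @export
rank_category_histogram <- function(sequence, ranks = NULL, adapter = NULL,
                                    breaks = c(0, 0.5, 2, 10, 50, 100)) {
  kmers <- enumerate_kmers(sequence)
  if (nrow(kmers) == 0L) {
    h <- integer(length(breaks) - 1L)
    names(h) <- paste0("(", utils::head(breaks, -1), ",", breaks[-1], "]")
    return(h)
  }
  if (is.null(ranks)) {
    if (is.null(adapter)) stop("supply `ranks` or a netMHCpan `adapter`")
    ranks <- netmhcpan_best_ranks(adapter, kmers$peptide)
  }
  if (length(ranks) != nrow(kmers))
    stop("`ranks` must have one entry per enumerated k-mer")
  ranks <- pmin(pmax(ranks, min(breaks)), max(breaks))
  tab <- table(cut(ranks, breaks, include.lowest = TRUE))
  h <- as.integer(tab)
  names(h) <- names(tab)
  h
}
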