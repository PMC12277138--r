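#' Specification of a planted bipartite block model
#'
#' The synthetic generator used throughout the test suite: circRNAs and drugs
#' are assigned to `n_blocks` blocks round-robin, and each circRNA-drug pair
#' is positive with probability `p_in` when the two nodes share a block and
#' `p_out` otherwise. With `p_in > p_out` this plants recoverable structure a
#' link predictor can exploit; with `p_in = p_out` there is none and held-out
#' AUC should sit near 0.5. Defaults emulate the scale of the curated
#' sensitivity screen the method was developed on (271 circRNAs x 218 drugs,
#' 4,314 positive associations).
#'
#' @param n_circ,n_drug Node counts per side.
#' @param n_blocks Number of planted blocks (<= both side sizes).
#' @param p_in,p_out Within-/between-block positive probabilities,
#'   `0 <= p_out < p_in <= 1` (equality allowed for null designs).
#' @param n_pos Optional exact number of positives: sampled edges are
#'   subsampled (or the draw repeated with enrichment) to hit this count.
#' @param seed Integer seed.
#' @return A list of class `block_model_spec`.
#' @export
block_model_spec <- function(n_circ = 271L, n_drug = 218L, n_blocks = 4L,
                             p_in = 0.3, p_out = 0.02, n_pos = NULL,
                             seed = 1L) {
  if (!is_count(n_circ, 1L) || !is_count(n_drug, 1L)) {
    abort("`n_circ` and `n_drug` must be positive integers.")
  }
  if (!is_count(n_blocks, 1L) || n_blocks > min(n_circ, n_drug)) {
    abort("`n_blocks` must be a positive integer <= min(n_circ, n_drug).")
  }
  if (!is_prob(p_in) || !is_prob(p_out) || p_out > p_in || p_in == 0) {
    abort("Need 0 <= p_out <= p_in <= 1 with p_in > 0.")
  }
  if (!is.null(n_pos) && !is_count(n_pos, 1L)) {
    abort("`n_pos` must be NULL or a positive integer.")
  }
  structure(list(n_circ = as.integer(n_circ), n_drug = as.integer(n_drug),
                 n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
                 n_pos = if (is.null(n_pos)) NULL else as.integer(n_pos),
                 seed = as.integer(seed)),
            class = "block_model_spec")
}

# Round-robin block assignment: node i -> block ((i - 1) mod n_blocks) + 1.
block_of <- function(n, n_blocks) ((seq_len(n) - 1L) %% n_blocks) + 1L

#' Generate a positive association table from a planted block model
#'
#' @param spec A [block_model_spec()].
#' @return A tibble with columns `circ_id` (`circ_1..`), `drug_id`
#'   (`drug_1..`) and `label` (all 1). Every circRNA and drug id appears in
#'   the attribute `"ids"` even if isolated.
#' @export
generate_block_model <- function(spec) {
  stopifnot(inherits(spec, "block_model_spec"))
  bc <- block_of(spec$n_circ, spec$n_blocks)
  bd <- block_of(spec$n_drug, spec$n_blocks)
  same <- outer(bc, bd, "==")
  pmat <- ifelse(same, spec$p_in, spec$p_out)
  if (sum(pmat) == 0) abort("Expected positive count is zero.")
  draw <- with_seed(spec$seed, {
    hits <- which(matrix(rbinom(length(pmat), 1L, pmat),
                         spec$n_circ, spec$n_drug) == 1L, arr.ind = TRUE)
    if (!is.null(spec$n_pos)) {
      if (nrow(hits) >= spec$n_pos) {
        hits <- hits[sample.int(nrow(hits), spec$n_pos), , drop = FALSE]
      } else {
        # top up from still-unsampled pairs, weighted by their probability
        all_idx <- seq_along(pmat)
        taken <- (hits[, 2] - 1L) * spec$n_circ + hits[, 1]
        pool <- setdiff(all_idx, taken)
        need <- spec$n_pos - nrow(hits)
        if (need > length(pool)) abort("`n_pos` exceeds the number of pairs.")
        extra <- sample(pool, need, prob = pmat[pool] + 1e-9)
        hits <- rbind(hits, cbind((extra - 1L) %% spec$n_circ + 1L,
                                  (extra - 1L) %/% spec$n_circ + 1L))
      }
    }
    hits
  })
  if (nrow(draw) == 0) abort("No positive association was sampled.")
  draw <- draw[order(draw[, 1], draw[, 2]), , drop = FALSE]
  out <- tibble::tibble(
    circ_id = paste0("circ_", draw[, 1]),
    drug_id = paste0("drug_", draw[, 2]),
    label = 1L
  )
  attr(out, "ids") <- list(circ_ids = paste0("circ_", seq_len(spec$n_circ)),
                           drug_ids = paste0("drug_", seq_len(spec$n_drug)),
                           circ_block = bc, drug_block = bd)
  out
}

#' Generate synthetic circRNA sequences
#'
#' I.i.d. uniform nucleotide strings over \{A,C,G,T\}; when `motif` is given,
#' ids sharing a planted block receive that block's copy of the motif at a
#' random position, so k-mer similarity correlates with block membership.
#' Sequences are synthetic stand-ins for real circRNA sequence data, not an
#' imitation of real base composition.
#'
#' @param circ_ids Character vector of ids.
#' @param length Sequence length (same for all).
#' @param seed Integer seed.
#' @param motif Optional motif length (integer >= 4): each block gets its own
#'   random motif of that length, planted once per sequence.
#' @param blocks Optional integer block assignment aligned with `circ_ids`
#'   (required when `motif` is given).
#' @return A named character vector (see [read_sequences()] for the same
#'   shape from FASTA input).
#' @export
generate_sequences <- function(circ_ids, length = 200L, seed = 1L,
                               motif = NULL, blocks = NULL) {
  if (!is_count(length, 1L)) abort("`length` must be a positive integer.")
  nts <- c("A", "C", "G", "T")
  with_seed(seed, {
    seqs <- vapply(seq_along(circ_ids), function(i) {
      paste(sample(nts, length, replace = TRUE), collapse = "")
    }, character(1))
    if (!is.null(motif)) {
      if (is.null(blocks) || length(blocks) != base::length(circ_ids)) {
        abort("`blocks` must align with `circ_ids` when planting motifs.")
      }
      if (!is_count(motif, 4L)) abort("`motif` must be an integer >= 4.")
      if (motif > length) abort("Motif longer than the sequence.")
      motifs <- vapply(seq_len(max(blocks)), function(b) {
        paste(sample(nts, motif, replace = TRUE), collapse = "")
      }, character(1))
      for (i in seq_along(seqs)) {
        at <- sample.int(length - motif + 1L, 1L)
        substr(seqs[i], at, at + motif - 1L) <- motifs[blocks[i]]
      }
    }
    setNames(seqs, circ_ids)
  })
}

#' Write a synthetic dataset to standard files
#'
#' Writes the association TSV (and optionally a FASTA of synthetic
#' sequences) so that generated and real data flow through the same readers.
#'
#' @param table An association tibble from [generate_block_model()].
#' @param assoc_path Output TSV path.
#' @param fasta_path Optional FASTA output path; requires `sequences`.
#' @param sequences Named character vector from [generate_sequences()].
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(table, assoc_path, fasta_path = NULL,
                            sequences = NULL) {
  readr::write_tsv(table, assoc_path, col_names = FALSE, progress = FALSE)
  written <- assoc_path
  if (!is.null(fasta_path)) {
    if (is.null(sequences)) abort("`sequences` required to write FASTA.")
    lines <- as.vector(rbind(paste0(">", names(sequences)),
                             unname(sequences)))
    writeLines(lines, fasta_path)
    written <- c(written, fasta_path)
  }
  invisible(written)
}
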