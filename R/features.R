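#' Initial node feature matrices
#'
#' The encoders start from an `(N + M) x d` matrix `H0` whose rows follow the
#' global node index (circRNAs first, then drugs). Five construction schemes
#' are supported, mirroring the feature study of the method: position
#' (adjacency rows), one-hot identities, random uniform/normal, and
#' similarity-based blocks.
#'
#' @name node_features
NULL

#' Position features: rows of the symmetric bipartite adjacency
#'
#' Each node is represented by its row of the symmetric `(N+M) x (N+M)`
#' expansion of the biadjacency matrix: circRNA rows carry `A`, drug rows
#' carry `t(A)`. Row sums therefore equal bipartite degrees.
#'
#' @param graph A `cda_graph`.
#' @return An `(N+M) x (N+M)` numeric matrix.
#' @export
position_features <- function(graph) {
  stopifnot(inherits(graph, "cda_graph"))
  n <- graph$n_circ; m <- graph$n_drug
  H <- matrix(0, n + m, n + m)
  H[seq_len(n), n + seq_len(m)] <- graph$A
  H[n + seq_len(m), seq_len(n)] <- t(graph$A)
  H
}

#' One-hot features: unique node identities
#'
#' @param graph A `cda_graph`.
#' @return The `(N+M) x (N+M)` identity matrix.
#' @export
onehot_features <- function(graph) {
  stopifnot(inherits(graph, "cda_graph"))
  diag(n_nodes(graph))
}

#' Random features (uniform or normal)
#'
#' @param graph A `cda_graph`.
#' @param dist `"uniform"` (i.i.d. on \[0, 1)) or `"normal"` (standard).
#' @param d Feature dimension.
#' @param seed Integer seed; same seed, same matrix.
#' @return An `(N+M) x d` numeric matrix.
#' @export
random_features <- function(graph, dist = c("uniform", "normal"), d = 64L,
                            seed = 1L) {
  stopifnot(inherits(graph, "cda_graph"))
  dist <- match.arg(dist)
  if (!is_count(d, 1L)) abort("`d` must be a positive integer.")
  nn <- n_nodes(graph)
  with_seed(seed, {
    if (dist == "uniform") matrix(runif(nn * d), nn, d)
    else matrix(rnorm(nn * d), nn, d)
  })
}

#' Circular k-mer frequency features for circRNA sequences
#'
#' Counts every k-mer of each sequence with wrap-around (circRNAs are
#' covalently closed, so the junction k-mers are real) and divides by the
#' sequence length; each row sums to exactly 1. Columns enumerate the 4^k
#' DNA k-mers in lexicographic order of A < C < G < T. k-mers containing `N`
#' are counted toward the length but not toward any column.
#'
#' @param seqs Named character vector of sequences over \{A,C,G,T,N\} (see
#'   [read_sequences()]).
#' @param k k-mer length; every sequence must be at least k long.
#' @return A numeric matrix with one row per sequence and `4^k` columns.
#' @export
kmer_features <- function(seqs, k = 4L) {
  if (!is_count(k, 1L)) abort("`k` must be a positive integer.")
  short <- names(seqs)[nchar(seqs) < k]
  if (length(short) > 0) {
    abort(sprintf("Sequence '%s' is shorter than k = %d.", short[1], k))
  }
  alphabet <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(alphabet), k),
                                           stringsAsFactors = FALSE)))
  out <- matrix(0, length(seqs), length(kmers),
                dimnames = list(names(seqs), kmers))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    len <- nchar(s)
    ext <- paste0(s, substr(s, 1, k - 1))
    words <- substring(ext, seq_len(len), seq_len(len) + k - 1)
    counts <- table(factor(words, levels = kmers))
    out[i, ] <- as.numeric(counts) / len
  }
  out
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity between binary interaction profiles (rows or columns of the
#' biadjacency matrix): `K(i, j) = exp(-gamma * ||x_i - x_j||^2)` with the
#' bandwidth normalized by the mean squared profile norm,
#' `gamma = 1 / mean_i(||x_i||^2)` (and `gamma = 1` if all profiles are zero).
#'
#' @param A A binary matrix (biadjacency of the training graph).
#' @param axis `"rows"` (circRNA profiles) or `"cols"` (drug profiles).
#' @return A symmetric similarity matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
gip_kernel <- function(A, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (length(A) == 0) abort("`A` must be non-empty.")
  X <- if (axis == "rows") A else t(A)
  sq <- rowSums(X^2)
  gamma <- if (all(sq == 0)) 1 else 1 / mean(sq)
  G <- tcrossprod(X)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  K <- exp(-gamma * D2)
  diag(K) <- 1
  (K + t(K)) / 2
}

#' Drug structural similarity from SMILES
#'
#' Parses SMILES, computes hashed substructure fingerprints (atom-pair
#' descriptors folded to `bits` bits) and returns pairwise Tanimoto
#' coefficients. Unparsable SMILES raise an error naming the drug rather than
#' being dropped silently.
#'
#' @param smiles Named character vector mapping drug id to SMILES (see
#'   [read_smiles()]).
#' @param bits Fingerprint length.
#' @return A symmetric similarity matrix with unit diagonal over the drugs,
#'   in the input order.
#' @export
structural_similarity <- function(smiles, bits = 1024L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("structural_similarity() requires ChemmineR and ChemmineOB.")
  }
  ids <- names(smiles)
  if (is.null(ids) || any(!nzchar(ids))) abort("SMILES must be named by drug id.")
  sdf <- tryCatch(ChemmineR::smiles2sdf(setNames(as.character(smiles), ids)),
                  error = function(e) abort(sprintf(
                    "Failed to parse SMILES set: %s", conditionMessage(e))))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    abort(sprintf("Unparsable SMILES for drug '%s'.", ids[!ok][1]))
  }
  ap <- ChemmineR::sdf2ap(sdf)
  # desc2fp() looks the reference atom-pair set up on the search path; load
  # it explicitly so an attached ChemmineR is not required
  env <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = env)
  descnames <- as.character(env$apfp$AP[seq_len(min(bits, nrow(env$apfp)))])
  fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "FPset")
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    S[i, ] <- ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE)
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Sequence similarity from k-mer frequency profiles
#'
#' Cosine similarity between k-mer frequency rows, clipped to \[0, 1\], with
#' the diagonal forced to 1. Rows with zero norm get similarity 0 to all
#' other rows.
#'
#' @param feats A k-mer frequency matrix from [kmer_features()].
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
sequence_similarity <- function(feats) {
  nrm <- sqrt(rowSums(feats^2))
  safe <- ifelse(nrm == 0, 1, nrm)
  X <- feats / safe
  S <- tcrossprod(X)
  S[nrm == 0, ] <- 0
  S[, nrm == 0] <- 0
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Fuse two similarity matrices
#'
#' Elementwise arithmetic mean of two similarity matrices of the same shape.
#' If one matrix is `NULL` (the corresponding data source is unavailable),
#' the other is returned unchanged.
#'
#' @param s1,s2 Similarity matrices of identical shape, or `NULL`.
#' @return A similarity matrix.
#' @export
fuse_similarity <- function(s1, s2) {
  if (is.null(s1) && is.null(s2)) abort("Both similarity matrices are NULL.")
  if (is.null(s1)) return(s2)
  if (is.null(s2)) return(s1)
  if (!all(dim(s1) == dim(s2))) abort("Similarity matrices differ in shape.")
  (s1 + s2) / 2
}

#' Similarity-based node features
#'
#' Block layout: circRNA row i is `(Sc[i, ], 0_M)`, drug row j is
#' `(0_N, Sd[j, ])`, giving an `(N+M) x (N+M)` matrix.
#'
#' @param sc circRNA similarity matrix (N x N).
#' @param sd Drug similarity matrix (M x M).
#' @return An `(N+M) x (N+M)` numeric matrix.
#' @export
sim_features <- function(sc, sd) {
  n <- nrow(sc); m <- nrow(sd)
  if (ncol(sc) != n || ncol(sd) != m) abort("Similarity matrices must be square.")
  H <- matrix(0, n + m, n + m)
  H[seq_len(n), seq_len(n)] <- sc
  H[n + seq_len(m), n + seq_len(m)] <- sd
  H
}

# Resolve the configured feature scheme into H0 for a training graph.
# `extras` may carry `sequences` (named character) and `smiles` (named
# character); the sim scheme fuses what is available with the GIP kernel.
build_features <- function(graph, config, extras = list()) {
  switch(config$feature_init,
    position = position_features(graph),
    onehot = onehot_features(graph),
    uniform = random_features(graph, "uniform", config$feature_dim, config$seed),
    normal = random_features(graph, "normal", config$feature_dim, config$seed),
    sim = {
      gip_c <- gip_kernel(graph$A, "rows")
      gip_d <- gip_kernel(graph$A, "cols")
      seq_sim <- NULL
      if (!is.null(extras$sequences)) {
        seqs <- extras$sequences[graph$circ_ids]
        if (anyNA(names(seqs)) || anyNA(seqs)) {
          abort("Sequences missing for some circRNAs in the graph.")
        }
        seq_sim <- sequence_similarity(kmer_features(seqs, config$kmer_k))
      }
      str_sim <- NULL
      if (!is.null(extras$smiles)) {
        sm <- extras$smiles[graph$drug_ids]
        if (anyNA(names(sm)) || anyNA(sm)) {
          abort("SMILES missing for some drugs in the graph.")
        }
        str_sim <- structural_similarity(sm)
      }
      sim_features(fuse_similarity(seq_sim, gip_c),
                   fuse_similarity(str_sim, gip_d))
    }
  )
}
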