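#' @useDynLib syllseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif var
#' @importFrom graphics matplot par
NULL

#' The six syllables of the repetition task, in task order
#'
#' The diadochokinesia task cycles through six consonant-vowel syllables in a
#' fixed order; after the last syllable the sequence wraps around to the first.
#'
#' @return Character vector of the six syllable labels.
#' @export
syllables <- function() c("BA", "DA", "GA", "PA", "TA", "KA")

#' Cyclic successor of a syllable
#'
#' @param name A syllable label (see [syllables()]).
#' @return The next syllable in task order; the last syllable maps back to the
#'   first.
#' @examples
#' next_syllable("BA") # "DA"
#' next_syllable("KA") # "BA"
#' @export
next_syllable <- function(name) {
  syl <- syllables()
  i <- match(name, syl)
  if (is.na(i)) stop("unknown syllable: ", name)
  syl[i %% length(syl) + 1L]
}

#' Execution-pointer label for a syllable
#'
#' Each syllable has a paired execution pointer (`<syllable>_EXEC`) carrying
#' its motor/somatosensory state.
#'
#' @param name A syllable label.
#' @return The `<name>_EXEC` label.
#' @export
exec_pointer <- function(name) {
  if (!name %in% syllables()) stop("not a syllable: ", name)
  paste0(name, "_EXEC")
}

#' Default pointer inventory of the sequencing model
#'
#' Six syllables, their six execution pointers, NEUTRAL (no speech activity)
#' and ZERO (empty screen): 14 pointers in all.
#'
#' @return Character vector of 14 pointer names.
#' @export
default_pointer_names <- function() {
  c(syllables(), vapply(syllables(), exec_pointer, character(1),
                        USE.NAMES = FALSE), "NEUTRAL", "ZERO")
}

#' Create a vocabulary of semantic pointers
#'
#' Samples one unit vector per name uniformly on the D-sphere. Any vector whose
#' absolute dot product with an already-accepted vector exceeds
#' `max_similarity` is resampled, so distinct pointers stay close to
#' orthogonal. Generation is deterministic given `seed`.
#'
#' @param dimension Pointer dimensionality (>= 8; default 32).
#' @param names Unique pointer labels (default: the 14 task pointers).
#' @param seed Integer RNG seed.
#' @param max_similarity Bound on |dot| between distinct pointers.
#' @param max_retries Resampling budget per pointer before the configuration
#'   is declared infeasible.
#' @return A `syllseq_vocab` object: list with `dimension`, `seed`,
#'   `max_similarity`, and `vectors` (a `dimension x length(names)` matrix with
#'   named columns, each of unit Euclidean norm).
#' @export
create_vocabulary <- function(dimension = 32L,
                              names = default_pointer_names(),
                              seed = 1L,
                              max_similarity = 0.5,
                              max_retries = 200L) {
  stopifnot(dimension >= 8, length(names) >= 1)
  if (anyDuplicated(names)) stop("pointer names must be unique")
  vecs <- matrix(0, nrow = dimension, ncol = length(names),
                 dimnames = list(NULL, names))
  rng <- local_rng(seed)
  for (k in seq_along(names)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      v <- rng$norm(dimension)
      v <- v / sqrt(sum(v^2))
      if (k == 1L || all(abs(crossprod(vecs[, seq_len(k - 1L), drop = FALSE],
                                       v)) <= max_similarity)) {
        vecs[, k] <- v
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("infeasible vocabulary: could not satisfy pairwise similarity ",
           "bound ", max_similarity, " for '", names[k], "' after ",
           max_retries, " attempts")
    }
  }
  structure(list(dimension = as.integer(dimension), seed = as.integer(seed),
                 max_similarity = max_similarity, vectors = vecs),
            class = "syllseq_vocab")
}

#' @export
print.syllseq_vocab <- function(x, ...) {
  cat("<syllseq_vocab> D =", x$dimension, "|", ncol(x$vectors), "pointers |",
      "seed", x$seed, "\n")
  cat("  ", paste(colnames(x$vectors), collapse = " "), "\n")
  invisible(x)
}

#' Retrieve a pointer vector from a vocabulary
#'
#' @param vocab A `syllseq_vocab`.
#' @param name Pointer label.
#' @return Numeric unit vector of length `vocab$dimension`.
#' @export
pointer <- function(vocab, name) {
  if (!name %in% colnames(vocab$vectors)) {
    stop("pointer not in vocabulary: ", name)
  }
  vocab$vectors[, name]
}

#' Similarity between a represented state and a pointer
#'
#' The plain dot product, not normalised by the state magnitude: buffer
#' activity stronger than a unit pointer yields similarity above 1.
#'
#' @param state Numeric vector (a decoded buffer state).
#' @param p Pointer vector, or a pointer name together with `vocab`.
#' @param vocab Optional vocabulary used to resolve `p` when it is a name.
#' @return Scalar dot product.
#' @export
similarity <- function(state, p, vocab = NULL) {
  if (is.character(p)) {
    if (is.null(vocab)) stop("vocab needed to resolve pointer name")
    p <- pointer(vocab, p)
  }
  if (length(state) != length(p)) stop("dimension mismatch")
  sum(state * p)
}

#' All pairwise pointer similarities
#'
#' @param vocab A `syllseq_vocab`.
#' @return Symmetric matrix of dot products between all pointers.
#' @export
pairwise_similarity <- function(vocab) crossprod(vocab$vectors)

#' Write / read a vocabulary as JSON
#'
#' Plain-text serialisation (name and vector per pointer) so that a trial can
#' be replayed exactly from its artifacts.
#'
#' @param vocab A `syllseq_vocab`.
#' @param path Output file.
#' @return `path`, invisibly (`write_vocab`); a `syllseq_vocab` (`read_vocab`).
#' @export
write_vocab <- function(vocab, path) {
  obj <- list(dimension = vocab$dimension, seed = vocab$seed,
              max_similarity = vocab$max_similarity,
              pointers = as.list(as.data.frame(vocab$vectors)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vecs <- do.call(cbind, obj$pointers)
  structure(list(dimension = as.integer(obj$dimension),
                 seed = as.integer(obj$seed),
                 max_similarity = obj$max_similarity, vectors = vecs),
            class = "syllseq_vocab")
}
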