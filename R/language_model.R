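#' Internal language model
#'
#' A language model here is simply a vocabulary plus a square matrix of
#' transition probabilities: `prediction[i, j]` is the probability that word
#' `j` follows word `i`. It plays the role of the top-down feedback weights
#' between the higher (context) level and the word level of the network.
#'
#' @param vocabulary character vector of word labels.
#' @param prediction numeric matrix, `length(vocabulary)` square, entries in
#'   `[0, 1]`; rows are contexts, columns predicted words.
#' @return An object of class `"stimcon_lm"`.
#' @seealso [lm_sentences()], [lm_daga()], [lm_chain()]
#' @examples
#' m <- stimcon_lm(c("a", "b"), matrix(c(0, 1, 0, 0), 2, byrow = TRUE))
#' m$prediction["a", "b"]
#' @export
stimcon_lm <- function(vocabulary, prediction) {
  vocabulary <- as.character(vocabulary)
  prediction <- as.matrix(prediction)
  n <- length(vocabulary)
  if (n == 0) stop("vocabulary is empty")
  if (anyDuplicated(vocabulary)) stop("vocabulary labels must be unique")
  if (nrow(prediction) != n || ncol(prediction) != n)
    stop("prediction must be a square matrix matching the vocabulary")
  if (any(!is.finite(prediction)) || any(prediction < 0 | prediction > 1))
    stop("prediction entries must lie in [0, 1]")
  dimnames(prediction) <- list(vocabulary, vocabulary)
  structure(list(vocabulary = vocabulary, prediction = prediction),
            class = "stimcon_lm")
}

#' @export
print.stimcon_lm <- function(x, ...) {
  cat(sprintf("Language model with %d words\n", length(x$vocabulary)))
  print(x$prediction)
  invisible(x)
}

word_index <- function(lm, word) {
  i <- match(word, lm$vocabulary)
  if (anyNA(i)) stop("unknown word(s): ",
                     paste(word[is.na(i)], collapse = ", "))
  i
}

#' Five-word toy language model
#'
#' The model of a network that has seen three sentences at different
#' probabilities: "I eat cake" (0.5), "I eat nice cake" (0.3), and
#' "I eat very nice cake" (0.2). /I/ predicts /eat/ with certainty; after
#' /eat/ the prediction is spread over /cake/, /nice/, /very/; /cake/ predicts
#' nothing.
#'
#' @return A [stimcon_lm()] with vocabulary `I, eat, very, nice, cake`.
#' @examples
#' lm_sentences()$prediction["eat", ]
#' @export
lm_sentences <- function() {
  v <- c("I", "eat", "very", "nice", "cake")
  p <- matrix(0, 5, 5, dimnames = list(v, v))
  p["I", "eat"] <- 1
  p["eat", c("very", "nice", "cake")] <- c(0.2, 0.3, 0.5)
  p["very", "nice"] <- 1
  p["nice", "cake"] <- 1
  stimcon_lm(v, p)
}

#' Four-node /da/-/ga/ language model
#'
#' Two entrainer nodes followed by the two candidate percepts: N1 predicts N2
#' with certainty, and N2 predicts /da/ at 0.2 and /ga/ at 0.1 — the uneven
#' base prediction (/da/ being the more prevalent syllable) that makes
#' categorization of an ambiguous /da/-/ga/ mixture phase-dependent. The
#' equal-feedback ablation uses `lm_daga(0.15, 0.15)`.
#'
#' @param p_da,p_ga prediction probabilities of /da/ and /ga/ given N2.
#' @return A [stimcon_lm()] with vocabulary `N1, N2, da, ga`.
#' @export
lm_daga <- function(p_da = 0.2, p_ga = 0.1) {
  v <- c("N1", "N2", "da", "ga")
  p <- matrix(0, 4, 4, dimnames = list(v, v))
  p["N1", "N2"] <- 1
  p["N2", "da"] <- p_da
  p["N2", "ga"] <- p_ga
  stimcon_lm(v, p)
}

#' Chain language model for word sequences
#'
#' One node per word of a sequence, where word `k` predicts word `k + 1` with
#' the given probability. Used for the rhythmicity experiment, where
#' word-to-word predictability is constant or alternates between low and
#' high.
#'
#' @param probs numeric vector in `[0, 1]`; `probs[k]` is the probability with
#'   which word `k` is predicted by word `k - 1` (the first entry is ignored:
#'   nothing precedes the first word).
#' @param labels optional word labels, default `w1, w2, ...`.
#' @return A [stimcon_lm()].
#' @examples
#' lm_chain(rep(c(0, 0.8), 5))  # alternating low-high predictability
#' @export
lm_chain <- function(probs, labels = paste0("w", seq_along(probs))) {
  n <- length(probs)
  if (n < 2) stop("need at least two words")
  p <- matrix(0, n, n)
  for (k in seq_len(n - 1)) p[k, k + 1] <- probs[k + 1]
  stimcon_lm(labels, p)
}

#' Read / write a language model as JSON
#'
#' Serialized as a vocabulary list plus row-major probability matrix.
#'
#' @param lm a [stimcon_lm()].
#' @param path file path.
#' @return `read_lm_json()` returns a [stimcon_lm()]; `write_lm_json()`
#'   returns `path` invisibly.
#' @export
write_lm_json <- function(lm, path) {
  stopifnot(inherits(lm, "stimcon_lm"))
  jsonlite::write_json(
    list(vocabulary = lm$vocabulary,
         prediction = unname(lm$prediction)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_lm_json
#' @export
read_lm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimcon_lm(x$vocabulary, x$prediction)
}
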