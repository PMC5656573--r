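#' k-mer feature vector(s) for sequences
#'
#' For each k in 1..5, overlapping k-mer counts are length-normalised to
#' frequencies and scaled by the per-k weight `1/4^k`; concatenated in
#' lexicographic order within k this gives a fixed 1364-long feature
#' vector per sequence.
#'
#' @param seqs Character vector of sequences (length >= 5 each).
#' @return Numeric matrix, one row per sequence, 1364 columns.
#' @export
kmer_features <- function(seqs) {
  if (any(nchar(seqs) < 5)) abort("sequences shorter than 5 nt")
  x <- Biostrings::DNAStringSet(seqs)
  feats <- lapply(1:5, function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(x, width = k)
    freq <- cnt / pmax(rowSums(cnt), 1)
    freq / 4^k
  })
  do.call(cbind, feats)
}

#' Fit the k-mer linear large-margin classifier
#'
#' A linear support-vector machine (hinge loss, L2 margin penalty) on the
#' [kmer_features()] representation; the stored decision function is the
#' extracted linear score `x . w + b`, oriented so that positive means
#' coding.
#'
#' @param seqs Training sequences.
#' @param labels `"coding"` / `"noncoding"` per sequence.
#' @param cost Soft-margin cost parameter (default 1e4; the 1/4^k feature
#'   scaling makes the feature space small in norm, so a large cost is
#'   needed for the margin to form).
#' @return A `kmer_classifier` with `weights` (length 1364) and `bias`.
#' @export
kmer_fit <- function(seqs, labels, cost = 1e4) {
  if (length(unique(labels)) < 2) abort("need both classes in training labels")
  X <- kmer_features(seqs)
  y <- factor(labels, levels = c("noncoding", "coding"))
  fit <- e1071::svm(X, y, kernel = "linear", scale = FALSE, cost = cost)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  sc <- X %*% w + b
  if (mean(sc[y == "coding"]) < mean(sc[y == "noncoding"])) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b), class = "kmer_classifier")
}

#' Predict coding/noncoding with a k-mer classifier
#'
#' @param seqs Character vector of sequences.
#' @param classifier A `kmer_classifier` from [kmer_fit()] (or any list
#'   with `weights` and `bias`).
#' @return Character vector: `"coding"` iff the linear score is > 0,
#'   else `"noncoding"`.
#' @export
kmer_predict <- function(seqs, classifier) {
  score <- kmer_score(seqs, classifier)
  ifelse(score > 0, "coding", "noncoding")
}

#' @rdname kmer_predict
#' @return `kmer_score()`: the raw linear decision values.
#' @export
kmer_score <- function(seqs, classifier) {
  X <- kmer_features(seqs)
  drop(X %*% classifier$weights + classifier$bias)
}
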