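#' Maximum-likelihood logistic regression (IRLS)
#'
#' Iteratively reweighted least squares with convergence when the largest
#' coefficient change falls below `tol` (default 1e-8) or after
#' `max_iter` iterations.  Under perfect separation the MLE diverges; a
#' warning is issued and an L2-regularised fit (ridge penalty
#' `lambda = 1e-6`) is returned instead.
#'
#' @param features Numeric matrix (no intercept column; one is added).
#' @param labels Binary labels: logical, 0/1, or `"coding"`/`"noncoding"`
#'   (coding = 1).
#' @param tol,max_iter Convergence controls.
#' @return Named coefficient vector (`(Intercept)` first).
#' @export
fit_logistic <- function(features, labels, tol = 1e-8, max_iter = 100L) {
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  y <- if (is.character(labels) || is.factor(labels)) {
    as.numeric(as.character(labels) == "coding")
  } else {
    as.numeric(labels)
  }
  if (length(unique(y)) < 2) abort("need both classes in training labels")
  irls <- function(lambda) {
    beta <- rep(0, ncol(X))
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      p <- 1 / (1 + exp(-eta))
      w <- pmax(p * (1 - p), 1e-10)
      z <- eta + (y - p) / w
      XtW <- t(X * w)
      H <- XtW %*% X + diag(lambda, ncol(X))
      beta_new <- tryCatch(
        drop(solve(H, XtW %*% z)),
        error = function(e) NULL # singular system (constant/collinear columns)
      )
      if (is.null(beta_new)) {
        return(list(beta = beta, converged = FALSE, singular = TRUE))
      }
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      if (!is.finite(delta)) return(list(beta = beta, converged = FALSE))
      if (delta < tol) return(list(beta = beta, converged = TRUE))
    }
    list(beta = beta, converged = FALSE)
  }
  fit <- irls(0)
  p <- 1 / (1 + exp(-drop(X %*% fit$beta)))
  degenerate <- !fit$converged ||
    (all(abs(y - p) < 1e-6) && max(abs(fit$beta[-1])) > 20)
  if (degenerate) {
    if (isTRUE(fit$singular)) {
      warn("singular information matrix; returning L2-regularised fit (lambda = 1e-6)")
    } else {
      warn("perfect separation detected; returning L2-regularised fit (lambda = 1e-6)")
    }
    fit <- irls(1e-6)
  }
  setNames(fit$beta, colnames(X))
}

#' Logistic coding probability
#'
#' @param features Numeric matrix with the same columns the coefficients
#'   were fitted on.
#' @param coefficients From [fit_logistic()].
#' @return Probability of the coding class per row.
#' @export
logistic_coding_score <- function(features, coefficients) {
  X <- cbind(1, as.matrix(features))
  drop(1 / (1 + exp(-X %*% coefficients)))
}

#' The four coding-potential features of transcript sequences
#'
#' @param seqs Tibble (`id`, `sequence`) or character vector.
#' @param hexamer_model A `hexamer_model`; hexamer bias is scored on the
#'   longest-ORF subsequence (0 when no ORF).
#' @return Tibble: `id`, `length`, `orf_size`, `orf_coverage`, `fickett`,
#'   `hexamer`.
#' @export
codpot_features <- function(seqs, hexamer_model) {
  if (is.character(seqs)) {
    seqs <- tibble(id = names(seqs) %||% as.character(seq_along(seqs)), sequence = unname(seqs))
  }
  rows <- map2(seqs$id, seqs$sequence, function(id, s) {
    orf <- find_longest_orf(s)
    orf_size <- if (nrow(orf) == 0) 0L else orf$length
    hex <- if (orf_size >= 6) {
      hexamer_score(substr(s, orf$start + 1L, orf$end), hexamer_model)
    } else {
      0
    }
    tibble(
      id = id, length = nchar(s), orf_size = orf_size,
      orf_coverage = orf_size / nchar(s),
      fickett = suppressWarnings(fickett_testcode(s)),
      hexamer = hex
    )
  })
  list_rbind(rows)
}

#' Train the two-classifier coding-potential model
#'
#' Fits (i) the four-feature logistic scorer (ORF size, ORF coverage,
#' Fickett TESTCODE, hexamer bias) and (ii) the k-mer large-margin
#' classifier, both on the same labelled sequences.  The hexamer table is
#' trained on the longest-ORF subsequences of the coding set versus the
#' full noncoding sequences.
#'
#' @param training Tibble with `id`, `sequence`, `label`
#'   (`"coding"`/`"noncoding"`), e.g. from [simulate_codpot_training()].
#' @param cutoff Logistic probability cutoff for the coding call
#'   (default 0.5).
#' @param pseudocount Hexamer smoothing count.
#' @return A `codpot_model`.
#' @export
train_codpot_model <- function(training, cutoff = 0.5, pseudocount = 1) {
  coding <- training$sequence[training$label == "coding"]
  noncoding <- training$sequence[training$label == "noncoding"]
  if (length(coding) == 0 || length(noncoding) == 0) {
    abort("training set must contain both classes")
  }
  hex <- train_hexamer_model(
    vapply(coding, orf_subsequence, character(1), USE.NAMES = FALSE),
    noncoding,
    pseudocount = pseudocount
  )
  feats <- codpot_features(training, hex)
  coef <- fit_logistic(
    as.matrix(feats[, c("orf_size", "orf_coverage", "fickett", "hexamer")]),
    training$label
  )
  kmer <- kmer_fit(training$sequence, training$label)
  structure(
    list(
      hexamer_model = hex, logistic_coef = coef, cutoff = cutoff,
      kmer_classifier = kmer
    ),
    class = "codpot_model"
  )
}

#' @export
print.codpot_model <- function(x, ...) {
  cat("<codpot_model> logistic cutoff ", x$cutoff, "\n", sep = "")
  invisible(x)
}

#' Consensus noncoding gate
#'
#' A transcript passes the gate only when *both* classifiers call it
#' noncoding; a coding call from either method removes it.
#'
#' @param cpat_label,kmer_label `"coding"`/`"noncoding"` labels.
#' @return Logical vector.
#' @export
consensus_noncoding <- function(cpat_label, kmer_label) {
  cpat_label == "noncoding" & kmer_label == "noncoding"
}

#' Score transcripts with a coding-potential model
#'
#' @param seqs Tibble (`id`, `sequence`).
#' @param model A `codpot_model` from [train_codpot_model()].
#' @return Tibble: `id`, `length`, `orf_size`, `orf_coverage`, `fickett`,
#'   `hexamer`, `logistic_prob`, `cpat_label`, `kmer_label`,
#'   `consensus_noncoding`.
#' @export
codpot_classify <- function(seqs, model) {
  stopifnot(inherits(model, "codpot_model"))
  feats <- codpot_features(seqs, model$hexamer_model)
  prob <- logistic_coding_score(
    as.matrix(feats[, c("orf_size", "orf_coverage", "fickett", "hexamer")]),
    model$logistic_coef
  )
  feats |>
    mutate(
      logistic_prob = prob,
      cpat_label = if_else(prob >= model$cutoff, "coding", "noncoding"),
      kmer_label = kmer_predict(seqs$sequence, model$kmer_classifier),
      consensus_noncoding = consensus_noncoding(.data$cpat_label, .data$kmer_label)
    )
}
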