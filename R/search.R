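#' Raw NBLAST score of a query against a target
#'
#' Every query segment is matched to its Euclidean-nearest target segment
#' and the scoring-matrix values at the matched (distance, |dot|) bins are
#' summed: `S(query, target) = sum_i f(d_i, |u_i . v_i|)`. The score is
#' asymmetric in general and scales with the query's segment count.
#'
#' @param query,target Non-empty [dotprops()] objects.
#' @param smat A [scoring_matrix()].
#' @return The raw score (a single number).
#' @export
raw_score <- function(query, target, smat) {
  m <- segment_matches(query, target)
  sum(smat_lookup(smat, m$d, m$absdot))
}

#' Normalized NBLAST score
#'
#' The raw score divided by the query's self-match score, correcting for
#' query size: a self comparison scores exactly 1.
#'
#' @inheritParams raw_score
#' @return Normalized score.
#' @export
normalized_score <- function(query, target, smat) {
  self <- raw_score(query, query, smat)
  if (!is.finite(self) || self <= 0)
    stop("query self-score is not positive; scoring matrix is pathological")
  raw_score(query, target, smat) / self
}

#' Mean NBLAST score
#'
#' The mean of the forward and reverse normalized scores, symmetric by
#' construction; the similarity used for clustering.
#'
#' @param a,b Non-empty [dotprops()] objects.
#' @param smat A [scoring_matrix()].
#' @return Mean score.
#' @export
mean_score <- function(a, b, smat) {
  (normalized_score(a, b, smat) + normalized_score(b, a, smat)) / 2
}

#' Construct a score table
#'
#' @param values Numeric |Q| x |T| matrix with query ids as row names and
#'   target ids as column names.
#' @param normalization One of `"raw"`, `"normalized"`, `"mean"`.
#' @return An object of class `score_table`.
#' @export
score_table <- function(values, normalization = c("raw", "normalized",
                                                  "mean")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (nrow(values) > 0L && is.null(rownames(values)) ||
      ncol(values) > 0L && is.null(colnames(values)))
    stop("score table needs query (row) and target (column) labels")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate query or target labels")
  structure(list(values = values, normalization = normalization),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table (%s): %d queries x %d targets\n",
              x$normalization, nrow(x$values), ncol(x$values)))
  invisible(x)
}

db_labels <- function(db) {
  labs <- names(db)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- vapply(db, function(d) d$label, character(1))
  if (any(!nzchar(labs)))
    stop("every neuron needs a label (list names or dotprops labels)")
  labs
}

#' Score one query neuron against a database
#'
#' @param query A non-empty [dotprops()] object.
#' @param db Named list of target [dotprops()] objects.
#' @param smat A [scoring_matrix()].
#' @param normalization `"raw"` (default for single queries),
#'   `"normalized"` or `"mean"`.
#' @param top Optional: keep only the best `top` hits.
#' @return A data frame of hits with columns `target`, `score`, `rank`,
#'   sorted by descending score with ties broken by target id (C-locale
#'   lexicographic).
#' @export
query_database <- function(query, db, smat,
                           normalization = c("raw", "normalized", "mean"),
                           top = NULL) {
  normalization <- match.arg(normalization)
  if (length(db) == 0L) stop("empty database")
  labs <- db_labels(db)
  if (anyDuplicated(labs)) stop("duplicate target labels in database")
  scores <- vapply(db, function(t) switch(normalization,
    raw = raw_score(query, t, smat),
    normalized = normalized_score(query, t, smat),
    mean = mean_score(query, t, smat)), numeric(1))
  ord <- order(-scores, labs, method = "radix")
  hits <- data.frame(target = labs[ord], score = scores[ord],
                     rank = seq_along(ord), row.names = NULL,
                     stringsAsFactors = FALSE)
  if (!is.null(top)) hits <- hits[seq_len(min(top, nrow(hits))), ]
  hits
}

#' All-by-all score table for a neuron database
#'
#' Computes the complete score matrix of a database against itself. Under
#' `"normalized"` each row is divided by the query's self raw score (so the
#' diagonal is exactly 1); `"mean"` symmetrizes the normalized table as
#' `(N + N^T) / 2`.
#'
#' @param db Named list of >= 2 [dotprops()] objects with unique labels.
#' @param smat A [scoring_matrix()].
#' @param normalization `"raw"`, `"normalized"` or `"mean"` (default:
#'   `"mean"`, the similarity used for clustering).
#' @return A [score_table()].
#' @export
all_by_all <- function(db, smat,
                       normalization = c("mean", "raw", "normalized")) {
  normalization <- match.arg(normalization)
  if (length(db) < 2L) stop("need at least 2 neurons")
  labs <- db_labels(db)
  if (anyDuplicated(labs)) stop("duplicate labels in database")
  n <- length(db)
  raw <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (j in seq_len(n)) {
    # one k-d tree per target: score all queries against it
    tgt <- db[[j]]
    for (i in seq_len(n)) {
      m <- segment_matches(db[[i]], tgt)
      raw[i, j] <- sum(smat_lookup(smat, m$d, m$absdot))
    }
  }
  if (normalization == "raw") return(score_table(raw, "raw"))
  self <- diag(raw)
  if (any(self <= 0))
    stop("non-positive self-score for: ",
         paste(labs[self <= 0], collapse = ", "))
  norm <- raw / self  # divides row-wise by the query's self score
  diag(norm) <- 1
  if (normalization == "normalized") return(score_table(norm, "normalized"))
  score_table((norm + t(norm)) / 2, "mean")
}

#' Filter a ranked hit list at a score cutoff
#'
#' Retains hits scoring strictly above `threshold`. A threshold of 0 is the
#' natural cutoff: segment pairs of such a query/target pair are on average
#' equally likely under the matching and random models.
#'
#' @param hits Data frame from [query_database()].
#' @param threshold Score cutoff (default 0).
#' @return The filtered hit data frame.
#' @export
score_cutoff_filter <- function(hits, threshold = 0) {
  hits[hits$score > threshold, , drop = FALSE]
}
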