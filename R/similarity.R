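#' Inter-subject similarity matrix for one domain
#'
#' Entry (u, v) is the Pearson correlation between participants u and v over
#' the items both rated. With complete data this is `cor(values)`; with
#' missing responses each pair uses its jointly observed items
#' (pairwise-complete). The diagonal is set to exactly 1.
#'
#' @param rm a [rating_matrix()] (raw or normalized).
#' @param min_overlap minimum number of jointly observed items per pair.
#' @return object of class `similarity_matrix`: list with `values` (n x n),
#'   `participant_ids`, `domain`.
#' @export
pairwise_similarity <- function(rm, min_overlap = 3L) {
  stopifnot(inherits(rm, "rating_matrix"))
  v <- rm$values
  n <- ncol(v)
  if (anyNA(v)) {
    obs <- !is.na(v)
    overlap <- crossprod(obs)
    short <- which(overlap < min_overlap & upper.tri(overlap), arr.ind = TRUE)
    if (nrow(short))
      stop("pairwise_similarity: participants '",
           rm$participant_ids[short[1, 1]], "' and '",
           rm$participant_ids[short[1, 2]], "' share only ",
           overlap[short[1, , drop = FALSE]], " items", call. = FALSE)
    s <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  } else {
    if (nrow(v) < min_overlap)
      stop("pairwise_similarity: fewer than ", min_overlap, " items",
           call. = FALSE)
    s <- suppressWarnings(stats::cor(v))
  }
  if (anyNA(s)) {
    bad <- which(is.na(s) & upper.tri(s), arr.ind = TRUE)
    stop("pairwise_similarity: undefined correlation (zero-variance overlap)",
         " for participants '", rm$participant_ids[bad[1, 1]], "' and '",
         rm$participant_ids[bad[1, 2]], "'", call. = FALSE)
  }
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(rm$participant_ids, rm$participant_ids)
  structure(list(values = s, participant_ids = rm$participant_ids,
                 domain = rm$domain),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> domain=%s  %d participants, mean r=%.3f\n",
              x$domain, length(x$participant_ids), mean_similarity(x)))
  invisible(x)
}

#' Vectorize the strict lower triangle of a similarity matrix
#'
#' Entries strictly below the diagonal in fixed row-major order: (2,1), (3,1),
#' (3,2), (4,1), ... This is the ordering used when correlating two domains'
#' similarity structures, so it is documented and deterministic.
#'
#' @param sm a [pairwise_similarity()] or [inter_domain_matrix()] result,
#'   or a plain symmetric matrix.
#' @return numeric vector of length n(n-1)/2.
#' @export
lower_triangle <- function(sm) {
  v <- if (is.list(sm) && !is.null(sm$values)) sm$values else as.matrix(sm)
  tv <- t(v)
  tv[upper.tri(tv)]  # row-major lower triangle of v
}

#' Second-order similarity between domains
#'
#' Correlates the lower-triangle vectors of several domains' inter-subject
#' similarity matrices: entry (a, b) is the Pearson correlation between
#' domains a and b's pairwise similarity structures. High values mean the
#' social geometry of preferences is preserved across stimulus categories.
#'
#' @param sms list of `similarity_matrix` objects over identical participants.
#' @return object of class `inter_domain_matrix`: list with `values` (d x d)
#'   and `domain_labels`.
#' @export
inter_domain_matrix <- function(sms) {
  stopifnot(length(sms) >= 2L)
  pid <- sms[[1]]$participant_ids
  for (sm in sms)
    if (!identical(sm$participant_ids, pid))
      stop("inter_domain_matrix: participant sets differ across domains",
           call. = FALSE)
  vecs <- vapply(sms, lower_triangle, numeric(length(pid) * (length(pid) - 1) / 2))
  m <- stats::cor(vecs)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  labels <- vapply(sms, function(s) s$domain, character(1))
  dimnames(m) <- list(labels, labels)
  structure(list(values = m, domain_labels = labels),
            class = "inter_domain_matrix")
}

#' Mean inter-subject similarity of a domain
#'
#' Plain arithmetic mean of the lower-triangle correlations (no Fisher
#' transform) — the summary used when characterizing how alike a cohort's
#' preferences are within one domain.
#'
#' @param sm a `similarity_matrix`.
#' @return scalar mean correlation.
#' @export
mean_similarity <- function(sm) {
  mean(lower_triangle(sm))
}

#' Write a similarity or inter-domain matrix as CSV
#'
#' @param x a `similarity_matrix` or `inter_domain_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(x, path) {
  utils::write.csv(as.data.frame(x$values), path, row.names = TRUE,
                   quote = FALSE)
  invisible(path)
}
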