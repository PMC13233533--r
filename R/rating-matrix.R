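#' Construct a rating matrix for one stimulus domain
#'
#' The central data container: an items x participants matrix of behavioral
#' responses for a single aesthetic domain (art, male faces, female faces,
#' scenes, or any user-defined label). Missing responses are `NA` and are
#' excluded from every downstream mean, correlation, and fit.
#'
#' @param values numeric matrix, items in rows, participants in columns.
#' @param item_ids character vector of unique item identifiers (rows).
#' @param participant_ids character vector of unique participant identifiers
#'   (columns).
#' @param domain single domain label.
#' @param scale one of `"raw_monetary"`, `"raw_rank"`, `"normalized"`.
#' @return an object of class `rating_matrix`.
#' @export
rating_matrix <- function(values, item_ids = rownames(values),
                          participant_ids = colnames(values),
                          domain = "domain", scale = "raw_monetary") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  item_ids <- as.character(item_ids)
  participant_ids <- as.character(participant_ids)
  scale <- match.arg(scale, c("raw_monetary", "raw_rank", "normalized"))
  if (nrow(values) != length(item_ids))
    stop("rating_matrix: ", nrow(values), " rows but ", length(item_ids),
         " item ids", call. = FALSE)
  if (ncol(values) != length(participant_ids))
    stop("rating_matrix: ", ncol(values), " columns but ",
         length(participant_ids), " participant ids", call. = FALSE)
  if (anyDuplicated(item_ids))
    stop("rating_matrix: duplicated item id(s) in domain '", domain, "': ",
         paste(unique(item_ids[duplicated(item_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(participant_ids))
    stop("rating_matrix: duplicated participant id(s): ",
         paste(unique(participant_ids[duplicated(participant_ids)]),
               collapse = ", "), call. = FALSE)
  dimnames(values) <- list(item_ids, participant_ids)
  out <- structure(
    list(values = values, item_ids = item_ids,
         participant_ids = participant_ids,
         domain = as.character(domain)[1], scale = scale),
    class = "rating_matrix")
  if (scale == "normalized") validate_normalized(out)
  out
}

# Each participant column of a normalized matrix must have mean ~0 and
# population SD ~1 over its non-missing entries.
validate_normalized <- function(rm, tol = 1e-9) {
  for (j in seq_along(rm$participant_ids)) {
    x <- rm$values[, j]
    x <- x[!is.na(x)]
    if (length(x) < 2L) next
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (abs(mu) > tol || abs(sigma - 1) > tol)
      stop("rating_matrix: column '", rm$participant_ids[j],
           "' tagged normalized but mean=", signif(mu, 3),
           ", sd=", signif(sigma, 3), call. = FALSE)
  }
  invisible(rm)
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> domain=%s scale=%s  %d items x %d participants",
              x$domain, x$scale, nrow(x$values), ncol(x$values)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  (%d missing)", n_na))
  cat("\n")
  invisible(x)
}

#' @export
dim.rating_matrix <- function(x) dim(x$values)

#' Construct a cohort (participant metadata) table
#'
#' @param participant_ids character vector of unique ids.
#' @param gender character vector, one of `"male"`, `"female"`, `"other"` per
#'   participant.
#' @return object of class `cohort`: a data.frame with columns
#'   `participant_id`, `gender`.
#' @export
cohort <- function(participant_ids, gender) {
  participant_ids <- as.character(participant_ids)
  gender <- as.character(gender)
  if (length(participant_ids) != length(gender))
    stop("cohort: ids and gender lengths differ", call. = FALSE)
  if (anyDuplicated(participant_ids))
    stop("cohort: duplicated participant id(s)", call. = FALSE)
  bad <- setdiff(unique(gender), c("male", "female", "other"))
  if (length(bad))
    stop("cohort: unknown gender label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(data.frame(participant_id = participant_ids, gender = gender,
                       stringsAsFactors = FALSE),
            class = c("cohort", "data.frame"))
}

#' Z-score normalize responses per participant within a domain
#'
#' Centers and scales each participant's column to mean 0, SD 1 over its
#' non-missing entries, using the population SD (divide by n). Scaling is per
#' participant within the domain, so that inter-subject correlations and the
#' collaborative-filtering formula see centered profiles with no participant
#' offset.
#'
#' @param rm a [rating_matrix()].
#' @return a `rating_matrix` with `scale = "normalized"`; missing entries
#'   preserved.
#' @export
zscore_normalize <- function(rm) {
  stopifnot(inherits(rm, "rating_matrix"))
  v <- rm$values
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- !is.na(x)
    if (sum(obs) < 2L)
      stop("zscore_normalize: participant '", rm$participant_ids[j],
           "' has fewer than 2 observed responses", call. = FALSE)
    mu <- mean(x[obs])
    sigma <- sqrt(mean((x[obs] - mu)^2))
    if (sigma == 0)
      stop("zscore_normalize: participant '", rm$participant_ids[j],
           "' has zero spread (constant responses)", call. = FALSE)
    v[, j] <- (x - mu) / sigma
  }
  rating_matrix(v, rm$item_ids, rm$participant_ids, rm$domain,
                scale = "normalized")
}

#' Orient raw responses so that larger always means more preferred
#'
#' Monetary valuations already satisfy "higher = preferred"; grid ranks do not
#' (rank 1 is the most preferred position). Negating rank responses before
#' normalization puts every domain on a common polarity.
#'
#' @param rm a raw-scale [rating_matrix()].
#' @param higher_is_better logical; if `FALSE` the values are negated.
#' @return a `rating_matrix` with the same scale tag.
#' @export
orient_preferences <- function(rm, higher_is_better = TRUE) {
  stopifnot(inherits(rm, "rating_matrix"))
  if (rm$scale == "normalized")
    stop("orient_preferences: expects a raw-scale matrix", call. = FALSE)
  v <- if (higher_is_better) rm$values else -rm$values
  rating_matrix(v, rm$item_ids, rm$participant_ids, rm$domain, scale = rm$scale)
}

#' Split a domain's items into train and test sets
#'
#' One uniform random item split per domain, shared by all participants: whole
#' item rows move together, so a held-out item is unseen for every participant
#' during fitting. The default 0.25 test fraction gives the 3:1 train:test
#' ratio used throughout the analyses.
#'
#' @param rm a [rating_matrix()].
#' @param fraction test fraction in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return object of class `split_index` with `train_items`, `test_items`,
#'   `seed`, `fraction`.
#' @export
split_items <- function(rm, fraction = 0.25, seed = 1L) {
  stopifnot(inherits(rm, "rating_matrix"))
  if (!(fraction > 0 && fraction < 1))
    stop("split_items: fraction must be in (0,1)", call. = FALSE)
  m <- length(rm$item_ids)
  if (m < 4L) stop("split_items: need at least 4 items", call. = FALSE)
  n_test <- round(fraction * m)
  if (n_test < 1L || n_test >= m)
    stop("split_items: fraction ", fraction, " leaves an empty train or test",
         " set for m=", m, call. = FALSE)
  idx <- with_seed(seed, sample.int(m, n_test))
  structure(list(train_items = rm$item_ids[-idx],
                 test_items = rm$item_ids[sort(idx)],
                 seed = as.integer(seed), fraction = fraction),
            class = "split_index")
}

#' Restrict a rating matrix to a subset of items
#'
#' @param rm a [rating_matrix()].
#' @param items character vector of item ids to keep, in `rm` order.
#' @return a `rating_matrix` over the chosen items.
#' @export
subset_items <- function(rm, items) {
  stopifnot(inherits(rm, "rating_matrix"))
  missing_ids <- setdiff(items, rm$item_ids)
  if (length(missing_ids))
    stop("subset_items: unknown item id(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  keep <- rm$item_ids %in% items
  structure(
    list(values = rm$values[keep, , drop = FALSE],
         item_ids = rm$item_ids[keep],
         participant_ids = rm$participant_ids,
         domain = rm$domain, scale = rm$scale),
    class = "rating_matrix")
}

#' Restrict a rating matrix to a subset of participants
#'
#' @param rm a [rating_matrix()].
#' @param participants participant ids to keep.
#' @return a `rating_matrix` over the chosen participants.
#' @export
subset_participants <- function(rm, participants) {
  stopifnot(inherits(rm, "rating_matrix"))
  missing_ids <- setdiff(participants, rm$participant_ids)
  if (length(missing_ids))
    stop("subset_participants: unknown participant id(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  keep <- rm$participant_ids %in% participants
  structure(
    list(values = rm$values[, keep, drop = FALSE],
         item_ids = rm$item_ids,
         participant_ids = rm$participant_ids[keep],
         domain = rm$domain, scale = rm$scale),
    class = "rating_matrix")
}

#' Stack two rating matrices of the same participants (e.g. both face subsets)
#'
#' @param a,b `rating_matrix` objects sharing `participant_ids` and scale.
#' @param domain label for the combined matrix.
#' @return a `rating_matrix` with the rows of `a` above the rows of `b`.
#' @export
bind_items <- function(a, b, domain = paste(a$domain, b$domain, sep = "+")) {
  stopifnot(inherits(a, "rating_matrix"), inherits(b, "rating_matrix"))
  if (!identical(a$participant_ids, b$participant_ids))
    stop("bind_items: participant ids differ", call. = FALSE)
  if (a$scale != b$scale)
    stop("bind_items: scales differ (", a$scale, " vs ", b$scale, ")",
         call. = FALSE)
  ids_a <- paste0(a$domain, ":", a$item_ids)
  ids_b <- paste0(b$domain, ":", b$item_ids)
  structure(
    list(values = rbind(a$values, b$values),
         item_ids = c(ids_a, ids_b),
         participant_ids = a$participant_ids,
         domain = domain, scale = a$scale),
    class = "rating_matrix")
}

# ---- file I/O -------------------------------------------------------------

#' Read multi-domain ratings from a wide CSV/TSV file
#'
#' Expected layout: columns `domain`, `item_id`, then one numeric column per
#' participant. Empty cells or `"NA"` denote missing responses. The file is
#' split into one [rating_matrix()] per distinct domain label, in order of
#' first appearance.
#'
#' @param path file path; `.tsv`/`.txt` files are read tab-separated,
#'   everything else comma-separated.
#' @param scale scale tag for the matrices: a single tag or a named vector
#'   `c(domain = tag, ...)`.
#' @return named list of `rating_matrix` objects, one per domain.
#' @export
read_ratings <- function(path, scale = "raw_monetary") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("domain", "item_id")))
    stop("read_ratings: expected columns domain, item_id, <participants...>",
         call. = FALSE)
  part_ids <- names(df)[-(1:2)]
  for (j in seq_along(part_ids)) {
    col <- df[[j + 2L]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      stop("read_ratings: non-numeric value in column '", part_ids[j],
           "', row ", bad[1] + 1L, " ('", col[bad[1]], "')", call. = FALSE)
    }
  }
  domains <- unique(df$domain)
  out <- lapply(domains, function(d) {
    sub <- df[df$domain == d, , drop = FALSE]
    tag <- if (length(scale) == 1L && is.null(names(scale))) scale
           else if (d %in% names(scale)) scale[[d]]
           else stop("read_ratings: no scale tag for domain '", d, "'",
                     call. = FALSE)
    rating_matrix(as.matrix(sub[, -(1:2), drop = FALSE]),
                  item_ids = as.character(sub$item_id),
                  participant_ids = part_ids, domain = d, scale = tag)
  })
  names(out) <- domains
  out
}

#' Write rating matrices to a wide CSV/TSV file
#'
#' Inverse of [read_ratings()]: domains are stacked row-wise with a `domain`
#' column. Missing responses are written as `NA`.
#'
#' @param rms list of `rating_matrix` objects sharing participant ids.
#' @param path output file path (`.tsv`/`.txt` for tab-separated).
#' @return `path`, invisibly.
#' @export
write_ratings <- function(rms, path) {
  if (inherits(rms, "rating_matrix")) rms <- list(rms)
  pid <- rms[[1]]$participant_ids
  for (rm in rms)
    if (!identical(rm$participant_ids, pid))
      stop("write_ratings: participant ids differ across domains",
           call. = FALSE)
  blocks <- lapply(rms, function(rm) {
    data.frame(domain = rm$domain, item_id = rm$item_ids, rm$values,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  df <- do.call(rbind, blocks)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participants file (`participant_id,gender` CSV)
#'
#' @param path CSV path.
#' @return a [cohort()].
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "gender") %in% names(df)))
    stop("read_cohort: expected columns participant_id, gender", call. = FALSE)
  cohort(df$participant_id, df$gender)
}

#' Write a cohort to CSV
#'
#' @param ch a [cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ch, path) {
  utils::write.csv(as.data.frame(ch), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
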