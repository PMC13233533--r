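# Seeded generator of multi-domain rating cohorts with a controllable
# domain-invariant latent preference trait. The generator is the test bed for
# the whole pipeline: its consistency parameter realizes both the
# shared-latent hypothesis (c > 0) and its null (c = 0) by construction.

#' Configuration for the synthetic cohort generator
#'
#' The default cohort mirrors the study design the package targets: 37
#' participants (9 male, 28 female) rating four domains — 400 art items
#' (monetary valuations), 80 male faces, 80 female faces, and 400 scenes
#' (grid rankings in 80-item blocks).
#'
#' Each participant u has a shared latent trait vector `p_u` (length
#' `latent_dim`); their effective trait in domain d is
#' `q_du = c * p_u + gamma * g[gender(u), d] + sqrt(1 - c^2 - gamma^2) * e_du`
#' with `g` a gender- and domain-specific trait and `e_du` independent noise
#' traits. `c` (consistency) controls how much of each domain's preference is
#' domain-invariant; `gamma` (gender_strength) how much is shared within a
#' gender.
#'
#' @param n_participants cohort size (default 37).
#' @param n_male number of male participants (default 9; the rest female).
#' @param items_per_domain named integer vector of items per domain.
#' @param latent_dim trait dimensionality k (default 8).
#' @param consistency c in `[0, 1]`.
#' @param gender_strength gamma `>= 0`, with `c^2 + gamma^2 <= 1`.
#' @param noise_sd response noise SD sigma `>= 0` (latent responses have unit
#'   signal variance, so sigma is a noise-to-signal ratio).
#' @param scales named character vector mapping each domain to `"monetary"`
#'   or `"rank"`.
#' @param rank_block block length for rank domains (default 80; must divide
#'   each rank domain's item count).
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 37L, n_male = 9L,
                             items_per_domain = c(art = 400L, face_male = 80L,
                                                  face_female = 80L,
                                                  scene = 400L),
                             latent_dim = 8L, consistency = 0.7,
                             gender_strength = 0.3, noise_sd = 0.3,
                             scales = c(art = "monetary", face_male = "rank",
                                        face_female = "rank", scene = "rank"),
                             rank_block = 80L, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_male = as.integer(n_male),
              items_per_domain = items_per_domain,
              latent_dim = as.integer(latent_dim),
              consistency = consistency, gender_strength = gender_strength,
              noise_sd = noise_sd, scales = scales,
              rank_block = as.integer(rank_block), seed = as.integer(seed))
  if (cfg$n_male > cfg$n_participants)
    stop("synthetic_config: n_male exceeds cohort size", call. = FALSE)
  if (any(items_per_domain <= 0) || cfg$n_participants <= 0 ||
      cfg$latent_dim <= 0)
    stop("synthetic_config: counts must be positive", call. = FALSE)
  if (consistency < 0 || consistency > 1 || gender_strength < 0)
    stop("synthetic_config: need 0 <= consistency <= 1, gender_strength >= 0",
         call. = FALSE)
  if (consistency^2 + gender_strength^2 > 1 + 1e-12)
    stop("synthetic_config: consistency^2 + gender_strength^2 must be <= 1",
         call. = FALSE)
  if (noise_sd < 0) stop("synthetic_config: noise_sd must be >= 0",
                         call. = FALSE)
  if (is.null(names(items_per_domain)) || anyDuplicated(names(items_per_domain)))
    stop("synthetic_config: items_per_domain must have unique names",
         call. = FALSE)
  missing_scale <- setdiff(names(items_per_domain), names(scales))
  if (length(missing_scale))
    stop("synthetic_config: no scale for domain(s): ",
         paste(missing_scale, collapse = ", "), call. = FALSE)
  for (d in names(items_per_domain))
    if (scales[[d]] == "rank" && items_per_domain[[d]] %% cfg$rank_block != 0)
      stop("synthetic_config: rank_block ", cfg$rank_block,
           " does not divide ", items_per_domain[[d]], " items of domain '",
           d, "'", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic multi-domain cohort
#'
#' Draws participant traits, domain traits, and item attributes per
#' [synthetic_config()], forms latent responses `s[u, j] = <q_du, a_dj> +
#' sigma * eps` (item attributes i.i.d. standard normal, scaled so the signal
#' has unit variance), and maps them to raw response scales with
#' [to_raw_scales()]. Deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `ratings` (named list of raw-scale [rating_matrix()]),
#'   `latent` (the noiseless-scale latent responses as matrices), `cohort`
#'   (a [cohort()]), and `truth` (participant/domain traits, item attributes,
#'   config echo).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_participants
  k <- cfg$latent_dim
  domains <- names(cfg$items_per_domain)
  pid <- sprintf("P%02d", seq_len(n))
  genders <- c(rep("male", cfg$n_male), rep("female", n - cfg$n_male))
  ch <- cohort(pid, genders)
  c_ <- cfg$consistency
  gam <- cfg$gender_strength
  resid <- sqrt(max(0, 1 - c_^2 - gam^2))
  out <- with_seed(cfg$seed, {
    p <- matrix(rnorm(n * k), n, k, dimnames = list(pid, NULL))
    g_traits <- lapply(domains, function(d) {
      m <- matrix(rnorm(2 * k), 2, k)
      rownames(m) <- c("male", "female")
      m
    })
    names(g_traits) <- domains
    q <- list(); attrs <- list(); latent <- list()
    for (d in domains) {
      m_d <- cfg$items_per_domain[[d]]
      e <- matrix(rnorm(n * k), n, k)
      q_d <- c_ * p + gam * g_traits[[d]][genders, , drop = FALSE] + resid * e
      a_d <- matrix(rnorm(m_d * k), m_d, k)
      # <q, a>/sqrt(k) has unit variance when q has unit-variance entries
      s <- a_d %*% t(q_d) / sqrt(k) +
        cfg$noise_sd * matrix(rnorm(m_d * n), m_d, n)
      dimnames(s) <- list(sprintf("%s_%03d", d, seq_len(m_d)), pid)
      q[[d]] <- q_d; attrs[[d]] <- a_d; latent[[d]] <- s
    }
    list(p = p, g = g_traits, q = q, attrs = attrs, latent = latent)
  })
  ratings <- to_raw_scales(out$latent, cfg)
  truth <- list(participant_traits = out$p, gender_traits = out$g,
                domain_traits = out$q, item_attributes = out$attrs,
                config = cfg)
  list(ratings = ratings, latent = out$latent, cohort = ch, truth = truth)
}

#' Map latent responses onto raw behavioral scales
#'
#' Monetary domains: each participant's latent responses are mapped
#' monotonically into JPY 100–10,000,000 through a piecewise-affine map in
#' log10 space anchored so the participant's median lands at the task's
#' 10,000 start value. Rank domains: within consecutive blocks of
#' `rank_block` items, responses are replaced by their descending rank
#' (1 = most preferred), ties broken by item order.
#'
#' @param latent named list of items x participants latent response matrices.
#' @param cfg the [synthetic_config()] describing scales and block size.
#' @return named list of raw-scale [rating_matrix()] objects.
#' @export
to_raw_scales <- function(latent, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  out <- lapply(names(latent), function(d) {
    s <- latent[[d]]
    if (!all(is.finite(s)))
      stop("to_raw_scales: non-finite latent responses in domain '", d, "'",
           call. = FALSE)
    if (cfg$scales[[d]] == "monetary") {
      v <- apply(s, 2, latent_to_jpy)
      dimnames(v) <- dimnames(s)
      rating_matrix(v, rownames(s), colnames(s), d, scale = "raw_monetary")
    } else {
      m_d <- nrow(s)
      if (m_d %% cfg$rank_block != 0)
        stop("to_raw_scales: block size ", cfg$rank_block,
             " does not divide ", m_d, " items (domain '", d, "')",
             call. = FALSE)
      v <- s
      for (b in seq_len(m_d %/% cfg$rank_block)) {
        rows <- ((b - 1) * cfg$rank_block + 1):(b * cfg$rank_block)
        v[rows, ] <- apply(s[rows, , drop = FALSE], 2,
                           function(x) rank(-x, ties.method = "first"))
      }
      rating_matrix(v, rownames(s), colnames(s), d, scale = "raw_rank")
    }
  })
  names(out) <- names(latent)
  out
}

# Monotone latent -> JPY map: median to 10^4, spread filling [10^2, 10^7]
# asymmetrically (2 decades below the median, 3 above).
latent_to_jpy <- function(x) {
  med <- stats::median(x)
  lo <- med - min(x)
  hi <- max(x) - med
  lg <- ifelse(x <= med,
               4 - 2 * (med - x) / if (lo > 0) lo else 1,
               4 + 3 * (x - med) / if (hi > 0) hi else 1)
  round(10^lg, 0)
}

#' Generate a cohort whose responses are linear in observable item features
#'
#' Companion generator for the feature-regression baseline. Item features are
#' i.i.d. standard normal in `2k` dimensions, but domain A's responses read
#' only the first `k` feature columns and domain B's only the last `k` —
#' while the *same* participant trait vector drives both blocks. The
#' feature-to-preference map is therefore disjoint across domains (a
#' regression fit on one domain carries no information about the other), yet
#' the inter-subject similarity structure is identical, so similarity-based
#' transfer still works.
#'
#' @param n_participants cohort size.
#' @param n_items items per domain (named vector over two domains).
#' @param latent_dim trait dimension k per block.
#' @param noise_sd response noise SD.
#' @param seed integer seed.
#' @return list with `ratings` (continuous-scale rating matrices, tagged
#'   `raw_monetary`), `features` (named list of [feature_matrix()]), and
#'   `truth`.
#' @export
generate_feature_cohort <- function(n_participants = 37L,
                                    n_items = c(A = 120L, B = 120L),
                                    latent_dim = 8L, noise_sd = 0.3,
                                    seed = 1L) {
  stopifnot(length(n_items) == 2L, !is.null(names(n_items)))
  k <- latent_dim
  pid <- sprintf("P%02d", seq_len(n_participants))
  doms <- names(n_items)
  with_seed(seed, {
    p <- matrix(rnorm(n_participants * k), n_participants, k,
                dimnames = list(pid, NULL))
    blocks <- list(seq_len(k), k + seq_len(k))
    names(blocks) <- doms
    ratings <- list(); feats <- list()
    for (d in doms) {
      m <- n_items[[d]]
      X <- matrix(rnorm(m * 2 * k), m, 2 * k)
      ids <- sprintf("%s_%03d", d, seq_len(m))
      rownames(X) <- ids
      s <- X[, blocks[[d]], drop = FALSE] %*% t(p) / sqrt(k) +
        noise_sd * matrix(rnorm(m * n_participants), m, n_participants)
      dimnames(s) <- list(ids, pid)
      ratings[[d]] <- rating_matrix(s, ids, pid, d, scale = "raw_monetary")
      feats[[d]] <- feature_matrix(X, ids, source_tag = "synthetic-latent")
    }
    list(ratings = ratings, features = feats,
         truth = list(participant_traits = p, blocks = blocks))
  })
}

#' Orient and normalize a cohort's raw ratings
#'
#' Convenience wrapper applying the standard preprocessing to each domain:
#' monetary valuations are log10-transformed (their permissible range spans
#' five decades, and z-scoring the raw scale would let a handful of
#' top-valued items dominate every correlation), rank domains are negated
#' (rank 1 = most preferred) so larger always means more preferred, and
#' every domain is then z-score normalized per participant.
#'
#' @param ratings named list of raw [rating_matrix()] objects.
#' @param scales named character vector (`"monetary"` or `"rank"` per
#'   domain); defaults to reading each matrix's scale tag.
#' @param monetary_log10 log-transform monetary responses before
#'   normalization (default `TRUE`).
#' @return named list of normalized `rating_matrix` objects.
#' @export
prepare_ratings <- function(ratings, scales = NULL, monetary_log10 = TRUE) {
  out <- lapply(ratings, function(rm) {
    tag <- if (!is.null(scales)) scales[[rm$domain]]
           else if (rm$scale == "raw_rank") "rank" else "monetary"
    if (tag == "monetary" && monetary_log10) {
      if (any(rm$values <= 0, na.rm = TRUE))
        stop("prepare_ratings: nonpositive monetary value in domain '",
             rm$domain, "' cannot be log-transformed", call. = FALSE)
      rm <- rating_matrix(log10(rm$values), rm$item_ids, rm$participant_ids,
                          rm$domain, scale = rm$scale)
    }
    zscore_normalize(orient_preferences(rm, higher_is_better = tag != "rank"))
  })
  names(out) <- names(ratings)
  out
}
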