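#' Greedy age/sex matched-pair construction
#'
#' Pairs each group-B subject with a group-A subject of the same sex whose age
#' differs by at most `max_age_gap` years, emulating a matched-pairs cohort
#' design. Matching is greedy: group-B subjects are visited in age order and
#' each takes the nearest-age available candidate of the same sex, ties broken
#' at random (seeded by the caller's RNG state). Unmatched subjects are
#' reported and excluded.
#'
#' @param covariates Cohort covariate data frame (columns `subject_id`,
#'   `group`, `sex`, `age`), e.g. `cohort$covariates`.
#' @param max_age_gap Maximum allowed |age difference| in years.
#' @return A list with `pairs` (data frame: `subject_a`, `subject_b`,
#'   `age_gap` = age(A) - age(B), i.e. the chosen partner's age relative to
#'   the group-B subject) and `unmatched` (character ids).
#' @export
match_pairs <- function(covariates, max_age_gap = 1) {
  a <- covariates[covariates$group == "A", ]
  b <- covariates[covariates$group == "B", ]
  if (nrow(a) == 0 || nrow(b) == 0) stop("both groups must be nonempty")
  b <- b[order(b$age), ]
  avail <- rep(TRUE, nrow(a))
  rows <- list(); unmatched <- character()
  for (i in seq_len(nrow(b))) {
    ok <- avail & a$sex == b$sex[i] & abs(a$age - b$age[i]) <= max_age_gap
    if (!any(ok)) { unmatched <- c(unmatched, b$subject_id[i]); next }
    gaps <- abs(a$age - b$age[i])
    cand <- which(ok & gaps == min(gaps[ok]))
    j <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    avail[j] <- FALSE
    rows[[length(rows) + 1]] <- data.frame(
      subject_a = a$subject_id[j], subject_b = b$subject_id[i],
      age_gap = a$age[j] - b$age[i], stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_a = character(), subject_b = character(),
               age_gap = numeric())
  list(pairs = pairs, unmatched = unmatched)
}

#' Pair-preserving train/test split
#'
#' Randomly assigns whole matched pairs to the test set, so both members of a
#' pair always land in the same partition.
#'
#' @param pairs Data frame from [match_pairs()] (`$pairs`).
#' @param n_test_pairs Number of pairs held out for testing.
#' @param seed Optional integer seed.
#' @return A list with `train_ids` and `test_ids` (character vectors) and the
#'   corresponding `train_pairs` / `test_pairs` data frames.
#' @export
split_pairs <- function(pairs, n_test_pairs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pairs)
  if (n_test_pairs >= n) stop("n_test_pairs must be < number of pairs")
  test_idx <- sample.int(n, n_test_pairs)
  test <- pairs[test_idx, , drop = FALSE]
  train <- pairs[-test_idx, , drop = FALSE]
  list(train_ids = c(train$subject_a, train$subject_b),
       test_ids = c(test$subject_a, test$subject_b),
       train_pairs = train, test_pairs = test)
}

#' Imbalance-sweep training subsets
#'
#' Builds one training subset per imbalance fraction `f`: `round(f * pool)`
#' group-B subjects and `pool - round(f * pool)` group-A subjects (rounding
#' half away from zero, group A adjusted to preserve the total). Subsets are
#' nested: each pool is shuffled once and subsets take its prefix, so the
#' subjects used at fraction 0.25 are a subset of those used at 0.5, etc.
#' Total training size is constant across fractions.
#'
#' @param train_ids_by_group Named list `list(A=, B=)` of available ids.
#' @param fractions Group-B fractions, default `c(1, 0.75, 0.5, 0.25, 0)`.
#' @param pool_per_group Training subjects drawn in total per split.
#' @param seed Optional integer seed.
#' @return A list of `imbalance_split` objects: `fraction_b`, `train_a`,
#'   `train_b`, `n_a`, `n_b`.
#' @export
imbalance_subsets <- function(train_ids_by_group,
                              fractions = c(1, 0.75, 0.5, 0.25, 0),
                              pool_per_group = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool_per_group))
    pool_per_group <- min(lengths(train_ids_by_group[c("A", "B")]))
  for (g in c("A", "B"))
    if (pool_per_group > length(train_ids_by_group[[g]]))
      stop("pool_per_group exceeds available ids for group ", g)
  pool_a <- sample(train_ids_by_group$A, pool_per_group)
  pool_b <- sample(train_ids_by_group$B, pool_per_group)
  lapply(fractions, function(f) {
    n_b <- floor(f * pool_per_group + 0.5)  # round half away from zero
    n_a <- pool_per_group - n_b
    structure(list(fraction_b = f,
                   train_a = if (n_a > 0) pool_a[seq_len(n_a)] else character(),
                   train_b = if (n_b > 0) pool_b[seq_len(n_b)] else character(),
                   n_a = n_a, n_b = n_b),
              class = "imbalance_split")
  })
}
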