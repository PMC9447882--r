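## Outcome-stratified partition into k groups and derived CV folds.
##
## Positives (CPC1/2) and negatives are each divided as evenly as possible
## across the k groups; the per-class remainders are handed to the same
## seeded tail groups so that, e.g., 8274 records with 286 positives in
## k = 5 yield the group-size multiset {1654, 1654, 1655, 1655, 1656} with
## per-group positives {57, 57, 57, 57, 58}. The test group is the first
## group in the seeded ordering (and therefore carries no remainder
## records). Group totals can differ by up to 2 (at most 1 per class).

#' Stratified assignment of records to k groups
#'
#' @param labels Logical (or 0/1) outcome per record; `TRUE` marks the
#'   minority CPC1/2 class.
#' @param k Number of groups (default 5).
#' @param seed Integer seed; identical seed reproduces the identical plan.
#' @return Object of class `split_plan`: `group` (integer group index per
#'   record), `k`, `seed`, `test_group`, `group_order` (seeded ordering).
#' @export
stratified_split <- function(labels, k = 5L, seed = 1L) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop_config("labels contain missing values")
  k <- as.integer(k)
  if (k < 2L) stop_config("k must be at least 2")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos < k) stop_config("stratification impossible: %d positives < k = %d", npos, k)
  if (nneg < k) stop_config("stratification impossible: %d negatives < k = %d", nneg, k)

  with_seed(seed, {
    perm <- sample.int(k)                       # seeded ordering of groups
    # Per-class group sizes: base count everywhere, remainders assigned to
    # the tail of the seeded ordering (never to the test group perm[1]).
    class_sizes <- function(ntotal) {
      base <- ntotal %/% k; r <- ntotal %% k
      sz <- rep(base, k)                         # indexed by group id
      if (r > 0) sz[perm[k:(k - r + 1L)]] <- base + 1L
      sz
    }
    pos_sizes <- class_sizes(npos)
    neg_sizes <- class_sizes(nneg)
    group <- integer(length(labels))
    group[sample(which(labels))] <- rep.int(seq_len(k), pos_sizes[seq_len(k)])
    group[sample(which(!labels))] <- rep.int(seq_len(k), neg_sizes[seq_len(k)])
    structure(list(group = group, k = k, seed = as.integer(seed),
                   test_group = perm[1L], group_order = perm,
                   n = length(labels), n_pos = npos),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Stratified split plan: n =", x$n, "into", x$k, "groups (seed", x$seed, ")\n")
  cat("  group sizes:", paste(tabulate(x$group, x$k), collapse = ", "), "\n")
  cat("  test group:", x$test_group, "\n")
  invisible(x)
}

#' Derive the cross-validation folds of a split plan
#'
#' Each non-test group serves as the validation set exactly once; the
#' training set is the union of the other non-test groups. The test group
#' appears in no fold.
#'
#' @param plan A [stratified_split()] plan.
#' @return List of `k - 1` folds, each with integer index vectors `train`
#'   and `validation` and the `validation_group` id.
#' @export
cv_folds <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  nontest <- setdiff(seq_len(plan$k), plan$test_group)
  lapply(nontest, function(v) {
    list(validation_group = v,
         validation = which(plan$group == v),
         train = which(plan$group %in% setdiff(nontest, v)))
  })
}

#' Indices of the held-out test group
#' @param plan A [stratified_split()] plan.
#' @export
test_indices <- function(plan) which(plan$group == plan$test_group)

#' Serialize a split plan to JSON (and back)
#'
#' Stores the per-group record indices, seed and test group so runs are
#' resumable and auditable.
#' @param plan A `split_plan`.
#' @param path Output path.
#' @export
write_split_json <- function(plan, path) {
  jsonlite::write_json(
    list(k = plan$k, seed = plan$seed, test_group = plan$test_group,
         group_order = plan$group_order,
         groups = lapply(seq_len(plan$k), function(g) which(plan$group == g))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  groups <- lapply(raw$groups, function(g) as.integer(unlist(g)))
  n <- sum(lengths(groups))
  group <- integer(n)
  for (g in seq_along(groups)) group[groups[[g]]] <- g
  structure(list(group = group, k = as.integer(raw$k[[1]]),
                 seed = as.integer(raw$seed[[1]]),
                 test_group = as.integer(raw$test_group[[1]]),
                 group_order = as.integer(unlist(raw$group_order)),
                 n = n, n_pos = NA_integer_),
            class = "split_plan")
}
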