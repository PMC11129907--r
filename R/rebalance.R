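# Class rebalancing: random undersampling of majority classes and SMOTE
# oversampling of minority classes, both to a common target count. Rows
# removed by undersampling are retained as the "discarded pool" used later
# for out-of-sample evaluation.

#' Randomly undersample one class to a target size
#'
#' @param X Numeric matrix of one class's rows.
#' @param target Target row count (must not exceed `nrow(X)`).
#' @param seed Integer seed.
#' @return List `kept` (row indices into `X`) and `discarded` (complement).
#' @export
random_undersample <- function(X, target, seed = 1L) {
  n <- nrow(X)
  if (n < target) stop("class size ", n, " below target ", target, "; undersampling not applicable")
  set.seed(seed)
  kept <- sort(sample.int(n, target))
  list(kept = kept, discarded = setdiff(seq_len(n), kept))
}

#' SMOTE-oversample one class to a target size
#'
#' Synthetic rows are convex combinations `x_i + u (x_nn - x_i)` with
#' `u ~ U(0, 1)` and `x_nn` one of the `k` nearest same-class neighbours of
#' `x_i`. Neighbours are found by Euclidean distance in z-scored feature
#' space (so no single feature's scale dominates); interpolation happens in
#' the original space, which gives identical results since the scaling is
#' affine. `k` is capped at `nrow(X) - 1`.
#'
#' @param X Numeric matrix of one class's rows (at least 2).
#' @param target Target row count (must exceed `nrow(X)`).
#' @param k Number of nearest neighbours considered (default 5).
#' @param seed Integer seed.
#' @return List `rows` (target x d matrix: real rows first, then synthetic),
#'   `synthetic` (logical flag per row), `parents` (target x 2 matrix of
#'   parent row indices into `X`; `NA` for real rows).
#' @export
smote_oversample <- function(X, target, k = 5, seed = 1L) {
  n <- nrow(X)
  if (n < 2) stop("SMOTE needs at least 2 rows in the class")
  if (n >= target) stop("class size ", n, " already at or above target ", target)
  k <- min(k, n - 1)
  set.seed(seed)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nn_idx <- matrix(vapply(seq_len(n), function(i) order(D[i, ])[seq_len(k)],
                          integer(k)),
                   nrow = n, ncol = k, byrow = TRUE)
  n_syn <- target - n
  base <- sample.int(n, n_syn, replace = TRUE)
  pick <- nn_idx[cbind(base, sample.int(k, n_syn, replace = TRUE))]
  u <- stats::runif(n_syn)
  syn <- X[base, , drop = FALSE] + u * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])
  rows <- rbind(X, syn)
  parents <- rbind(matrix(NA_integer_, n, 2), cbind(base, pick))
  colnames(parents) <- c("parent_i", "parent_nn")
  list(rows = rows, synthetic = c(rep(FALSE, n), rep(TRUE, n_syn)),
       parents = parents)
}

#' Rebalance a selected-feature matrix to equal class counts
#'
#' Classes above `target` are randomly undersampled (their removed rows form
#' the discarded pool); classes below it are SMOTE-oversampled; a class
#' exactly at `target` passes through unchanged.
#'
#' @param X Numeric matrix (rows = samples, columns = selected features).
#' @param labels Integer labels in `{0, 1, 2}` per row.
#' @param target Per-class target count (default 300).
#' @param k SMOTE neighbour count.
#' @param seed Integer seed.
#' @return A `resampled_dataset`: list with `matrix` (3*target x d),
#'   `labels`, `synthetic` (logical per row), `provenance` (source row id in
#'   the input for real rows, `NA` for synthetic ones, plus parent ids),
#'   `discarded` (matrix of undersampled-away rows), `discarded_labels`,
#'   `discarded_ids` (row ids in the input).
#' @export
rebalance_dataset <- function(X, labels, target = 300, k = 5, seed = 1L) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to rebalance")
  mats <- list(); labs <- list(); syn <- list(); prov <- list()
  disc <- list(); disc_lab <- list(); disc_id <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    idx <- which(labels == cl)
    Xc <- X[idx, , drop = FALSE]
    sd_cl <- seed + ci # per-class seed stream
    if (length(idx) >= target) {
      us <- random_undersample(Xc, target, seed = sd_cl)
      mats[[ci]] <- Xc[us$kept, , drop = FALSE]
      syn[[ci]] <- rep(FALSE, target)
      prov[[ci]] <- cbind(source_id = idx[us$kept], parent_i = NA_integer_,
                          parent_nn = NA_integer_)
      disc[[ci]] <- Xc[us$discarded, , drop = FALSE]
      disc_lab[[ci]] <- rep(cl, length(us$discarded))
      disc_id[[ci]] <- idx[us$discarded]
    } else {
      sm <- smote_oversample(Xc, target, k = k, seed = sd_cl)
      mats[[ci]] <- sm$rows
      syn[[ci]] <- sm$synthetic
      prov[[ci]] <- cbind(source_id = ifelse(sm$synthetic, NA_integer_, idx),
                          parent_i = ifelse(is.na(sm$parents[, 1]), NA_integer_,
                                            idx[sm$parents[, 1]]),
                          parent_nn = ifelse(is.na(sm$parents[, 2]), NA_integer_,
                                             idx[sm$parents[, 2]]))
      disc[[ci]] <- matrix(numeric(0), 0, ncol(X), dimnames = list(NULL, colnames(X)))
      disc_lab[[ci]] <- integer(0)
      disc_id[[ci]] <- integer(0)
    }
    labs[[ci]] <- rep(cl, target)
  }
  structure(list(
    matrix = do.call(rbind, mats),
    labels = unlist(labs),
    synthetic = unlist(syn),
    provenance = do.call(rbind, prov),
    discarded = do.call(rbind, disc),
    discarded_labels = unlist(disc_lab),
    discarded_ids = unlist(disc_id)
  ), class = "resampled_dataset")
}
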