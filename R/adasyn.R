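# ADASYN adaptive synthetic oversampling, implemented from first principles
# for feature vectors and flattened images.

#' ADASYN oversampling
#'
#' Synthesizes minority-class points preferentially near the class boundary.
#' With `m` minority and `M` majority points, the total to generate is
#' `G = round(beta * (M - m))`. For each minority point `x_i`, `Delta_i`
#' counts majority points among its `k` Euclidean nearest neighbors in the
#' combined set; the normalized ratios `r_i = Delta_i / k` allocate `G`
#' across minority points by largest-remainder rounding (which guarantees
#' the allocations sum to `G` exactly; if no minority point has majority
#' neighbors the allocation is uniform). Each synthetic point is
#' `x_i + lambda * (x_z - x_i)` with `lambda ~ U(0, 1)` and `x_z` drawn
#' uniformly from `x_i`'s `k` nearest minority neighbors.
#'
#' @param minority numeric matrix of minority-class rows (at least 2).
#' @param majority numeric matrix of majority-class rows.
#' @param k neighborhood size.
#' @param beta balance fraction in `(0, 1]`; 1 balances fully.
#' @param seed integer seed; the draw is deterministic under it.
#' @return a matrix of synthetic rows with attributes `parent` (minority row
#'   index of each synthetic point) and `allocation` (`g_i` per minority
#'   row).
#' @export
adasyn <- function(minority, majority, k = 5L, beta = 1, seed = 1L) {
  minority <- as.matrix(minority)
  majority <- as.matrix(majority)
  m <- nrow(minority); M <- nrow(majority)
  if (m < 2)
    mwi_stop("ADASYN needs at least 2 minority points to interpolate",
             "mwi_validation_error")
  if (!is_count(k))
    mwi_stop("k must be a positive integer", "mwi_validation_error")
  if (!is_number(beta) || beta <= 0 || beta > 1)
    mwi_stop("beta must be in (0, 1]", "mwi_validation_error")
  if (ncol(minority) != ncol(majority))
    mwi_stop("minority and majority dimensionality differ",
             "mwi_dimension_error")
  G <- round(beta * (M - m))
  empty <- matrix(numeric(0), 0, ncol(minority),
                  dimnames = list(NULL, colnames(minority)))
  if (G <= 0)
    return(structure(empty, parent = integer(0), allocation = integer(m)))

  combined <- rbind(minority, majority)
  is_majority <- c(rep(FALSE, m), rep(TRUE, M))
  delta <- integer(m)
  min_nn <- vector("list", m)
  for (i in seq_len(m)) {
    d2 <- colSums((t(combined) - minority[i, ])^2)
    d2[i] <- Inf  # a point is not its own neighbor
    nn <- order(d2)[seq_len(min(k, m + M - 1))]
    delta[i] <- sum(is_majority[nn])
    dmin <- colSums((t(minority) - minority[i, ])^2)
    dmin[i] <- Inf
    min_nn[[i]] <- order(dmin)[seq_len(min(k, m - 1))]
  }
  r <- delta / k
  rhat <- if (sum(r) == 0) rep(1 / m, m) else r / sum(r)
  # largest-remainder allocation: the g_i sum to G exactly
  quota <- rhat * G
  g <- floor(quota)
  rem <- G - sum(g)
  if (rem > 0) {
    extra <- order(quota - g, decreasing = TRUE)[seq_len(rem)]
    g[extra] <- g[extra] + 1
  }
  out <- matrix(NA_real_, G, ncol(minority))
  colnames(out) <- colnames(minority)
  parent <- integer(G)
  with_seed(seed, {
    q <- 0
    for (i in seq_len(m)) {
      for (s in seq_len(g[i])) {
        q <- q + 1
        z <- min_nn[[i]][sample.int(length(min_nn[[i]]), 1)]
        lambda <- stats::runif(1)
        out[q, ] <- minority[i, ] + lambda * (minority[z, ] - minority[i, ])
        parent[q] <- i
      }
    }
  })
  structure(out, parent = parent, allocation = as.integer(g))
}

#' Labeled feature/image table
#'
#' Row container shared by the tabular and image pipelines: a numeric matrix
#' `x` (one row per instance; images are stored flattened), binary labels,
#' case ids, parent case ids (the originating measurement, used for
#' leakage-safe splitting) and provenance tags.
#'
#' @param x numeric matrix.
#' @param label integer vector of 0/1 labels (or numeric targets).
#' @param case_id character ids, unique per row.
#' @param parent_id originating case id per row (defaults to `case_id`).
#' @param provenance one of `"original"`, `"synthetic"`, `"augmented"` per
#'   row.
#' @return an object of class `labeled_table`.
#' @export
labeled_table <- function(x, label, case_id,
                          parent_id = case_id,
                          provenance = rep("original", nrow(x))) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(label), nrow(x) == length(case_id),
            nrow(x) == length(parent_id), nrow(x) == length(provenance))
  if (anyDuplicated(case_id))
    mwi_stop("duplicate case_id in labeled_table", "mwi_validation_error")
  structure(list(x = x, label = label, case_id = as.character(case_id),
                 parent_id = as.character(parent_id),
                 provenance = as.character(provenance)),
            class = "labeled_table")
}

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf("<labeled_table> %d rows x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s:%d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

table_subset <- function(tab, idx) {
  labeled_table(tab$x[idx, , drop = FALSE], tab$label[idx], tab$case_id[idx],
                tab$parent_id[idx], tab$provenance[idx])
}

table_rbind <- function(a, b) {
  labeled_table(rbind(a$x, b$x), c(a$label, b$label),
                c(a$case_id, b$case_id), c(a$parent_id, b$parent_id),
                c(a$provenance, b$provenance))
}

#' Balance a binary labeled table with ADASYN
#'
#' Appends ADASYN output to the minority class so the class counts become
#' equal. New rows carry provenance `"synthetic"` and their parent's case id.
#'
#' @param table a [labeled_table()] with 0/1 labels.
#' @param k,beta,seed passed to [adasyn()] (`beta` is forced to 1 so counts
#'   equalize).
#' @return a balanced [labeled_table()].
#' @export
balance_dataset <- function(table, k = 5L, beta = 1, seed = 1L) {
  stopifnot(inherits(table, "labeled_table"))
  tab <- base::table(factor(table$label, levels = c(0, 1)))
  if (any(tab == 0))
    mwi_stop("balance_dataset needs both classes present",
             "mwi_validation_error")
  if (tab[1] == tab[2]) return(table)
  minority_lab <- as.integer(names(which.min(tab)))
  mi <- table$label == minority_lab
  syn <- adasyn(table$x[mi, , drop = FALSE], table$x[!mi, , drop = FALSE],
                k = k, beta = beta, seed = seed)
  parents <- table$case_id[mi][attr(syn, "parent")]
  extra <- labeled_table(
    syn, rep(minority_lab, nrow(syn)),
    case_id = sprintf("%s-syn%03d", parents, seq_len(nrow(syn))),
    parent_id = parents,
    provenance = rep("synthetic", nrow(syn))
  )
  table_rbind(table, extra)
}
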