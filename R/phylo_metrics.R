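#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning a set of tips.
#' With `include_root = TRUE` (the default, matching the common default of
#' community-phylogenetics software) the path from the spanning subtree up
#' to the tree's root is included; with `FALSE` only branches between the
#' tips and their most recent common ancestor count.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param tips character vector of tip labels, at least one.
#' @param include_root include the path to the root (default `TRUE`).
#' @return total branch length of the spanning subtree.
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (!length(tips)) stop("need at least one tip", call. = FALSE)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tipn <- match(unique(tips), tree$tip.label)
  root <- ape::Ntip(tree) + 1L
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  on_path <- rep(FALSE, nrow(tree$edge))
  for (t in tipn) {
    p <- ape::nodepath(tree, root, t)
    on_path[match(paste(p[-length(p)], p[-1]), edge_key)] <- TRUE
  }
  if (!include_root) {
    mrca <- if (length(tipn) == 1) tipn else ape::getMRCA(tree, tipn)
    if (mrca != root) {
      p <- ape::nodepath(tree, root, mrca)
      on_path[match(paste(p[-length(p)], p[-1]), edge_key)] <- FALSE
    }
  }
  sum(tree$edge.length[on_path])
}

# logical matrix: for each edge (row), which tip labels (columns) descend
# from its child node
edge_tip_incidence <- function(tree) {
  ntip <- ape::Ntip(tree)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  inc <- matrix(FALSE, nrow(tree$edge), ntip,
                dimnames = list(NULL, tree$tip.label))
  inc[cbind(rep(seq_along(desc), lengths(desc)), unlist(desc))] <- TRUE
  inc
}

#' Unweighted UniFrac distance between two communities of tips
#'
#' Presence/absence measure: the fraction of the branch length leading to
#' either community's tips that leads to tips of exactly one of them.
#' Branches with no descendants in either community are ignored.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param tips_a,tips_b non-empty character vectors of tip labels.
#' @return distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(tree, tips_a, tips_b) {
  if (!length(tips_a) || !length(tips_b)) {
    stop("both tip sets must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(c(tips_a, tips_b), tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  inc <- edge_tip_incidence(tree)
  in_a <- rowSums(inc[, tree$tip.label %in% tips_a, drop = FALSE]) > 0
  in_b <- rowSums(inc[, tree$tip.label %in% tips_b, drop = FALSE]) > 0
  len <- tree$edge.length
  total <- sum(len[in_a | in_b])
  if (total == 0) return(0)
  sum(len[xor(in_a, in_b)]) / total
}

#' Pairwise unweighted UniFrac distances among communities
#'
#' Treats each group's tip set as one community (presence/absence) and
#' returns the symmetric distance matrix over all group pairs. Groups may
#' be treatment cells (isolate sets per richness x fungicide cell) or
#' finer units such as plants, in which case the result is the sample-level
#' matrix a PERMANOVA consumes.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param groups named list mapping group label -> character vector of tip
#'   labels; at least two groups.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @export
pairwise_unifrac <- function(tree, groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list", call. = FALSE)
  }
  labs <- names(groups)
  unknown <- setdiff(unlist(groups), tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  inc <- edge_tip_incidence(tree)
  pres <- vapply(groups, function(tp) {
    rowSums(inc[, tree$tip.label %in% tp, drop = FALSE]) > 0
  }, logical(nrow(tree$edge)))
  len <- tree$edge.length
  k <- length(groups)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      either <- pres[, i] | pres[, j]
      tot <- sum(len[either])
      val <- if (tot == 0) 0 else sum(len[xor(pres[, i], pres[, j])]) / tot
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' PERMANOVA on a distance matrix with sequential terms
#'
#' Permutational multivariate analysis of variance: partitions the sum of
#' squared distances among sequential model terms via the Gower-centred
#' inner-product matrix, forms a pseudo-F for each term against the
#' residual, and assesses it by permuting observation labels. The p-value
#' uses the add-one convention `(1 + #{F* >= F}) / (1 + n_permutations)`,
#' so the smallest attainable p is `1/(n_permutations + 1)`.
#'
#' @param d distance matrix (`dist` or square symmetric matrix) over
#'   observations.
#' @param data data.frame of factors, rows aligned with the rows of `d`.
#' @param terms character vector of sequential model terms, e.g.
#'   `c("richness", "richness:fungicide")` for the nested
#'   richness/fungicide layout, or a single factor name.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @param strata optional factor restricting permutations to occur within
#'   its levels (e.g. within richness plots for the nested term);
#'   default `NULL` permutes labels freely.
#' @return data.frame of class `permanova` with one row per term plus a
#'   residual and total row: columns `term`, `df`, `SS`, `R2`, `F`, `p`.
#' @export
permanova <- function(d, data, terms, n_permutations = 999, seed = NULL,
                      strata = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n != nrow(data)) stop("factors do not align with distance labels",
                            call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1",
                               call. = FALSE)
  for (tm in terms) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    for (v in vars) {
      if (!v %in% names(data)) stop("unknown factor: ", v, call. = FALSE)
      if (length(unique(data[[v]])) < 2) {
        stop("constant factor: ", v, call. = FALSE)
      }
    }
  }

  gower <- function(mm) {
    a <- -0.5 * mm^2
    ctr <- diag(n) - matrix(1 / n, n, n)
    ctr %*% a %*% ctr
  }

  # sequential hat matrices from cumulative model matrices
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mf <- stats::model.frame(fml, data)
  hats <- vector("list", length(terms))
  dfs <- numeric(length(terms))
  prev_rank <- 1L  # intercept
  prev_hat <- matrix(1 / n, n, n)
  for (i in seq_along(terms)) {
    fi <- stats::as.formula(paste("~", paste(terms[seq_len(i)],
                                             collapse = " + ")))
    x <- stats::model.matrix(fi, mf)
    qx <- qr(x)
    hat <- tcrossprod(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE])
    hats[[i]] <- hat - prev_hat
    dfs[i] <- qx$rank - prev_rank
    prev_hat <- hat
    prev_rank <- qx$rank
  }
  df_res <- n - prev_rank
  if (df_res < 1) stop("fewer observations than model degrees of freedom",
                       call. = FALSE)
  resid_hat <- diag(n) - prev_hat

  stat <- function(g) {
    # tr(HG) = sum(H * G) for symmetric G
    ss <- vapply(hats, function(h) sum(h * g), numeric(1))
    ss_res <- sum(resid_hat * g)
    # near-zero residual SS can round negative; its F is infinite when
    # the term carries signal and zero otherwise
    tiny <- sqrt(.Machine$double.eps) * max(abs(sum(diag(g))), 1e-12)
    f <- if (ss_res < tiny) {
      ifelse(ss > tiny, Inf, 0)
    } else {
      (ss / dfs) / (ss_res / df_res)
    }
    list(ss = ss, ss_res = ss_res, f = f)
  }

  g0 <- gower(m)
  obs <- stat(g0)
  ss_total <- sum(diag(g0))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  exceed <- numeric(length(terms))
  for (p in seq_len(n_permutations)) {
    perm <- if (is.null(strata)) {
      sample.int(n)
    } else {
      out <- seq_len(n)
      for (lv in unique(strata)) {
        idx <- which(strata == lv)
        out[idx] <- idx[sample.int(length(idx))]
      }
      out
    }
    fp <- stat(gower(m[perm, perm]))$f
    # count numerical ties as exceedances
    exceed <- exceed + (fp >= obs$f - sqrt(.Machine$double.eps))
  }
  pvals <- (1 + exceed) / (1 + n_permutations)

  res <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p = c(pvals, NA, NA))
  class(res) <- c("permanova", "data.frame")
  res
}

#' Faith's PD per treatment group
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param groups named list mapping group label -> tip labels.
#' @param include_root passed to [faith_pd()].
#' @return data.frame `group`, `n_tips`, `pd`.
#' @export
pd_by_group <- function(tree, groups, include_root = TRUE) {
  data.frame(group = names(groups),
             n_tips = vapply(groups, length, integer(1)),
             pd = vapply(groups, faith_pd, numeric(1), tree = tree,
                         include_root = include_root),
             row.names = NULL)
}
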