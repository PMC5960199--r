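#' Quartet topologies
#'
#' For four taxa taken in the fixed group order (t1, t2, t3, t4) the three
#' unrooted resolutions are labelled `T1 = (t1,t2 | t3,t4)`,
#' `T2 = (t1,t3 | t2,t4)` and `T3 = (t1,t4 | t2,t3)`. The label order fixes
#' the corner identity in the likelihood-mapping simplex.
#' @format a named list of length-4 leaf permutations, one per topology label.
#' @export
QUARTET_TOPOLOGIES <- list(
  T1 = c(1L, 2L, 3L, 4L),
  T2 = c(1L, 3L, 2L, 4L),
  T3 = c(1L, 4L, 2L, 3L)
)

# Compress a 4 x n integer site matrix (states 1..k, NA = missing) into
# unique fully-observed patterns with multiplicities.
quartet_patterns <- function(codes) {
  usable <- colSums(is.na(codes)) == 0L
  codes <- codes[, usable, drop = FALSE]
  n_used <- ncol(codes)
  if (n_used == 0L) {
    return(list(patterns = matrix(integer(), 4L, 0L), weights = numeric(),
                n_sites_used = 0L))
  }
  key <- paste(codes[1L, ], codes[2L, ], codes[3L, ], codes[4L, ])
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = codes[, first, drop = FALSE],
       weights = as.numeric(tab),
       n_sites_used = n_used)
}

# Site-pattern likelihoods for one resolved quartet ((a,b),(c,d)) with the
# five branch lengths (four terminal, one internal), averaged over
# discrete-gamma categories. `pat` is 4 x npat (rows a,b,c,d).
quartet_pattern_lik <- function(pat, model, bl) {
  k <- model$k
  npat <- ncol(pat)
  lik <- numeric(npat)
  for (r in model$category_rates) {
    Pa <- transition_matrix(model, bl[1L], r)
    Pb <- transition_matrix(model, bl[2L], r)
    Pc <- transition_matrix(model, bl[3L], r)
    Pd <- transition_matrix(model, bl[4L], r)
    Pi <- transition_matrix(model, bl[5L], r)
    # u_x = pi_x P(x->a) P(x->b); v_y = P(y->c) P(y->d); L = u' Pi v
    U <- (Pa[, pat[1L, ], drop = FALSE] * Pb[, pat[2L, ], drop = FALSE]) *
      model$frequencies
    V <- Pc[, pat[3L, ], drop = FALSE] * Pd[, pat[4L, ], drop = FALSE]
    lik <- lik + colSums(crossprod(Pi, U) * V)
  }
  lik / model$n_categories
}

# Branch-length vector convention: bl[1..4] belong to the four taxa in
# their input order; bl[5] is the internal branch. The topology permutation
# reorders rows/branches into the ((a,b),(c,d)) layout.
quartet_loglik_single <- function(pats, model, topology, branch_lengths) {
  perm <- QUARTET_TOPOLOGIES[[topology]]
  pat <- pats$patterns[perm, , drop = FALSE]
  bl <- c(branch_lengths[perm], branch_lengths[5L])
  lik <- quartet_pattern_lik(pat, model, bl)
  lik <- pmax(lik, .Machine$double.xmin)  # underflow guard for impossible columns
  sum(pats$weights * log(lik))
}

#' Quartet log-likelihood
#'
#' Exact Felsenstein pruning on a four-taxon alignment slice under one of
#' the three resolved topologies, additive over partitions. Columns in which
#' any of the four taxa is missing are excluded partition-wise.
#'
#' @param qaln a `phylo_alignment` with exactly 4 taxa; the row order is the
#'   group order of the hypothesis.
#' @param topology `"T1"`, `"T2"` or `"T3"` (see [QUARTET_TOPOLOGIES]).
#' @param models a `substitution_model`, or a list of one per partition.
#' @param branch_lengths five non-negative reals: one per taxon (input
#'   order) plus the internal branch.
#' @param scheme optional `partition_scheme`; `NULL` treats the slice as a
#'   single partition.
#' @return log-likelihood (`NA_real_` with zero usable sites: an
#'   undetermined quartet).
#' @export
quartet_loglik <- function(qaln, topology, models, branch_lengths,
                           scheme = NULL) {
  if (n_taxa(qaln) != 4L) stop("quartet alignment must have exactly 4 taxa")
  if (length(branch_lengths) != 5L || any(branch_lengths < 0)) {
    stop("branch_lengths must be 5 non-negative values")
  }
  parts <- prepare_quartet_partitions(qaln, models, scheme)
  if (sum(vapply(parts, function(p) p$pats$n_sites_used, integer(1L))) == 0L) {
    return(NA_real_)
  }
  sum(vapply(parts, function(p) {
    if (p$pats$n_sites_used == 0L) return(0)
    quartet_loglik_single(p$pats, p$model, topology, branch_lengths)
  }, numeric(1L)))
}

# Pattern-compress each partition of a 4-taxon slice once; reused across
# topologies and optimizer iterations.
prepare_quartet_partitions <- function(qaln, models, scheme = NULL) {
  codes <- encode_alignment(qaln)  # 4 x n_sites, states 1..k, NA = missing
  if (is.null(scheme)) {
    model <- if (inherits(models, "substitution_model")) models else models[[1L]]
    return(list(list(model = model, pats = quartet_patterns(codes))))
  }
  if (inherits(models, "substitution_model")) {
    models <- rep(list(models), length(scheme$partitions))
    names(models) <- names(scheme$partitions)
  }
  lapply(names(scheme$partitions), function(nm) {
    cols <- scheme$partitions[[nm]]
    list(model = models[[nm]],
         pats = quartet_patterns(codes[, cols, drop = FALSE]))
  })
}

#' Optimize quartet branch lengths
#'
#' Round-robin bounded scalar search (Brent) over the five branch lengths,
#' iterated until the log-likelihood improves by less than `tol` or
#' `max_rounds` rounds elapse. Deterministic for fixed input.
#'
#' @inheritParams quartet_loglik
#' @param lower,upper branch-length search bounds.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_rounds round cap; on hitting it the best-so-far is returned
#'   with `converged = FALSE`.
#' @param init initial branch lengths (5 values).
#' @return list with `loglik`, `branch_lengths`, `converged`,
#'   `n_sites_used`; `loglik` is `NA` for an undetermined quartet.
#' @export
optimize_quartet <- function(qaln, topology, models, scheme = NULL,
                             lower = 1e-8, upper = 10, tol = 1e-6,
                             max_rounds = 100L, init = rep(0.1, 5L)) {
  parts <- prepare_quartet_partitions(qaln, models, scheme)
  n_used <- sum(vapply(parts, function(p) p$pats$n_sites_used, integer(1L)))
  if (n_used == 0L) {
    return(list(loglik = NA_real_, branch_lengths = rep(NA_real_, 5L),
                converged = NA, n_sites_used = 0L))
  }
  parts <- Filter(function(p) p$pats$n_sites_used > 0L, parts)
  perm <- QUARTET_TOPOLOGIES[[topology]]
  # per-partition arranged patterns ((a,b),(c,d) layout) and log weights
  arranged <- lapply(parts, function(p) {
    list(model = p$model, pat = p$pats$patterns[perm, , drop = FALSE],
         w = p$pats$weights)
  })
  lnl_fun <- function(bl) {
    bla <- c(bl[perm], bl[5L])
    sum(vapply(arranged, function(a) {
      lik <- pmax(quartet_pattern_lik(a$pat, a$model, bla),
                  .Machine$double.xmin)
      sum(a$w * log(lik))
    }, numeric(1L)))
  }
  bl <- pmin(pmax(init, lower), upper)
  best <- lnl_fun(bl)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    prev <- best
    for (b in 1:5) {
      pos <- if (b == 5L) 5L else match(b, perm)
      # fix the four other branches: precompute their partial products so
      # the scalar search only rebuilds one transition matrix per eval
      pre <- lapply(arranged, function(a) {
        bla <- c(bl[perm], bl[5L])
        fixed <- lapply(a$model$category_rates, function(r) {
          m <- a$model
          P <- lapply(1:5, function(i) {
            if (i == pos) NULL else transition_matrix(m, bla[i], r)
          })
          Xb <- function(i) P[[i]][, a$pat[i, ], drop = FALSE]
          switch(pos,
            (m$frequencies * Xb(2L)) * (P[[5L]] %*% (Xb(3L) * Xb(4L))),
            (m$frequencies * Xb(1L)) * (P[[5L]] %*% (Xb(3L) * Xb(4L))),
            crossprod(P[[5L]], m$frequencies * Xb(1L) * Xb(2L)) * Xb(4L),
            crossprod(P[[5L]], m$frequencies * Xb(1L) * Xb(2L)) * Xb(3L),
            list(U = m$frequencies * Xb(1L) * Xb(2L), W = Xb(3L) * Xb(4L)))
        })
        list(model = a$model, pat = a$pat, w = a$w, fixed = fixed)
      })
      part_lnl <- function(x) {
        sum(vapply(pre, function(a) {
          m <- a$model
          lik <- 0
          for (ci in seq_along(m$category_rates)) {
            P <- transition_matrix(m, x, m$category_rates[ci])
            f <- a$fixed[[ci]]
            lik <- lik + if (pos == 5L) {
              colSums(crossprod(P, f$U) * f$W)
            } else {
              colSums(P[, a$pat[pos, ], drop = FALSE] * f)
            }
          }
          lik <- pmax(lik / m$n_categories, .Machine$double.xmin)
          sum(a$w * log(lik))
        }, numeric(1L)))
      }
      opt <- stats::optimize(function(x) -part_lnl(x),
                             lower = lower, upper = upper, tol = 1e-7)
      if (-opt$objective > best) {
        best <- -opt$objective
        bl[b] <- opt$minimum
      }
    }
    if (best - prev < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("quartet branch-length optimization hit the round cap")
  }
  list(loglik = best, branch_lengths = bl, converged = converged,
       n_sites_used = n_used)
}

#' Likelihood-mapping topology weights
#'
#' Normalized posterior weights p_i proportional to exp(lnL_i), computed via
#' log-sum-exp; invariant to adding a constant to all three log-likelihoods.
#'
#' @param loglik numeric vector of the three topology log-likelihoods.
#' @return numeric length-3 simplex vector `(p1, p2, p3)`.
#' @export
topology_weights <- function(loglik) {
  if (length(loglik) != 3L || any(!is.finite(loglik))) {
    stop("topology_weights needs 3 finite log-likelihoods")
  }
  w <- exp(loglik - logsumexp(loglik))
  w / sum(w)
}

#' Evaluate one quartet under all three topologies
#'
#' @inheritParams optimize_quartet
#' @return one-row tibble with taxa, per-topology optimized log-likelihoods,
#'   weights, and `n_sites_used` (all-`NA` likelihoods mark an undetermined
#'   quartet).
#' @export
evaluate_quartet <- function(qaln, models, scheme = NULL, ...) {
  fits <- lapply(names(QUARTET_TOPOLOGIES), function(tp) {
    optimize_quartet(qaln, tp, models, scheme = scheme, ...)
  })
  lnl <- vapply(fits, `[[`, numeric(1L), "loglik")
  taxa <- taxa_labels(qaln)
  if (anyNA(lnl)) {
    w <- rep(NA_real_, 3L)
  } else {
    w <- topology_weights(lnl)
  }
  tibble::tibble(
    taxon1 = taxa[1L], taxon2 = taxa[2L], taxon3 = taxa[3L], taxon4 = taxa[4L],
    lnl1 = lnl[1L], lnl2 = lnl[2L], lnl3 = lnl[3L],
    p1 = w[1L], p2 = w[2L], p3 = w[3L],
    n_sites_used = fits[[1L]]$n_sites_used
  )
}
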